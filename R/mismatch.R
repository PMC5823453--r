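#' The twelve ordered substitution labels
#'
#' `A>G` is the canonical A-to-I signature (inosine reads as guanosine);
#' `C>T` is C-to-U.
#' @return character vector of the 12 labels in fixed display order.
#' @export
mismatch_classes <- function() {
  c("A>G", "A>C", "A>T", "C>A", "C>G", "C>T",
    "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")
}

#' Resolve the transcribed strand for genomic positions
#'
#' Strand is taken from an overlapping gene when all overlapping genes agree;
#' positions covered by genes on both strands are flagged bidirectional
#' (classification deferred; such sites are removed by the bidirectional
#' filter). Positions overlapping no gene take the strand of the single gene
#' within `flank` bp when exactly one exists (`flank_gene`); otherwise the
#' strand is unresolved and plus-strand labelling is used downstream.
#'
#' @param gene_models a [gene_model_set()].
#' @param contig,pos parallel vectors of positions.
#' @param flank search distance for flanking genes (bp).
#' @return data.frame with columns `strand` (`+`/`-`/`NA`), `strand_source`
#'   (`gene`, `flank_gene`, `unknown`), `bidirectional` (logical).
#' @export
resolve_strand <- function(gene_models, contig, pos, flank = 5000L) {
  n <- length(pos)
  out <- data.frame(strand = rep(NA_character_, n),
                    strand_source = rep("unknown", n),
                    bidirectional = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (!n || !nrow(gene_models$genes)) return(out)
  gr <- gene_granges(gene_models)
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))

  ov <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
  gstrand <- as.character(GenomicRanges::strand(gr))
  if (length(ov)) {
    byq <- split(gstrand[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
    for (k in names(byq)) {
      i <- as.integer(k)
      s <- unique(byq[[k]])
      if (length(s) == 1L) {
        out$strand[i] <- s
        out$strand_source[i] <- "gene"
      } else {
        out$bidirectional[i] <- TRUE
      }
    }
  }
  todo <- which(is.na(out$strand) & !out$bidirectional)
  if (length(todo)) {
    ovf <- GenomicRanges::findOverlaps(q[todo], gr + flank, ignore.strand = TRUE)
    byq <- split(S4Vectors::subjectHits(ovf), S4Vectors::queryHits(ovf))
    for (k in names(byq)) {
      i <- todo[as.integer(k)]
      hits <- byq[[k]]
      if (length(hits) == 1L) {
        out$strand[i] <- gstrand[hits]
        out$strand_source[i] <- "flank_gene"
      }
    }
  }
  out
}

#' Classify mismatches on the transcribed strand
#'
#' Assigns each observation one of the twelve substitution labels. When a
#' strand is provided (strand-specific protocols resolve it at read level)
#' it is used directly; otherwise the strand comes from the gene context via
#' [resolve_strand()]. On the minus strand both ref and alt are
#' complemented, so a genomic T>C inside a minus-strand gene is reported as
#' the canonical A>G.
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param gene_models a [gene_model_set()], used when `provided_strand` is
#'   missing.
#' @param provided_strand optional `+`/`-` vector (length 1 or nrow).
#' @param flank flanking-gene search distance (bp).
#' @return `variants` with added columns `strand`, `strand_source`
#'   (`gene`, `flank_gene`, `provided`, `unknown`), `bidirectional` and
#'   `mismatch_class` (`NA` while deferred for bidirectional overlap).
#' @export
classify_mismatch <- function(variants, gene_models = NULL,
                              provided_strand = NULL, flank = 5000L) {
  n <- nrow(variants)
  if (!is.null(provided_strand)) {
    st <- rep(provided_strand, length.out = n)
    res <- data.frame(strand = st, strand_source = "provided",
                      bidirectional = FALSE, stringsAsFactors = FALSE)
  } else if (!is.null(gene_models)) {
    res <- resolve_strand(gene_models, variants$contig, variants$pos, flank)
  } else {
    res <- data.frame(strand = rep(NA_character_, n), strand_source = "unknown",
                      bidirectional = FALSE, stringsAsFactors = FALSE)
  }
  minus <- !is.na(res$strand) & res$strand == "-"
  ref_t <- ifelse(minus, complement_base(variants$ref), variants$ref)
  alt_t <- ifelse(minus, complement_base(variants$alt), variants$alt)
  cls <- paste0(ref_t, ">", alt_t)
  cls[res$bidirectional] <- NA_character_
  stopifnot(all(is.na(cls) | cls %in% mismatch_classes()))
  variants$strand <- res$strand
  variants$strand_source <- res$strand_source
  variants$bidirectional <- res$bidirectional
  variants$mismatch_class <- cls
  variants
}
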