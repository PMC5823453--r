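REGION_LEVELS <- c("CDS", "UTR5", "UTR3", "intron", "pseudogene",
                   "upstream", "downstream", "intergenic")

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter")

#' Genomic-region class of a site
#'
#' Precedence: CDS > UTR5/UTR3 > intron > pseudogene > upstream (<= 5 kb,
#' strand-aware) > downstream (<= 5 kb) > intergenic. The reported gene is
#' the one contributing the highest-precedence region; gene-body positions
#' of non-coding (`other`-biotype) genes count as intronic. Sites covered
#' by genes on both strands get `NA` (they are removed earlier by the
#' bidirectional filter).
#'
#' @param sites data.frame with `contig`, `pos`.
#' @param gene_models a [gene_model_set()].
#' @param config a [threshold_config()] (`gene_flank`).
#' @return data.frame with `region`, `gene_id`, `gene_symbol`.
#' @export
annotate_region <- function(sites, gene_models, config = threshold_config()) {
  n <- nrow(sites)
  out <- data.frame(region = rep("intergenic", n),
                    gene_id = rep(NA_character_, n),
                    gene_symbol = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  genes <- gene_models$genes
  feats <- gene_models$features
  complete_tx <- gene_models$transcripts
  for (i in seq_len(n)) {
    ctg <- sites$contig[i]; p <- sites$pos[i]
    ov <- genes[genes$contig == ctg & genes$start <= p & genes$end >= p, ,
                drop = FALSE]
    if (nrow(ov) && length(unique(ov$strand)) > 1L) {
      out$region[i] <- NA_character_
      next
    }
    best_rank <- length(REGION_LEVELS) # intergenic
    best_gene <- NA_character_
    for (j in seq_len(nrow(ov))) {
      g <- ov[j, ]
      if (g$biotype == "protein_coding") {
        f <- feats[feats$gene_id == g$gene_id & feats$start <= p &
                     feats$end >= p, , drop = FALSE]
        reg <- if (any(f$type == "cds")) "CDS"
        else if (any(f$type == "utr5")) "UTR5"
        else if (any(f$type == "utr3")) "UTR3"
        else "intron"
      } else if (g$biotype == "pseudogene") reg <- "pseudogene"
      else reg <- "intron"
      r <- match(reg, REGION_LEVELS)
      if (r < best_rank) { best_rank <- r; best_gene <- g$gene_id }
    }
    if (!nrow(ov)) {
      near <- genes[genes$contig == ctg &
                      genes$start - config$gene_flank <= p &
                      genes$end + config$gene_flank >= p, , drop = FALSE]
      for (j in seq_len(nrow(near))) {
        g <- near[j, ]
        before <- p < g$start
        upstream <- (g$strand == "+" && before) || (g$strand == "-" && !before)
        reg <- if (upstream) "upstream" else "downstream"
        r <- match(reg, REGION_LEVELS)
        if (r < best_rank) { best_rank <- r; best_gene <- g$gene_id }
      }
    }
    out$region[i] <- REGION_LEVELS[best_rank]
    out$gene_id[i] <- best_gene
    if (!is.na(best_gene))
      out$gene_symbol[i] <- genes$symbol[genes$gene_id == best_gene]
  }
  out
}

#' Coding consequence of an edited base
#'
#' Rebuilds the codon containing the site from the CDS of a complete
#' transcript (phase-aware, on the coding strand), substitutes the edited
#' base and translates both codons with the standard genetic code.
#'
#' @param contig,pos site location.
#' @param alt_t alternative base on the transcribed strand (for an A-to-I
#'   site, `G`).
#' @param gene_models a [gene_model_set()].
#' @param genome `DNAStringSet`.
#' @return list with `consequence` (`synonymous`, `non_synonymous`,
#'   `stop_gained`, `stop_lost`), `aa_change` ("Asn>Asp" style), `ref_aa`,
#'   `alt_aa`, `codon_ref`, `codon_alt`; or `NULL` when the position is in
#'   no complete transcript's CDS (a warning notes incomplete transcripts).
#' @export
coding_consequence <- function(contig, pos, alt_t, gene_models, genome) {
  feats <- gene_models$features
  hits <- feats[feats$type == "cds" & feats$contig == contig &
                  feats$start <= pos & feats$end >= pos, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  for (tx in unique(hits$transcript_id)) {
    complete <- gene_models$transcripts$complete[
      gene_models$transcripts$transcript_id == tx]
    if (!isTRUE(complete)) {
      warning("transcript ", tx, " incomplete (CDS not divisible by 3); ",
              "consequence omitted")
      next
    }
    cds <- feats[feats$transcript_id == tx & feats$type == "cds", , drop = FALSE]
    minus <- cds$strand[1] == "-"
    cds <- cds[order(cds$start, decreasing = minus), ]
    segs <- vapply(seq_len(nrow(cds)), function(k) {
      s <- genome_slice(genome, contig, cds$start[k], cds$end[k])
      if (minus) revcomp(s) else s
    }, character(1))
    coding <- paste(segs, collapse = "")
    # coding-order offset of the site within the concatenated CDS
    lens <- nchar(segs)
    off <- 0L; idx <- NA_integer_
    for (k in seq_len(nrow(cds))) {
      if (cds$start[k] <= pos && cds$end[k] >= pos) {
        idx <- off + if (minus) cds$end[k] - pos + 1L else pos - cds$start[k] + 1L
        break
      }
      off <- off + lens[k]
    }
    phase <- cds$phase[1]
    if (is.na(phase)) phase <- 0L
    idx0 <- idx - phase
    if (idx0 < 1L) next
    codon_i <- (idx0 - 1L) %/% 3L
    cstart <- phase + codon_i * 3L + 1L
    if (cstart + 2L > nchar(coding)) next
    codon_ref <- substr(coding, cstart, cstart + 2L)
    within <- idx - cstart + 1L
    codon_alt <- codon_ref
    substr(codon_alt, within, within) <- alt_t
    ref_aa <- unname(Biostrings::GENETIC_CODE[codon_ref])
    alt_aa <- unname(Biostrings::GENETIC_CODE[codon_alt])
    consequence <-
      if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gained"
      else if (ref_aa == "*") "stop_lost"
      else "non_synonymous"
    return(list(consequence = consequence,
                aa_change = paste0(AA3[ref_aa], ">", AA3[alt_aa]),
                ref_aa = ref_aa, alt_aa = alt_aa,
                codon_ref = codon_ref, codon_alt = codon_alt))
  }
  NULL
}

#' Repeat overlap of sites
#'
#' Class and family of the repeat covering each site; ties (nested or
#' overlapping repeats) go to the longest repeat, then the first by
#' coordinate.
#' @param sites data.frame with `contig`, `pos`.
#' @param repeats `GRanges` from [read_repeats()].
#' @return data.frame with `repeat_class` (`none` when uncovered) and
#'   `repeat_family`.
#' @export
repeat_overlap <- function(sites, repeats) {
  n <- nrow(sites)
  out <- data.frame(repeat_class = rep("none", n),
                    repeat_family = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (!n || !length(repeats)) return(out)
  q <- GenomicRanges::GRanges(sites$contig, IRanges::IRanges(sites$pos, sites$pos))
  ov <- GenomicRanges::findOverlaps(q, repeats, ignore.strand = TRUE)
  if (!length(ov)) return(out)
  widths <- GenomicRanges::width(repeats)
  starts <- GenomicRanges::start(repeats)
  for (i in unique(S4Vectors::queryHits(ov))) {
    hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    hits <- hits[order(-widths[hits], starts[hits])]
    out$repeat_class[i] <- as.character(repeats$repeat_class[hits[1L]])
    out$repeat_family[i] <- repeats$family[hits[1L]]
  }
  out
}

#' Annotate a site table
#'
#' Adds region/gene, coding consequence (CDS sites of complete transcripts
#' only) and repeat overlap columns.
#' @param sites a site table (needs `contig`, `pos`, `alt_t`).
#' @param gene_models a [gene_model_set()].
#' @param genome `DNAStringSet`.
#' @param repeats `GRanges` or `NULL`.
#' @param config a [threshold_config()].
#' @return `sites` with added columns `region`, `gene_id`, `gene_symbol`,
#'   `consequence`, `aa_change`, `repeat_class`, `repeat_family`.
#' @export
annotate_sites <- function(sites, gene_models, genome, repeats = NULL,
                           config = threshold_config()) {
  reg <- annotate_region(sites, gene_models, config)
  sites$region <- reg$region
  sites$gene_id <- reg$gene_id
  sites$gene_symbol <- reg$gene_symbol
  sites$consequence <- NA_character_
  sites$aa_change <- NA_character_
  cds_idx <- which(!is.na(sites$region) & sites$region == "CDS")
  for (i in cds_idx) {
    minus <- !is.na(sites$strand[i]) && sites$strand[i] == "-"
    alt_coding <- sites$alt_t[i] # transcribed strand == coding strand
    cc <- coding_consequence(sites$contig[i], sites$pos[i], alt_coding,
                             gene_models, genome)
    if (!is.null(cc)) {
      sites$consequence[i] <- cc$consequence
      sites$aa_change[i] <- cc$aa_change
    }
  }
  if (!is.null(repeats)) {
    ro <- repeat_overlap(sites, repeats)
    sites$repeat_class <- ro$repeat_class
    sites$repeat_family <- ro$repeat_family
  } else {
    sites$repeat_class <- "none"
    sites$repeat_family <- NA_character_
  }
  sites
}
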