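#' Find simple sequence repeats (microsatellites)
#'
#' Reports every maximal perfect tandem repeat with a primitive motif of
#' 1-8 nt and a total span of at least 6 bases (and at least two full motif
#' copies for motifs longer than one base). Motifs are reported in canonical
#' form, the lexicographically minimal rotation, and nested reports of the
#' same run under a non-primitive motif (a poly-A run re-found as "AA") are
#' suppressed. `N` never participates in a repeat.
#'
#' @param sequence a character scalar over A/C/G/T/N.
#' @param config a [threshold_config()] supplying `ssr_motif_len_range` and
#'   `ssr_min_total_len`.
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `motif`, `copies` (full copies), `total_len`.
#' @examples
#' find_ssrs("GGACACACTT")   # one AC repeat spanning 3..8
#' @export
find_ssrs <- function(sequence, config = threshold_config()) {
  df <- find_ssrs_cpp(sequence,
                      min_total = as.integer(config$ssr_min_total_len),
                      max_motif = as.integer(config$ssr_motif_len_range[2]))
  df <- df[nchar(df$motif) >= config$ssr_motif_len_range[1], , drop = FALSE]
  df$total_len <- df$end - df$start + 1L
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Is a position inside an SSR masking zone?
#'
#' SSR regions are considered biased with an offset of +/-3 bases: a
#' position is masked when it falls within `[start - offset, end + offset]`
#' of any repeat.
#'
#' @param pos integer vector of positions.
#' @param ssrs output of [find_ssrs()] for the same contig.
#' @param config a [threshold_config()] (uses `ssr_offset`).
#' @return logical vector.
#' @export
in_ssr_zone <- function(pos, ssrs, config = threshold_config()) {
  if (!nrow(ssrs)) return(rep(FALSE, length(pos)))
  off <- config$ssr_offset
  ir <- IRanges::IRanges(ssrs$start - off, ssrs$end + off)
  IRanges::overlapsAny(IRanges::IRanges(pos, pos), ir)
}

#' Homopolymer run adjacent to a variant (GATK HRun convention)
#'
#' Length of the longest run of reference bases equal to the ALT allele
#' immediately left or right of the variant position. Used to recompute
#' HRun locally when a VCF lacks the annotation.
#'
#' @param genome a `DNAStringSet`.
#' @param contig,pos site location.
#' @param alt_base the alternative allele.
#' @return integer run length (0 when neither neighbour matches).
#' @export
homopolymer_run <- function(genome, contig, pos, alt_base) {
  seq <- genome[[contig]]
  w <- length(seq)
  left <- 0L
  i <- pos - 1L
  while (i >= 1L && as.character(Biostrings::subseq(seq, i, i)) == alt_base) {
    left <- left + 1L; i <- i - 1L
  }
  right <- 0L
  i <- pos + 1L
  while (i <= w && as.character(Biostrings::subseq(seq, i, i)) == alt_base) {
    right <- right + 1L; i <- i + 1L
  }
  max(left, right)
}

#' Splice-junction proximity filter predicate
#'
#' TRUE when the position lies inside an intron within `splice_flank` bases
#' of either flanking exon boundary (misalignment around junctions inflates
#' false variant calls there).
#'
#' @param pos integer vector of positions.
#' @param contig contig name vector (length 1 or length of `pos`).
#' @param gene_models a [gene_model_set()].
#' @param config a [threshold_config()] (uses `splice_flank`).
#' @return logical vector.
#' @export
near_splice_junction <- function(pos, contig, gene_models,
                                 config = threshold_config()) {
  introns <- transcript_introns(gene_models)
  n <- length(pos)
  contig <- rep(contig, length.out = n)
  if (!nrow(introns)) return(rep(FALSE, n))
  k <- config$splice_flank
  # the first/last `k` intronic bases on each side
  zs <- pmin(introns$start + k - 1L, introns$end)
  ze <- pmax(introns$end - k + 1L, introns$start)
  zones <- GenomicRanges::GRanges(
    rep(introns$contig, 2L),
    IRanges::IRanges(c(introns$start, ze), c(zs, introns$end)))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, zones, ignore.strand = TRUE)
}

#' Bidirectional-transcription predicate
#'
#' TRUE when a position is covered by at least one gene on each strand
#' (sense/antisense gene pair); the transcribed strand of a variant there is
#' ambiguous, so such sites are removed.
#'
#' @param pos integer vector of positions.
#' @param contig contig name vector (length 1 or length of `pos`).
#' @param gene_models a [gene_model_set()].
#' @return logical vector.
#' @export
bidirectional_overlap <- function(pos, contig, gene_models) {
  n <- length(pos)
  contig <- rep(contig, length.out = n)
  if (!nrow(gene_models$genes)) return(rep(FALSE, n))
  gr <- gene_granges(gene_models)
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  plus <- IRanges::overlapsAny(q, gr[GenomicRanges::strand(gr) == "+"],
                                     ignore.strand = TRUE)
  minus <- IRanges::overlapsAny(q, gr[GenomicRanges::strand(gr) == "-"],
                                      ignore.strand = TRUE)
  plus & minus
}
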