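#' Numeric thresholds of the editing-site discovery pipeline
#'
#' Collects every cutoff used by the filter cascade, the cluster/extension
#' step and the validation matchers in a single validated record, so that a
#' run is fully described by one configuration object.
#'
#' Defaults are the published operating point of the method: sites need at
#' least 10 reads of coverage with at least 3 reads supporting the variant,
#' an editing ratio of at least 10% but below 100%; GATK site annotations
#' must satisfy HRun <= 5, MQ >= 40, QD >= 2, MQRankSum >= -12.5 and
#' ReadPosRankSum >= -8; simple sequence repeats are perfect tandem repeats
#' of a 1-8 nt motif spanning >= 6 bases and mask sites within +/-3 bases;
#' intronic sites within 5 bp of an exon boundary are discarded; the 101-bp
#' flank window (50 each side) must be unique in the assembly; editing sites
#' within 100 bp form clusters and recruit nearby variants; genes within
#' 5 kb assign strand/region to flanking sites; recurrence requires 2 of the
#' study's individuals.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return An object of class `threshold_config` (a validated named list)
#'   with elements `min_depth`, `min_alt_reads`, `min_ratio`,
#'   `max_ratio_exclusive`, `max_hrun`, `min_mq`, `min_qd`, `min_mqranksum`,
#'   `min_readposranksum`, `ssr_motif_len_range`, `ssr_min_total_len`,
#'   `ssr_offset`, `splice_flank`, `uniq_flank`, `cluster_window`,
#'   `gene_flank`, `min_individuals`, `motif_flank`, `est_evalue`,
#'   `cons_evalue`, `cons_min_identity`, `cons_min_alnlen`,
#'   `uniq_min_identity`, `uniq_min_coverage`, `snp_match_alleles`,
#'   `recurrence_same_tissue`, `transitive_extension`.
#' @examples
#' cfg <- threshold_config()
#' cfg$min_depth
#' threshold_config(min_individuals = 3)$min_individuals
#' @export
threshold_config <- function(...) {
  cfg <- list(
    min_depth = 10L,
    min_alt_reads = 3L,
    min_ratio = 0.10,
    max_ratio_exclusive = 1.0,
    max_hrun = 5L,
    min_mq = 40,
    min_qd = 2,
    min_mqranksum = -12.5,
    min_readposranksum = -8,
    ssr_motif_len_range = c(1L, 8L),
    ssr_min_total_len = 6L,
    ssr_offset = 3L,
    splice_flank = 5L,
    uniq_flank = 50L,
    cluster_window = 100L,
    gene_flank = 5000L,
    min_individuals = 2L,
    motif_flank = 10L,
    est_evalue = 1e-5,
    cons_evalue = 1e-3,
    cons_min_identity = 0.85,
    cons_min_alnlen = 50L,
    # rule used by the flank-uniqueness (BLAT-style) filter
    uniq_min_identity = 0.90,
    uniq_min_coverage = 0.90,
    # behavioural switches
    snp_match_alleles = FALSE,
    recurrence_same_tissue = FALSE,
    transitive_extension = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_threshold_config(cfg)
  structure(cfg, class = "threshold_config")
}

validate_threshold_config <- function(cfg) {
  pos <- c("min_depth", "min_alt_reads", "max_hrun", "min_mq", "min_qd",
           "ssr_min_total_len", "ssr_offset", "splice_flank", "uniq_flank",
           "cluster_window", "gene_flank", "min_individuals", "motif_flank",
           "est_evalue", "cons_evalue", "cons_min_identity", "cons_min_alnlen")
  for (k in pos)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      stop("threshold '", k, "' must be a positive scalar")
  if (cfg$min_ratio >= cfg$max_ratio_exclusive)
    stop("min_ratio must be below max_ratio_exclusive")
  r <- cfg$ssr_motif_len_range
  if (length(r) != 2L || r[1] < 1L || r[2] < r[1])
    stop("ssr_motif_len_range must be an increasing pair of positive lengths")
  invisible(cfg)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}
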