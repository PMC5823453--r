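#' Detect hyper-editing clusters
#'
#' Single-linkage chaining: two sites on the same contig join when their
#' positions differ by at most `cluster_window` bp (inclusive); clusters are
#' the connected components with at least two members, everything else is a
#' singleton. ADAR acts promiscuously on double-stranded RNA, so genuine
#' editing sites pile up in short windows while isolated artefacts do not.
#'
#' @param sites data.frame with `contig` and `pos` (one row per site).
#' @param config a [threshold_config()] (`cluster_window`).
#' @return list with `clusters` (data.frame: `cluster_id`, `contig`,
#'   `span_start`, `span_end`, `n_sites`, `members` comma-list of
#'   positions) and `singletons` (site rows not in any cluster). Row order
#'   of the input is preserved in the `cluster_id` column added to `sites`
#'   (`NA` for singletons), returned as `assignment`.
#' @export
detect_clusters <- function(sites, config = threshold_config()) {
  n <- nrow(sites)
  cluster_id <- rep(NA_integer_, n)
  clusters <- list()
  if (n) {
    o <- order(sites$contig, sites$pos)
    ctg <- sites$contig[o]; pos <- sites$pos[o]
    new_comp <- c(TRUE, ctg[-1L] != ctg[-n] |
                    pos[-1L] - pos[-n] > config$cluster_window)
    comp <- cumsum(new_comp)
    next_id <- 0L
    for (cp in unique(comp)) {
      idx <- o[comp == cp]
      if (length(idx) < 2L) next
      next_id <- next_id + 1L
      cluster_id[idx] <- next_id
      p <- sort(sites$pos[idx])
      clusters[[next_id]] <- data.frame(
        cluster_id = next_id, contig = sites$contig[idx][1L],
        span_start = p[1L], span_end = p[length(p)],
        n_sites = length(p), members = paste(p, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster_id = integer(), contig = character(),
               span_start = integer(), span_end = integer(),
               n_sites = integer(), members = character(),
               stringsAsFactors = FALSE)
  assignment <- sites
  assignment$cluster_id <- cluster_id
  list(clusters = clusters,
       singletons = sites[is.na(cluster_id), , drop = FALSE],
       assignment = assignment)
}

#' Extend the editome around high-confidence sites
#'
#' Single-pass recruitment: every variant of the relaxed pool (quality
#' filters and known-SNP subtraction only) within `cluster_window` bp of at
#' least one high-confidence A>G site is added to the editome with
#' `origin = "extended"`, keeping its own mismatch class. Newly added sites
#' do not recruit further unless `config$transitive_extension` is set.
#' Recruited positions already in the high-confidence set are dropped.
#'
#' @param high_conf_sites site table ([recurrence_filter()] output).
#' @param snv_pool classified pool variants (data.frame with `contig`,
#'   `pos`, `mismatch_class`, ...). Typically deduplicated by position.
#' @param config a [threshold_config()].
#' @return the recruited subset of `snv_pool` (deduplicated by contig/pos)
#'   with an `origin = "extended"` column; attribute `a_to_i_fraction`
#'   holds the A>G percentage of the added set.
#' @export
extend_sites <- function(high_conf_sites, snv_pool,
                         config = threshold_config()) {
  pool <- snv_pool[!duplicated(paste(snv_pool$contig, snv_pool$pos)), ,
                   drop = FALSE]
  hc_key <- paste(high_conf_sites$contig, high_conf_sites$pos)
  pool <- pool[!paste(pool$contig, pool$pos) %in% hc_key, , drop = FALSE]
  anchors <- high_conf_sites[high_conf_sites$mismatch_class == "A>G", ,
                             drop = FALSE]
  recruited <- rep(FALSE, nrow(pool))
  repeat {
    if (!nrow(anchors)) break
    agr <- GenomicRanges::GRanges(
      anchors$contig,
      IRanges::IRanges(pmax(1L, anchors$pos - config$cluster_window),
                       anchors$pos + config$cluster_window))
    hit <- IRanges::overlapsAny(
      GenomicRanges::GRanges(pool$contig, IRanges::IRanges(pool$pos, pool$pos)),
      agr, ignore.strand = TRUE)
    new_hits <- hit & !recruited
    recruited <- recruited | hit
    if (!config$transitive_extension || !any(new_hits)) break
    anchors <- pool[new_hits & pool$mismatch_class %in% "A>G", , drop = FALSE]
  }
  out <- pool[recruited, , drop = FALSE]
  out$origin <- rep("extended", nrow(out))
  rownames(out) <- NULL
  attr(out, "a_to_i_fraction") <- if (nrow(out))
    100 * mean(out$mismatch_class == "A>G", na.rm = TRUE) else NA_real_
  out
}

#' Write cluster table as TSV
#' @param clusters the `clusters` element of [detect_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
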