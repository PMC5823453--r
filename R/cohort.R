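site_key <- function(df) paste(df$contig, df$pos, df$ref_t, df$alt_t, sep = ":")

#' Recurrence filter: candidate sites seen in several individuals
#'
#' Groups per-sample cascade survivors by (contig, pos, ref, alt on the
#' transcribed strand) and keeps groups supported by at least
#' `min_individuals` distinct individuals — in any tissue by default, since
#' editing recurs across animals while private SNPs and errors do not. The
#' tissue set of a site is every tissue with at least one passing support
#' observation.
#'
#' @param candidates classified cascade survivors: a data.frame with
#'   `contig`, `pos`, `ref`, `alt`, `strand`, `mismatch_class`,
#'   `individual`, `tissue`, `alt_depth`, `total_depth`.
#' @param config a [threshold_config()] (`min_individuals`,
#'   `recurrence_same_tissue`).
#' @return a site table: one row per site with columns `contig`, `pos`,
#'   `ref_t`, `alt_t` (transcribed strand), `strand`, `strand_source`,
#'   `mismatch_class`, `n_individuals`, `individuals`, `tissues`,
#'   `n_tissues`, `mean_ratio`, `origin` (`high_confidence`) and a `support`
#'   list-column of per-sample observations.
#' @export
recurrence_filter <- function(candidates, config = threshold_config()) {
  cand <- candidates[!is.na(candidates$mismatch_class), , drop = FALSE]
  if (!nrow(cand)) return(site_frame())
  sp <- strsplit(cand$mismatch_class, ">", fixed = TRUE)
  cand$ref_t <- vapply(sp, `[[`, character(1), 1L)
  cand$alt_t <- vapply(sp, `[[`, character(1), 2L)
  cand$ratio <- cand$alt_depth / cand$total_depth
  groups <- split(cand, site_key(cand))
  rows <- lapply(groups, function(g) {
    if (config$recurrence_same_tissue) {
      per_tissue <- vapply(split(g$individual, g$tissue),
                           function(x) length(unique(x)), integer(1))
      if (!any(per_tissue >= config$min_individuals)) return(NULL)
    } else {
      if (length(unique(g$individual)) < config$min_individuals) return(NULL)
    }
    data.frame(contig = g$contig[1], pos = g$pos[1],
               ref_t = g$ref_t[1], alt_t = g$alt_t[1],
               strand = g$strand[1], strand_source = g$strand_source[1],
               mismatch_class = g$mismatch_class[1],
               n_individuals = length(unique(g$individual)),
               individuals = paste(sort(unique(g$individual)), collapse = ","),
               tissues = paste(sort(unique(g$tissue)), collapse = ","),
               n_tissues = length(unique(g$tissue)),
               mean_ratio = mean(g$ratio),
               origin = "high_confidence", stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  if (is.null(out)) return(site_frame())
  out$support <- I(lapply(groups[keep], function(g)
    g[, c("individual", "tissue", "ratio", "alt_depth", "total_depth")]))
  out <- out[order(out$contig, out$pos), ]
  rownames(out) <- NULL
  out
}

site_frame <- function() {
  df <- data.frame(contig = character(), pos = integer(), ref_t = character(),
                   alt_t = character(), strand = character(),
                   strand_source = character(), mismatch_class = character(),
                   n_individuals = integer(), individuals = character(),
                   tissues = character(), n_tissues = integer(),
                   mean_ratio = numeric(), origin = character(),
                   stringsAsFactors = FALSE)
  df$support <- I(list())
  df
}

tissue_sets <- function(sites) strsplit(sites$tissues, ",", fixed = TRUE)

#' Tissue-specific editing sites
#'
#' A site is specific to a tissue when its tissue set has exactly one
#' member.
#' @param sites a site table ([recurrence_filter()]).
#' @return named list, tissue -> site table of sites specific to it.
#' @export
tissue_specific_sites <- function(sites) {
  ts <- tissue_sets(sites)
  spec <- lengths(ts) == 1L
  split(sites[spec, , drop = FALSE],
        vapply(ts[spec], `[[`, character(1), 1L))
}

#' Count sites shared by at least k tissues
#' @param sites a site table.
#' @param k minimum tissue count (>= 1).
#' @return integer count.
#' @export
shared_site_counts <- function(sites, k) {
  if (k < 1L) stop("k must be >= 1")
  sum(lengths(tissue_sets(sites)) >= k)
}

#' Mismatch spectrum over the twelve substitution classes
#'
#' Counts and percentages of each class; the A>G share is the A-to-I
#' fraction, the headline enrichment quantity of the filter cascade.
#'
#' @param classes character vector of mismatch labels, or a site table
#'   (its `mismatch_class` column is used).
#' @return data.frame (class, count, percent) with attribute
#'   `a_to_i_fraction` (in percent).
#' @examples
#' sp <- mismatch_spectrum(c(rep("A>G", 697), rep("C>T", 97)))
#' attr(sp, "a_to_i_fraction")  # 87.78
#' @export
mismatch_spectrum <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$mismatch_class
  classes <- classes[!is.na(classes)]
  counts <- table(factor(classes, levels = mismatch_classes()))
  total <- sum(counts)
  out <- data.frame(class = names(counts), count = as.integer(counts),
                    percent = if (total) 100 * as.integer(counts) / total else
                      rep(0, length(counts)),
                    stringsAsFactors = FALSE)
  attr(out, "a_to_i_fraction") <-
    if (total) 100 * out$count[out$class == "A>G"] / total else NA_real_
  out
}

#' Per-tissue mismatch spectrum
#' @param sites a site table.
#' @return matrix of counts, 12 classes x tissues (a site contributes to
#'   every tissue it is edited in).
#' @export
spectrum_by_tissue <- function(sites) {
  ts <- tissue_sets(sites)
  long <- data.frame(class = rep(sites$mismatch_class, lengths(ts)),
                     tissue = unlist(ts))
  table(factor(long$class, levels = mismatch_classes()), long$tissue)
}

#' Site-by-tissue editing-ratio matrix
#'
#' A site's editing ratio in a tissue is the mean over that tissue's
#' supporting samples; `NA` where the site was not observed.
#' @param sites a site table with its `support` list-column.
#' @param tissues tissue order for the columns (default: all observed).
#' @return numeric matrix, sites x tissues, rownames `contig:pos`.
#' @export
site_tissue_matrix <- function(sites, tissues = NULL) {
  if (is.null(tissues))
    tissues <- sort(unique(unlist(tissue_sets(sites))))
  m <- matrix(NA_real_, nrow(sites), length(tissues),
              dimnames = list(paste0(sites$contig, ":", sites$pos), tissues))
  for (i in seq_len(nrow(sites))) {
    sup <- sites$support[[i]]
    agg <- tapply(sup$ratio, sup$tissue, mean)
    keep <- intersect(names(agg), tissues)
    m[i, keep] <- agg[keep]
  }
  m
}

#' Two-tissue comparison of editing ratios
#'
#' Unpaired two-sample Student t-test (pooled variance by default) on the
#' per-site mean editing ratios of the two tissues. When both groups are
#' degenerate (zero variance) and the means are equal, p = 1 by convention.
#'
#' @param sites a site table.
#' @param tissue_a,tissue_b tissue names.
#' @param var_equal pooled-variance Student test (`TRUE`, default) or Welch.
#' @return list with `t`, `df`, `p`, `n_a`, `n_b`.
#' @export
compare_editing_ratios <- function(sites, tissue_a, tissue_b, var_equal = TRUE) {
  m <- site_tissue_matrix(sites, tissues = c(tissue_a, tissue_b))
  a <- m[, 1L][!is.na(m[, 1L])]
  b <- m[, 2L][!is.na(m[, 2L])]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two ratio observations per tissue")
  res <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                  error = function(e) NULL)
  if (is.null(res)) { # degenerate: constant data
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  n_a = length(a), n_b = length(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0,
                n_a = length(a), n_b = length(b)))
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, n_a = length(a), n_b = length(b))
}

#' All-pairs tissue comparison with FDR control
#'
#' Student t-tests for every tissue pair, Benjamini-Hochberg corrected
#' across the pairs; significance at q < 0.05.
#' @param sites a site table.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return data.frame with `tissue_a`, `tissue_b`, `t`, `df`, `p`, `q`,
#'   `significant`.
#' @export
tissue_ratio_tests <- function(sites, var_equal = TRUE) {
  tissues <- sort(unique(unlist(tissue_sets(sites))))
  pairs <- utils::combn(tissues, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    r <- compare_editing_ratios(sites, pairs[1L, j], pairs[2L, j], var_equal)
    data.frame(tissue_a = pairs[1L, j], tissue_b = pairs[2L, j],
               t = r$t, df = r$df, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < 0.05
  out
}

#' Correlation between deaminase expression and per-tissue editing
#'
#' Pearson correlation (two-sided test) between the summed TPM expression
#' of the given gene(s) — typically the ADAR deaminase family — and a
#' per-tissue editing count across tissues.
#'
#' @param tpm_table numeric matrix or data.frame, genes x tissues (rownames
#'   = gene ids), e.g. from [read_tpm_matrix()].
#' @param per_tissue_edit_counts named numeric vector, tissue -> count.
#' @param genes gene id(s) whose expression is summed.
#' @return list with `pearson_r`, `p`, `n`.
#' @export
expression_editing_correlation <- function(tpm_table, per_tissue_edit_counts,
                                           genes) {
  tpm_table <- as.matrix(tpm_table)
  missing_g <- setdiff(genes, rownames(tpm_table))
  if (length(missing_g)) stop("gene(s) absent from TPM table: ",
                              paste(missing_g, collapse = ", "))
  tissues <- intersect(colnames(tpm_table), names(per_tissue_edit_counts))
  if (length(tissues) < 3L) stop("need at least 3 shared tissues")
  expr <- colSums(tpm_table[genes, tissues, drop = FALSE])
  ct <- stats::cor.test(expr, per_tissue_edit_counts[tissues],
                        method = "pearson")
  list(pearson_r = unname(ct$estimate), p = ct$p.value, n = length(tissues))
}

#' Read a TPM expression matrix
#' @param path TSV, first column gene id, remaining columns tissues.
#' @return numeric matrix with gene rownames.
#' @export
read_tpm_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
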