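FILTER_REASONS <- c("known_snp", "multi_allelic", "hom_alt", "low_depth",
                    "few_alt_reads", "low_ratio", "full_ratio", "hrun",
                    "low_mq", "low_qd", "mqranksum", "readposranksum",
                    "bidirectional", "ssr", "splice_junction",
                    "non_unique_flank", "none")

first_reason <- function(n, checks) {
  # checks: named list of logical fail-vectors, in documented order
  reason <- rep("none", n)
  for (nm in names(checks)) {
    fail <- checks[[nm]]
    fail[is.na(fail)] <- FALSE
    reason[reason == "none" & fail] <- nm
  }
  reason
}

#' GATK-style site quality filters
#'
#' A variant fails when HRun > 5, total depth < 10, RMS mapping quality
#' < 40, quality-by-depth < 2, MQRankSum < -12.5 or ReadPosRankSum < -8
#' (strict inequalities exactly as printed; a site at a boundary value
#' passes). Missing annotations pass and are recorded as absent.
#'
#' @param variants variant observation data.frame (see [read_variants()]).
#' @param config a [threshold_config()].
#' @return data.frame with `passed` and `reason` (the first failing check in
#'   the order above, or `none`).
#' @export
apply_quality_filters <- function(variants, config = threshold_config()) {
  n <- nrow(variants)
  reason <- first_reason(n, list(
    hrun = variants$hrun > config$max_hrun,
    low_depth = variants$total_depth < config$min_depth,
    low_mq = variants$mq < config$min_mq,
    low_qd = variants$qd < config$min_qd,
    mqranksum = variants$mq_rank_sum < config$min_mqranksum,
    readposranksum = variants$read_pos_rank_sum < config$min_readposranksum))
  data.frame(passed = reason == "none", reason = reason, stringsAsFactors = FALSE)
}

#' Allele, zygosity and editing-ratio filters
#'
#' Fails, in order: more than one non-reference allele; homozygous for the
#' alternative allele; fewer than 10 reads of coverage; fewer than 3 reads
#' supporting the variant; editing ratio below 10%; editing ratio exactly
#' 100% (full variation is assumed to be a homozygous genotype, not
#' editing).
#'
#' @inheritParams apply_quality_filters
#' @return data.frame with `passed` and `reason`.
#' @export
apply_allele_filters <- function(variants, config = threshold_config()) {
  n <- nrow(variants)
  ratio <- variants$alt_depth / variants$total_depth
  reason <- first_reason(n, list(
    multi_allelic = variants$multi_allelic,
    hom_alt = variants$genotype == "hom_alt",
    low_depth = variants$total_depth < config$min_depth,
    few_alt_reads = variants$alt_depth < config$min_alt_reads,
    low_ratio = ratio < config$min_ratio,
    full_ratio = ratio >= config$max_ratio_exclusive))
  data.frame(passed = reason == "none", reason = reason, stringsAsFactors = FALSE)
}

# vectorized HRun recomputation (GATK convention), capped at cap bases
hrun_batch <- function(genome, contig, pos, alt, cap = 8L) {
  n <- length(pos)
  run <- integer(n)
  for (ctg in unique(contig)) {
    idx <- which(contig == ctg)
    s <- as.character(genome[[ctg]])
    w <- nchar(s)
    left <- matrix(FALSE, length(idx), cap)
    right <- matrix(FALSE, length(idx), cap)
    for (d in seq_len(cap)) {
      pl <- pos[idx] - d
      pr <- pos[idx] + d
      left[, d] <- pl >= 1L & substring(s, pmax(pl, 1L), pmax(pl, 1L)) == alt[idx]
      right[, d] <- pr <= w & substring(s, pmin(pr, w), pmin(pr, w)) == alt[idx]
    }
    lrun <- rowSums(t(apply(left, 1L, cumprod)))
    rrun <- rowSums(t(apply(right, 1L, cumprod)))
    if (length(idx) == 1L) { # apply() drops dims for single rows
      lrun <- sum(cumprod(left[1, ]))
      rrun <- sum(cumprod(right[1, ]))
    }
    run[idx] <- pmax(lrun, rrun)
  }
  run
}

#' Run the full per-sample filter cascade
#'
#' Deterministic stage order: known-SNP subtraction (when `known_snps`
#' given), GATK quality filters, allele filters, bidirectional
#' transcription, SSR masking, splice-junction proximity, flank uniqueness.
#' Each rejected observation records exactly the first failing stage, so
#' the ledger's reason counts sum to input minus survivors. When the VCF
#' lacks an HRun annotation it is recomputed from the genome.
#'
#' @param variants variant observation data.frame.
#' @param genome `DNAStringSet` (for HRun recomputation, SSRs and flank
#'   uniqueness).
#' @param gene_models a [gene_model_set()].
#' @param config a [threshold_config()].
#' @param known_snps optional known-SNP data.frame or VCF path.
#' @param skip_uniqueness skip the (most expensive) flank-uniqueness stage.
#' @return list with `verdicts` (the input plus `passed`/`reason`),
#'   `passed` (surviving rows) and `ledger` (named rejection counts).
#' @export
run_cascade <- function(variants, genome, gene_models,
                        config = threshold_config(), known_snps = NULL,
                        skip_uniqueness = FALSE) {
  n <- nrow(variants)
  reason <- rep("none", n)
  live <- function() which(reason == "none")

  if (!is.null(known_snps)) {
    kept <- subtract_known_snps(variants, known_snps,
                                match_alleles = config$snp_match_alleles)
    key <- paste(variants$contig, variants$pos, variants$alt)
    reason[!key %in% paste(kept$contig, kept$pos, kept$alt)] <- "known_snp"
  }

  i <- live()
  if (length(i)) {
    v <- variants[i, ]
    if (any(is.na(v$hrun)))
      v$hrun[is.na(v$hrun)] <- hrun_batch(genome, v$contig[is.na(v$hrun)],
                                          v$pos[is.na(v$hrun)],
                                          v$alt[is.na(v$hrun)])
    q <- apply_quality_filters(v, config)
    reason[i] <- q$reason
  }

  i <- live()
  if (length(i)) reason[i] <- apply_allele_filters(variants[i, ], config)$reason

  i <- live()
  if (length(i)) {
    bid <- bidirectional_overlap(variants$pos[i], variants$contig[i], gene_models)
    reason[i][bid] <- "bidirectional"
  }

  i <- live()
  if (length(i)) {
    inssr <- logical(length(i))
    for (ctg in unique(variants$contig[i])) {
      sel <- variants$contig[i] == ctg
      ssrs <- find_ssrs(as.character(genome[[ctg]]), config)
      inssr[sel] <- in_ssr_zone(variants$pos[i][sel], ssrs, config)
    }
    reason[i][inssr] <- "ssr"
  }

  i <- live()
  if (length(i)) {
    spl <- near_splice_junction(variants$pos[i], variants$contig[i],
                                gene_models, config)
    reason[i][spl] <- "splice_junction"
  }

  i <- live()
  if (length(i) && !skip_uniqueness) {
    sites <- unique(variants[i, c("contig", "pos")])
    uq <- flank_unique_sites(genome, sites, config)
    key <- paste(uq$contig, uq$pos)
    bad <- !uq$unique[match(paste(variants$contig[i], variants$pos[i]), key)]
    reason[i][bad] <- "non_unique_flank"
  }

  verdicts <- variants
  verdicts$passed <- reason == "none"
  verdicts$reason <- reason
  ledger <- table(factor(reason[reason != "none"],
                         levels = setdiff(FILTER_REASONS, "none")))
  list(verdicts = verdicts, passed = variants[reason == "none", , drop = FALSE],
       ledger = c(ledger))
}

#' Write the filter ledger as TSV
#'
#' One row per observation: location, sample, verdict, reason and the
#' values the decision used (JSON column).
#' @param verdicts the `verdicts` element of [run_cascade()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_ledger <- function(verdicts, path) {
  vals <- vapply(seq_len(nrow(verdicts)), function(i) {
    v <- verdicts[i, ]
    jsonlite::toJSON(list(
      dp = v$total_depth, alt_reads = v$alt_depth,
      ratio = round(v$alt_depth / v$total_depth, 4),
      genotype = v$genotype, hrun = v$hrun, mq = v$mq, qd = v$qd,
      mq_rank_sum = v$mq_rank_sum, read_pos_rank_sum = v$read_pos_rank_sum),
      auto_unbox = TRUE, na = "null", digits = NA)
  }, character(1))
  df <- data.frame(contig = verdicts$contig, pos = verdicts$pos,
                   ref = verdicts$ref, alt = verdicts$alt,
                   sample = paste(verdicts$individual, verdicts$tissue, sep = "_"),
                   verdict = ifelse(verdicts$passed, "pass", "fail"),
                   reason = verdicts$reason, values_used = vals,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
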