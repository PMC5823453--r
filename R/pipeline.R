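#' Run the end-to-end editome discovery pipeline
#'
#' Executes the full discovery cascade on a study directory: per-sample
#' variant loading, known-SNP subtraction, quality/allele/context filters,
#' strand-aware mismatch classification, recurrence across individuals,
#' cluster detection and extension, annotation, tissue statistics, the
#' neighbour-preference matrix and (optionally) flank validation. Reports
#' are written as TSV plus a JSON run manifest.
#'
#' @param study_dir directory containing `genome.fa`, `genes.gff3`,
#'   `repeats.bed` (optional), `known_snps.vcf` (optional), `meta.tsv` and
#'   the per-sample VCFs it references (the layout written by
#'   [simulate_study()]). Individual paths can be overridden.
#' @param out_dir output directory (created).
#' @param config a [threshold_config()].
#' @param genome_path,gff_path,repeats_path,known_snps_path,meta_path
#'   optional explicit input paths overriding the `study_dir` layout.
#' @param tpm_path optional TPM matrix TSV (genes x tissues) for the
#'   deaminase-expression correlation.
#' @param adar_genes gene ids in the TPM table whose summed expression is
#'   correlated with per-tissue editing counts.
#' @param est_fasta optional reference FASTA for flank validation.
#' @param skip_validation skip the validation stage even if `est_fasta`
#'   is given.
#' @param verbose log stage progress to stderr.
#' @return (invisibly) a list with `sites` (high-confidence annotated site
#'   table), `extended`, `clusters`, `spectrum_raw`, `spectrum_final`,
#'   `pfm`, `ledger`, `manifest`, and the paths written.
#' @export
run_pipeline <- function(study_dir, out_dir,
                         config = threshold_config(),
                         genome_path = file.path(study_dir, "genome.fa"),
                         gff_path = file.path(study_dir, "genes.gff3"),
                         repeats_path = file.path(study_dir, "repeats.bed"),
                         known_snps_path = file.path(study_dir, "known_snps.vcf"),
                         meta_path = file.path(study_dir, "meta.tsv"),
                         tpm_path = NULL, adar_genes = NULL,
                         est_fasta = NULL, skip_validation = FALSE,
                         verbose = TRUE) {
  t0 <- Sys.time()
  log_msg <- function(...) if (verbose) message(sprintf(...))
  for (p in c(genome_path, gff_path, meta_path))
    if (!file.exists(p)) stop("input stage: unreadable input: ", p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_msg("[load] reading reference inputs")
  genome <- read_genome(genome_path)
  gms <- read_gene_models(gff_path)
  repeats <- if (file.exists(repeats_path)) read_repeats(repeats_path) else NULL
  known <- if (file.exists(known_snps_path)) read_known_snps(known_snps_path) else NULL
  meta <- read_sample_sheet(meta_path)

  log_msg("[variants] reading %d sample VCFs", nrow(meta))
  obs <- lapply(seq_len(nrow(meta)), function(i) {
    if (!file.exists(meta$vcf_path[i]))
      stop("variants stage: unreadable input: ", meta$vcf_path[i])
    read_variants(meta$vcf_path[i], meta$individual_id[i], meta$tissue[i])
  })
  variants <- do.call(rbind, obs)
  n_input <- nrow(variants)

  log_msg("[cascade] filtering %d observations", n_input)
  cas <- run_cascade(variants, genome, gms, config, known_snps = known)
  stopifnot(sum(cas$ledger) + nrow(cas$passed) == n_input)

  # relaxed pool for cluster extension: survivors of known-SNP subtraction
  # and the GATK-style quality checks only
  quality_reasons <- c("known_snp", "hrun", "low_depth", "low_mq", "low_qd",
                       "mqranksum", "readposranksum")
  pool <- cas$verdicts[!cas$verdicts$reason %in% quality_reasons, , drop = FALSE]

  log_msg("[classify] strand-aware mismatch classification")
  pool <- classify_mismatch(pool, gms, flank = config$gene_flank)
  candidates <- pool[pool$passed, , drop = FALSE]

  log_msg("[recurrence] %d passing observations", nrow(candidates))
  sites <- recurrence_filter(candidates, config)

  spectrum_raw <- mismatch_spectrum(
    classify_mismatch(cas$verdicts[!cas$verdicts$reason %in% "known_snp", ,
                                   drop = FALSE],
                      gms, flank = config$gene_flank))
  spectrum_final <- mismatch_spectrum(sites)

  log_msg("[clusters] %d high-confidence sites", nrow(sites))
  ag_sites <- sites[sites$mismatch_class == "A>G", , drop = FALSE]
  cl <- detect_clusters(ag_sites, config)
  extended <- extend_sites(sites, pool, config)
  ext_ag <- extended[extended$mismatch_class %in% "A>G", , drop = FALSE]
  all_ag <- rbind(
    data.frame(contig = ag_sites$contig, pos = ag_sites$pos,
               origin = rep("high_confidence", nrow(ag_sites)),
               stringsAsFactors = FALSE),
    data.frame(contig = ext_ag$contig, pos = ext_ag$pos,
               origin = rep("extended", nrow(ext_ag)),
               stringsAsFactors = FALSE))
  cl_ext <- detect_clusters(all_ag, config)

  log_msg("[annotate] region / consequence / repeats")
  sites <- annotate_sites(sites, gms, genome, repeats, config)
  cl_assign <- detect_clusters(sites, config)$assignment
  sites$cluster_id <- cl_assign$cluster_id

  tissues <- sort(unique(meta$tissue))
  per_tissue <- vapply(tissues, function(t)
    sum(vapply(tissue_sets(sites), function(s) t %in% s, logical(1))),
    integer(1))
  specific <- vapply(tissues, function(t) {
    ts <- tissue_sets(sites)
    sum(lengths(ts) == 1L & vapply(ts, `[[`, character(1), 1L) == t)
  }, integer(1))
  ratio_tests <- tryCatch(tissue_ratio_tests(sites), error = function(e) NULL)

  pfm <- tryCatch(neighbor_pfm(sites, genome, config), error = function(e) NULL)

  validation <- NULL
  if (!is.null(est_fasta) && !skip_validation && nrow(ag_sites)) {
    log_msg("[validate] flank alignment against reference set")
    fl <- extract_flanks(ag_sites, genome, flank = config$uniq_flank)
    validation <- match_reference(stats::setNames(fl$seq,
                                                  paste0(ag_sites$contig, ":",
                                                         ag_sites$pos)),
                                  est_fasta, validation_profile("est"))
  }

  correlation <- NULL
  if (!is.null(tpm_path) && !is.null(adar_genes)) {
    tpm <- read_tpm_matrix(tpm_path)
    correlation <- tryCatch(
      expression_editing_correlation(tpm, stats::setNames(specific, tissues),
                                     adar_genes),
      error = function(e) NULL)
  }

  # ---- reports ----
  site_cols <- setdiff(names(sites), "support")
  paths <- list(
    sites = file.path(out_dir, "sites.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    extended = file.path(out_dir, "extended_sites.tsv"),
    spectrum = file.path(out_dir, "spectrum.tsv"),
    tissue_matrix = file.path(out_dir, "tissue_matrix.tsv"),
    ledger = file.path(out_dir, "filter_ledger.tsv"),
    pfm = file.path(out_dir, "pfm.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.table(sites[, site_cols], paths$sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_clusters(cl_ext$clusters, paths$clusters)
  ext_cols <- intersect(c("contig", "pos", "ref", "alt", "mismatch_class",
                          "strand", "origin"), names(extended))
  utils::write.table(extended[, ext_cols], paths$extended, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- spectrum_final
  sp$percent_raw <- spectrum_raw$percent[match(sp$class, spectrum_raw$class)]
  utils::write.table(sp, paths$spectrum, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tm <- site_tissue_matrix(sites, tissues)
  utils::write.table(data.frame(site = rownames(tm), tm, check.names = FALSE),
                     paths$tissue_matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_filter_ledger(cas$verdicts, paths$ledger)
  if (!is.null(pfm)) write_pfm(pfm, paths$pfm)
  if (!is.null(validation))
    utils::write.table(data.frame(site = rownames(validation), validation),
                       file.path(out_dir, "validation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  manifest <- list(
    tool = "rnaeditome",
    version = as.character(utils::packageVersion("rnaeditome")),
    config = unclass(config),
    inputs = lapply(
      Filter(file.exists,
             list(genome = genome_path, gff = gff_path, repeats = repeats_path,
                  known_snps = known_snps_path, meta = meta_path)),
      function(p) unname(tools::md5sum(p))),
    counts = list(
      observations = n_input,
      rejected = as.list(cas$ledger[cas$ledger > 0]),
      cascade_passed = nrow(cas$passed),
      pool = nrow(pool),
      high_confidence_sites = nrow(sites),
      a_to_i_high_confidence = nrow(ag_sites),
      extended_added = nrow(extended),
      clusters = nrow(cl_ext$clusters),
      per_tissue = as.list(stats::setNames(per_tissue, tissues)),
      tissue_specific = as.list(stats::setNames(specific, tissues))),
    a_to_i_fraction = list(
      raw = attr(spectrum_raw, "a_to_i_fraction"),
      high_confidence = attr(spectrum_final, "a_to_i_fraction"),
      extended_added = attr(extended, "a_to_i_fraction")),
    correlation = correlation,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  log_msg("[done] %d high-confidence sites, %d extended, %.1fs",
          nrow(sites), nrow(extended), manifest$runtime_sec)

  invisible(list(sites = sites, extended = extended,
                 clusters = cl_ext$clusters, cluster_detail = cl,
                 spectrum_raw = spectrum_raw, spectrum_final = spectrum_final,
                 per_tissue = stats::setNames(per_tissue, tissues),
                 tissue_specific = stats::setNames(specific, tissues),
                 ratio_tests = ratio_tests, pfm = pfm,
                 validation = validation, correlation = correlation,
                 ledger = cas$ledger, verdicts = cas$verdicts, pool = pool,
                 manifest = manifest, paths = paths))
}
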