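#' Read per-sample variant observations from a VCF
#'
#' Produces one observation per ALT allele per record. Indels, MNVs and
#' symbolic alleles are skipped; records lacking both AD and DP genotype
#' fields are skipped (no editing ratio can be computed). GATK site
#' annotations (HRun, MQ, QD, MQRankSum, ReadPosRankSum) are lifted from the
#' INFO column when present, `NA` otherwise.
#'
#' @param path VCF (v4.x) file, uncompressed or bgzipped.
#' @param individual,tissue sample metadata attached to every observation.
#' @return a data.frame of variant observations with columns `contig`,
#'   `pos`, `ref`, `alt`, `total_depth`, `alt_depth`, `genotype` (`het`,
#'   `hom_alt`, `hom_ref`), `multi_allelic`, `hrun`, `mq`, `qd`,
#'   `mq_rank_sum`, `read_pos_rank_sum`, `individual`, `tissue`. The counts
#'   of skipped records are in `attr(x, "skipped")`.
#' @export
read_variants <- function(path, individual = NA_character_, tissue = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  empty <- variant_frame()
  if (n == 0L) return(empty)
  fix <- v@fix
  gt <- if (ncol(v@gt) >= 2L) vcfR::extract.gt(v, element = "GT")[, 1L] else rep(NA_character_, n)
  ad <- if (ncol(v@gt) >= 2L) vcfR::extract.gt(v, element = "AD")[, 1L] else rep(NA_character_, n)
  dp <- if (ncol(v@gt) >= 2L) suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1L])) else rep(NA_integer_, n)
  info_num <- function(key) suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  hrun <- info_num("HRun"); mq <- info_num("MQ"); qd <- info_num("QD")
  mqrs <- info_num("MQRankSum"); rprs <- info_num("ReadPosRankSum")

  skipped <- c(indel_mnv = 0L, missing_depth = 0L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    snv_alts <- alts[nchar(alts) == 1L & alts %in% c("A", "C", "G", "T")]
    if (nchar(ref) != 1L || !length(snv_alts) || length(snv_alts) < length(alts)) {
      if (nchar(ref) != 1L || length(snv_alts) < length(alts)) {
        skipped["indel_mnv"] <- skipped["indel_mnv"] + 1L
        if (nchar(ref) != 1L || !length(snv_alts)) next
      }
    }
    ad_i <- suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    if ((is.na(ad[i]) || !length(ad_i)) && is.na(dp[i])) {
      skipped["missing_depth"] <- skipped["missing_depth"] + 1L
      next
    }
    total <- if (!is.na(dp[i])) dp[i] else sum(ad_i, na.rm = TRUE)
    geno <- parse_genotype(gt[i])
    alt_idx <- match(snv_alts, alts)
    rows[[i]] <- data.frame(
      contig = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
      ref = ref, alt = snv_alts,
      total_depth = total,
      alt_depth = if (!is.na(ad[i]) && length(ad_i) > max(alt_idx))
        ad_i[alt_idx + 1L] else NA_integer_,
      genotype = geno, multi_allelic = length(alts) > 1L,
      hrun = hrun[i], mq = mq[i], qd = qd[i],
      mq_rank_sum = mqrs[i], read_pos_rank_sum = rprs[i],
      individual = individual, tissue = tissue,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  if (any(!is.na(out$alt_depth) & out$alt_depth > out$total_depth))
    stop("alt depth exceeds total depth in ", path)
  attr(out, "skipped") <- skipped
  out
}

variant_frame <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), total_depth = integer(), alt_depth = integer(),
             genotype = character(), multi_allelic = logical(),
             hrun = numeric(), mq = numeric(), qd = numeric(),
             mq_rank_sum = numeric(), read_pos_rank_sum = numeric(),
             individual = character(), tissue = character(),
             stringsAsFactors = FALSE)
}

parse_genotype <- function(gt) {
  if (is.na(gt)) return(NA_character_)
  al <- strsplit(gt, "[/|]")[[1]]
  al <- al[al != "."]
  if (!length(al)) return(NA_character_)
  if (all(al == "0")) "hom_ref"
  else if (all(al == al[1]) && al[1] != "0") "hom_alt"
  else "het"
}

#' Read the sample metadata sheet
#'
#' @param path TSV with columns `individual_id`, `tissue`, `vcf_path`.
#' @param base_dir optional directory against which relative `vcf_path`
#'   entries are resolved.
#' @return a data.frame.
#' @export
read_sample_sheet <- function(path, base_dir = dirname(path)) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "tissue", "vcf_path")
  if (!all(need %in% names(meta)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", meta$vcf_path)
  meta$vcf_path[rel] <- file.path(base_dir, meta$vcf_path[rel])
  meta
}

#' Load known-SNP positions from a VCF
#' @param path VCF of known SNPs.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt` (first alt).
#' @export
read_known_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L)
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character()))
  data.frame(contig = v@fix[, "CHROM"], pos = as.integer(v@fix[, "POS"]),
             ref = v@fix[, "REF"],
             alt = sub(",.*$", "", v@fix[, "ALT"]),
             stringsAsFactors = FALSE)
}

#' Remove observations at known-SNP positions
#'
#' By default matching is by position only (allele-agnostic): any
#' observation whose (contig, pos) coincides with a known SNP record is
#' dropped. Set `match_alleles = TRUE` to require the ALT allele to match
#' as well.
#'
#' @param variants a variant observation data.frame ([read_variants()]).
#' @param known_snps data.frame with `contig`, `pos` (and `alt` when
#'   allele-aware), or a path to a known-SNP VCF.
#' @param match_alleles require ALT agreement, not just position.
#' @return the subset of `variants` not matching any known SNP.
#' @export
subtract_known_snps <- function(variants, known_snps, match_alleles = FALSE) {
  if (is.character(known_snps)) known_snps <- read_known_snps(known_snps)
  if (!nrow(known_snps) || !nrow(variants)) return(variants)
  if (match_alleles) {
    key_v <- paste(variants$contig, variants$pos, variants$alt)
    key_s <- paste(known_snps$contig, known_snps$pos, known_snps$alt)
  } else {
    key_v <- paste(variants$contig, variants$pos)
    key_s <- paste(known_snps$contig, known_snps$pos)
  }
  out <- variants[!key_v %in% key_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Editing ratio of variant observations
#'
#' The fraction of reads carrying the edited (alternative) base,
#' `alt_depth / total_depth`.
#'
#' @param variants data.frame with `alt_depth` and `total_depth` columns.
#' @return numeric vector in `[0, 1]`.
#' @export
editing_ratio <- function(variants) {
  if (any(is.na(variants$total_depth) | variants$total_depth <= 0))
    stop("editing ratio undefined at zero total depth")
  variants$alt_depth / variants$total_depth
}
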