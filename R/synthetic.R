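#' Configuration of the synthetic editing study
#'
#' Defines a miniature strand-specific RNA-seq study with the structure the
#' pipeline assumes: three individuals by nine tissues, clustered A>G
#' editing sites enriched in SINE-like repeats with the T(-1)/G(+1)
#' sequence-context bias, plus germline SNPs (known and private) and
#' singleton error SNVs across all twelve mismatch classes.
#'
#' @param seed RNG seed; runs are reproducible bit-for-bit.
#' @param genome_len single-contig genome length (default 1 Mb).
#' @param n_genes number of non-overlapping genes (default 30).
#' @param n_repeats SINE-like repeat copies inserted (default 200), each
#'   `repeat_len` bp diverged from one consensus by `repeat_divergence`
#'   substitutions per base; `inverted_frac` of them in inverted
#'   orientation.
#' @param repeat_len,repeat_divergence,inverted_frac see `n_repeats`.
#' @param n_edit_sites planted A-to-I sites (default 120).
#' @param frac_in_repeats fraction of edit clusters inside repeats (0.8).
#' @param cluster_mean mean cluster size of the geometric size distribution.
#' @param ratio_shape,ratio_range Beta(2,4) editing-ratio distribution
#'   truncated to `[0.10, 0.95]`.
#' @param depth_mean,depth_floor Poisson read depth (mean 40, floor 10).
#' @param context_bias target marginal probabilities of T at -1 and G at +1
#'   of planted sites (0.5 each, vs the 0.25 background).
#' @param n_error_snvs singleton error SNVs (300), present in exactly one
#'   sample at low ratio.
#' @param n_known_snps germline SNPs present in every individual and listed
#'   in the known-SNP VCF (400).
#' @param n_private_snps unlisted single-individual het SNPs (60) — the
#'   pipeline's acknowledged confound.
#' @param tissues tissue names (default nine body tissues).
#' @param individuals individual ids (default three).
#' @param tissue_presence per-site probability that a tissue expresses the
#'   edited transcript (0.6).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             genome_len = 1000000L,
                             n_genes = 30L,
                             n_repeats = 200L,
                             repeat_len = 150L,
                             repeat_divergence = 0.15,
                             inverted_frac = 0.3,
                             n_edit_sites = 120L,
                             frac_in_repeats = 0.8,
                             cluster_mean = 3,
                             ratio_shape = c(2, 4),
                             ratio_range = c(0.10, 0.95),
                             depth_mean = 40,
                             depth_floor = 10L,
                             context_bias = c(t_m1 = 0.5, g_p1 = 0.5),
                             n_error_snvs = 300L,
                             n_known_snps = 400L,
                             n_private_snps = 60L,
                             tissues = c("brain", "colon", "heart", "kidney",
                                         "liver", "lung", "muscle", "spleen",
                                         "testes"),
                             individuals = c("bull1", "bull2", "bull3"),
                             tissue_presence = 0.6) {
  cfg <- as.list(environment())
  probs <- c(cfg$frac_in_repeats, cfg$inverted_frac, cfg$tissue_presence,
             cfg$repeat_divergence, unname(cfg$context_bias))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$genome_len < cfg$n_genes * 2000L)
    stop("genome too short for the requested gene count")
  structure(cfg, class = "synthetic_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate the synthetic reference: genome, gene models, repeats, SNPs
#'
#' Genes with exon/intron/CDS/UTR structure on both strands are laid out in
#' equal slots with wide intergenic margins; SINE-like repeat copies
#' (diverged from a single consensus, a fraction inverted) are written into
#' introns and intergenic space; known-SNP positions are drawn genome-wide.
#' Deterministic under `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `genome` (`DNAStringSet`), `gene_models`
#'   ([gene_model_set()]), `repeats` (`GRanges`), `known_snps` (data.frame),
#'   `config`.
#' @export
generate_reference <- function(config = synthetic_config()) {
  set.seed(config$seed)
  L <- config$genome_len
  contig <- "chr1"
  gchars <- sample(c("A", "C", "G", "T"), L, TRUE)

  # --- genes in equal slots with margins ---
  slot <- L %/% config$n_genes
  margin <- min(6000L, slot %/% 4L)
  if (slot - 2L * margin < 1200L)
    stop("infeasible packing: gene slots too small for gene structure")
  genes <- transcripts <- feats <- list()
  biotype_pool <- rep("protein_coding", config$n_genes)
  n_pseudo <- max(1L, round(0.1 * config$n_genes))
  n_other <- max(1L, round(0.07 * config$n_genes))
  biotype_pool[sample(config$n_genes, n_pseudo + n_other)] <-
    c(rep("pseudogene", n_pseudo), rep("other", n_other))
  for (gi in seq_len(config$n_genes)) {
    slot_start <- (gi - 1L) * slot + 1L
    avail <- slot - 2L * margin
    glen <- round(stats::runif(1, 0.5, 0.8) * avail)
    gstart <- slot_start + margin + sample.int(avail - glen, 1L)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(3:6, 1L)
    ex_len <- sample(150:300, n_ex, TRUE)
    min_intron <- 400L
    while (sum(ex_len) + (n_ex - 1L) * min_intron > glen) {
      n_ex <- max(2L, n_ex - 1L)
      ex_len <- sample(150:300, n_ex, TRUE)
    }
    spare <- glen - sum(ex_len) - (n_ex - 1L) * min_intron
    intron_len <- min_intron + as.integer(round(
      spare * diff(c(0, sort(stats::runif(n_ex - 2L)), 1))))
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    cur <- gstart
    for (k in seq_len(n_ex)) {
      ex_start[k] <- cur
      ex_end[k] <- cur + ex_len[k] - 1L
      cur <- ex_end[k] + if (k < n_ex) intron_len[k] else 0L
      if (k < n_ex) cur <- cur + 1L
    }
    gend <- ex_end[n_ex]
    gid <- sprintf("G%03d", gi)
    tid <- paste0(gid, ".t1")
    bt <- biotype_pool[gi]
    genes[[gi]] <- data.frame(gene_id = gid, symbol = paste0("SYN", gi),
                              biotype = bt, contig = contig, strand = strand,
                              start = gstart, end = gend,
                              stringsAsFactors = FALSE)
    transcripts[[gi]] <- data.frame(transcript_id = tid, gene_id = gid,
                                    stringsAsFactors = FALSE)
    fr <- data.frame(transcript_id = tid, type = "exon",
                     start = ex_start, end = ex_end, phase = NA_integer_,
                     stringsAsFactors = FALSE)
    if (bt == "protein_coding") {
      # carve UTRs from the terminal exons (coding order is strand-aware)
      u5 <- sample(50:120, 1L); u3 <- sample(50:120, 1L)
      cds_len <- sum(ex_len) - u5 - u3
      u3 <- u3 + cds_len %% 3L
      if (strand == "+") {
        cds_s <- ex_start; cds_e <- ex_end
        cds_s[1L] <- ex_start[1L] + u5
        cds_e[n_ex] <- ex_end[n_ex] - u3
        utr5 <- data.frame(transcript_id = tid, type = "utr5",
                           start = ex_start[1L], end = cds_s[1L] - 1L,
                           phase = NA_integer_, stringsAsFactors = FALSE)
        utr3 <- data.frame(transcript_id = tid, type = "utr3",
                           start = cds_e[n_ex] + 1L, end = ex_end[n_ex],
                           phase = NA_integer_, stringsAsFactors = FALSE)
        ord <- seq_len(n_ex)
      } else {
        cds_s <- ex_start; cds_e <- ex_end
        cds_e[n_ex] <- ex_end[n_ex] - u5
        cds_s[1L] <- ex_start[1L] + u3
        utr5 <- data.frame(transcript_id = tid, type = "utr5",
                           start = cds_e[n_ex] + 1L, end = ex_end[n_ex],
                           phase = NA_integer_, stringsAsFactors = FALSE)
        utr3 <- data.frame(transcript_id = tid, type = "utr3",
                           start = ex_start[1L], end = cds_s[1L] - 1L,
                           phase = NA_integer_, stringsAsFactors = FALSE)
        ord <- rev(seq_len(n_ex))
      }
      seg_len <- (cds_e - cds_s + 1L)[ord]
      phase <- as.integer((3L - cumsum(c(0L, seg_len[-n_ex])) %% 3L) %% 3L)
      cds <- data.frame(transcript_id = tid, type = "cds",
                        start = cds_s[ord], end = cds_e[ord], phase = phase,
                        stringsAsFactors = FALSE)
      fr <- rbind(fr, cds, utr5, utr3)
    }
    feats[[gi]] <- fr
  }
  genes <- do.call(rbind, genes)
  gms <- gene_model_set(genes, do.call(rbind, transcripts), do.call(rbind, feats))

  # --- repeats: diverged copies of one SINE-like consensus ---
  consensus <- rand_dna(config$repeat_len)
  exon_iv <- gms$features[gms$features$type == "exon", c("start", "end")]
  occupied <- IRanges::IRanges(exon_iv$start - 10L, exon_iv$end + 10L)
  rep_rows <- list()
  fam_pool <- function() {
    r <- stats::runif(1)
    if (r < 0.85) c("SINE", "Bov-tA") else if (r < 0.95) c("LINE", "L1")
    else c("DNA", "hAT")
  }
  attempts <- 0L
  while (length(rep_rows) < config$n_repeats && attempts < config$n_repeats * 60L) {
    attempts <- attempts + 1L
    s <- sample.int(L - config$repeat_len - 20L, 1L) + 10L
    iv <- IRanges::IRanges(s, s + config$repeat_len - 1L)
    if (IRanges::countOverlaps(iv, occupied) > 0L) next
    occupied <- c(occupied, IRanges::IRanges(s - 10L, s + config$repeat_len + 9L))
    copy <- mutate_seq(consensus, config$repeat_divergence)
    inverted <- stats::runif(1) < config$inverted_frac
    if (inverted) copy <- revcomp(copy)
    gchars[s:(s + config$repeat_len - 1L)] <- strsplit(copy, "")[[1]]
    fam <- fam_pool()
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      start = s, end = s + config$repeat_len - 1L,
      strand = if (inverted) "-" else "+",
      repeat_class = fam[1L], family = fam[2L], stringsAsFactors = FALSE)
  }
  if (length(rep_rows) < config$n_repeats)
    stop("infeasible packing: could not place all repeats")
  rp <- do.call(rbind, rep_rows)
  repeats <- GenomicRanges::GRanges(contig, IRanges::IRanges(rp$start, rp$end),
                                    strand = rp$strand,
                                    repeat_class = rp$repeat_class,
                                    family = rp$family)

  # --- known SNPs, genome-wide ---
  snp_pos <- sort(sample.int(L, config$n_known_snps))
  known_snps <- data.frame(
    contig = contig, pos = snp_pos, ref = gchars[snp_pos],
    alt = vapply(gchars[snp_pos],
                 function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                 character(1)),
    zygosity = sample(c("het", "hom"), config$n_known_snps, TRUE,
                      prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(paste(gchars, collapse = ""))
  names(genome) <- contig
  list(genome = genome, gene_models = gms, repeats = repeats,
       known_snps = known_snps, config = config)
}

#' Plant variants into the synthetic study
#'
#' Plants clustered A>G editing sites (transcribed-strand adenosines inside
#' genes or their flanks, preferentially in repeats and with the T(-1)/G(+1)
#' context bias), singleton error SNVs, known germline SNPs (every
#' individual, listed) and private SNPs (one individual, unlisted). Read
#' support is sampled per sample as Poisson depth and binomial alternative
#' counts at the site's true ratio. Deterministic under `config$seed`.
#'
#' @param reference output of [generate_reference()].
#' @param config the same [synthetic_config()].
#' @return list with `truth` (the planted-site ledger), `samples` (named
#'   list of per-sample VCF row data.frames), `sample_meta` (individual,
#'   tissue, vcf name).
#' @export
plant_variants <- function(reference, config = reference$config) {
  set.seed(config$seed + 1L)
  gms <- reference$gene_models
  genome <- reference$genome
  contig <- names(genome)[1]
  gchars <- strsplit(as.character(genome[[contig]]), "")[[1]]
  L <- length(gchars)

  # masks of positions to avoid when planting edits
  ssrs <- find_ssrs(as.character(genome[[contig]]))
  bad <- logical(L)
  if (nrow(ssrs))
    for (k in seq_len(nrow(ssrs)))
      bad[max(1, ssrs$start[k] - 3L):min(L, ssrs$end[k] + 3L)] <- TRUE
  introns <- transcript_introns(gms)
  if (nrow(introns))
    for (k in seq_len(nrow(introns))) {
      s <- introns$start[k]; e <- introns$end[k]; fl <- 5L
      bad[s:min(e, s + fl - 1L)] <- TRUE
      bad[max(s, e - fl + 1L):e] <- TRUE
    }
  bad[reference$known_snps$pos] <- TRUE

  rep_start <- GenomicRanges::start(reference$repeats)
  rep_end <- GenomicRanges::end(reference$repeats)
  in_repeat <- logical(L)
  for (k in seq_along(rep_start)) in_repeat[rep_start[k]:rep_end[k]] <- TRUE

  # candidate edit positions per gene: transcribed-strand A, within the gene
  # body or a 2 kb flank, not masked; context-bias weights favour T(-1)/G(+1)
  genes <- gms$genes
  cand <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    lo <- max(2L, g$start - 2000L); hi <- min(L - 1L, g$end + 2000L)
    pos <- lo:hi
    want <- if (g$strand == "+") "A" else "T"
    pos <- pos[gchars[pos] == want & !bad[pos]]
    if (!length(pos)) next
    # exclude homopolymer contexts that would fail HRun (alt G on +, C on -)
    altg <- if (g$strand == "+") "G" else "C"
    hr_ok <- vapply(pos, function(p) {
      run <- 0L; i <- p - 1L
      while (i >= 1L && gchars[i] == altg) { run <- run + 1L; i <- i - 1L }
      r2 <- 0L; i <- p + 1L
      while (i <= L && gchars[i] == altg) { r2 <- r2 + 1L; i <- i + 1L }
      max(run, r2) <= 5L
    }, logical(1))
    pos <- pos[hr_ok]
    if (!length(pos)) next
    # weights on the transcribed strand: T 5' and G 3' of the edited A
    if (g$strand == "+") {
      w <- ifelse(gchars[pos - 1L] == "T", 3, 1) *
        ifelse(gchars[pos + 1L] == "G", 3, 1)
    } else {
      w <- ifelse(gchars[pos + 1L] == "A", 3, 1) *
        ifelse(gchars[pos - 1L] == "C", 3, 1)
    }
    cand[[g$gene_id]] <- data.frame(pos = pos, w = w, strand = g$strand,
                                    in_rep = in_repeat[pos],
                                    stringsAsFactors = FALSE)
  }

  # cluster sizes: 1 + geometric, mean cluster_mean
  sizes <- integer(0)
  while (sum(sizes) < config$n_edit_sites)
    sizes <- c(sizes, 1L + stats::rgeom(1L, prob = 1 / config$cluster_mean))
  sizes[length(sizes)] <- sizes[length(sizes)] -
    (sum(sizes) - config$n_edit_sites)
  sizes <- sizes[sizes > 0L]

  used <- logical(L)
  truth_rows <- list()
  cluster_id <- 0L
  for (s in sizes) {
    cluster_id <- cluster_id + 1L
    want_rep <- stats::runif(1) < config$frac_in_repeats
    placed <- NULL
    for (try in 1:80) {
      gid <- sample(names(cand), 1L)
      cc <- cand[[gid]]
      cc <- cc[!used[cc$pos] & cc$in_rep == want_rep, , drop = FALSE]
      if (nrow(cc) < s) next
      anchor <- sample.int(nrow(cc), 1L, prob = cc$w)
      win <- cc[cc$pos >= cc$pos[anchor] &
                  cc$pos <= cc$pos[anchor] + 60L * s, , drop = FALSE]
      if (nrow(win) < s) next
      pick <- sort(win$pos[sample.int(nrow(win), s, prob = win$w)])
      if (s > 1L && any(diff(pick) > 100L)) next
      placed <- list(pos = pick, strand = cc$strand[1L])
      break
    }
    if (is.null(placed)) stop("could not place edit cluster of size ", s)
    used[placed$pos] <- TRUE
    for (p in placed$pos) {
      inds <- sample(config$individuals,
                     sample(2:length(config$individuals), 1L))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        contig = contig, pos = p, class = "edit",
        ref = gchars[p], alt = if (placed$strand == "+") "G" else "C",
        strand = placed$strand,
        true_ratio = trunc_beta(1L, config$ratio_shape, config$ratio_range),
        individuals = paste(sort(inds), collapse = ","),
        tissues = paste(sort(sample_tissues(config)), collapse = ","),
        in_repeat = in_repeat[p], cluster_id = cluster_id,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)

  # error SNVs: one sample each, low ratio
  free <- which(!used & !bad)
  err_pos <- sample(free, config$n_error_snvs)
  used[err_pos] <- TRUE
  err <- data.frame(
    contig = contig, pos = err_pos, class = "error", ref = gchars[err_pos],
    alt = vapply(gchars[err_pos],
                 function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                 character(1)),
    strand = NA_character_,
    true_ratio = stats::runif(config$n_error_snvs, 0.10, 0.25),
    individuals = sample(config$individuals, config$n_error_snvs, TRUE),
    tissues = sample(config$tissues, config$n_error_snvs, TRUE),
    in_repeat = in_repeat[err_pos], cluster_id = NA_integer_,
    stringsAsFactors = FALSE)

  # private SNPs: one individual (all its tissues), het, unlisted
  free <- which(!used & !bad)
  priv_pos <- sample(free, config$n_private_snps)
  used[priv_pos] <- TRUE
  priv <- data.frame(
    contig = contig, pos = priv_pos, class = "private_snp",
    ref = gchars[priv_pos],
    alt = vapply(gchars[priv_pos],
                 function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                 character(1)),
    strand = NA_character_, true_ratio = 0.5,
    individuals = sample(config$individuals, config$n_private_snps, TRUE),
    tissues = rep(paste(sort(config$tissues), collapse = ","),
                  config$n_private_snps),
    in_repeat = in_repeat[priv_pos], cluster_id = NA_integer_,
    stringsAsFactors = FALSE)

  ks <- reference$known_snps
  known <- data.frame(
    contig = contig, pos = ks$pos, class = "known_snp", ref = ks$ref,
    alt = ks$alt, strand = NA_character_,
    true_ratio = ifelse(ks$zygosity == "hom", 1.0, 0.5),
    individuals = rep(paste(sort(config$individuals), collapse = ","),
                      nrow(ks)),
    tissues = rep(paste(sort(config$tissues), collapse = ","), nrow(ks)),
    in_repeat = in_repeat[ks$pos], cluster_id = NA_integer_,
    stringsAsFactors = FALSE)

  truth <- rbind(truth, err, priv, known)
  truth <- truth[order(truth$pos), ]
  rownames(truth) <- NULL
  stopifnot(!anyDuplicated(truth$pos))

  # per-sample VCF rows
  samples <- list()
  meta <- list()
  ind_sets <- strsplit(truth$individuals, ",", fixed = TRUE)
  tis_sets <- strsplit(truth$tissues, ",", fixed = TRUE)
  for (ind in config$individuals) {
    for (tis in config$tissues) {
      present <- vapply(ind_sets, function(s) ind %in% s, logical(1)) &
        vapply(tis_sets, function(s) tis %in% s, logical(1))
      tr <- truth[present, , drop = FALSE]
      n <- nrow(tr)
      depth <- pmax(config$depth_floor, stats::rpois(n, config$depth_mean))
      altd <- stats::rbinom(n, depth, tr$true_ratio)
      keep <- altd > 0L
      rows <- data.frame(
        contig = tr$contig[keep], pos = tr$pos[keep], ref = tr$ref[keep],
        alt = tr$alt[keep], dp = depth[keep], ad_alt = altd[keep],
        gt = ifelse(altd[keep] == depth[keep], "1/1", "0/1"),
        stringsAsFactors = FALSE)
      nm <- paste0(ind, "_", tis)
      samples[[nm]] <- rows[order(rows$pos), ]
      meta[[nm]] <- data.frame(individual_id = ind, tissue = tis,
                               vcf_path = file.path("samples", paste0(nm, ".vcf")),
                               stringsAsFactors = FALSE)
    }
  }
  list(truth = truth, samples = samples,
       sample_meta = do.call(rbind, meta))
}

trunc_beta <- function(n, shape, range) {
  x <- stats::rbeta(n, shape[1], shape[2])
  while (any(out <- x < range[1] | x > range[2]))
    x[out] <- stats::rbeta(sum(out), shape[1], shape[2])
  x
}

sample_tissues <- function(config) {
  t <- config$tissues[stats::runif(length(config$tissues)) < config$tissue_presence]
  if (!length(t)) t <- sample(config$tissues, 1L)
  t
}

write_simple_vcf <- function(rows, path, sample_name = "SAMPLE",
                             sites_only = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read pos rank sum\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  if (sites_only) {
    hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                    rows$contig, rows$pos, rows$ref, rows$alt)
  } else {
    hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                         sample_name))
    info <- "MQ=60.00;QD=25.00;MQRankSum=0.00;ReadPosRankSum=0.00"
    body <- sprintf("%s\t%d\t.\t%s\t%s\t100\t.\t%s\tGT:AD:DP\t%s:%d,%d:%d",
                    rows$contig, rows$pos, rows$ref, rows$alt, info,
                    rows$gt, rows$dp - rows$ad_alt, rows$ad_alt, rows$dp)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a complete synthetic study to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `repeats.bed`, `known_snps.vcf`,
#' `samples/<individual>_<tissue>.vcf`, `meta.tsv` and `truth.tsv`.
#' @param reference output of [generate_reference()].
#' @param planted output of [plant_variants()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(reference, planted, dir) {
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  write_genome(reference$genome, file.path(dir, "genome.fa"))
  write_gene_models_gff3(reference$gene_models, file.path(dir, "genes.gff3"))
  write_repeats_bed(reference$repeats, file.path(dir, "repeats.bed"))
  write_simple_vcf(reference$known_snps, file.path(dir, "known_snps.vcf"),
                   sites_only = TRUE)
  for (nm in names(planted$samples))
    write_simple_vcf(planted$samples[[nm]],
                     file.path(dir, "samples", paste0(nm, ".vcf")),
                     sample_name = nm)
  utils::write.table(planted$sample_meta, file.path(dir, "meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(planted$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate and write a synthetic study in one call
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @return list with `reference`, `planted`, `dir` (invisibly).
#' @export
simulate_study <- function(config = synthetic_config(), dir) {
  reference <- generate_reference(config)
  planted <- plant_variants(reference, config)
  write_synthetic_study(reference, planted, dir)
  invisible(list(reference = reference, planted = planted, dir = dir))
}

#' Score pipeline calls against the planted truth
#'
#' True positives are called positions planted as edits; false positives
#' are broken down by the truth class at the called position (`error`,
#' `private_snp`, `known_snp`, `none`).
#'
#' @param calls data.frame with `contig` and `pos` (the called editome).
#' @param truth the planted-site ledger (`truth` element of
#'   [plant_variants()] or `truth.tsv` re-read).
#' @return list with `precision` (`NA` when nothing is called), `recall`,
#'   `f1`, `tp`, `fn`, `fp_breakdown` (named counts).
#' @export
evaluate_recovery <- function(calls, truth) {
  edits <- truth[truth$class == "edit", , drop = FALSE]
  call_key <- unique(paste(calls$contig, calls$pos))
  edit_key <- paste(edits$contig, edits$pos)
  tp <- sum(call_key %in% edit_key)
  fp_keys <- setdiff(call_key, edit_key)
  truth_key <- paste(truth$contig, truth$pos)
  fp_class <- truth$class[match(fp_keys, truth_key)]
  fp_class[is.na(fp_class)] <- "none"
  fp_breakdown <- table(factor(fp_class,
                               levels = c("error", "private_snp",
                                          "known_snp", "none")))
  n_called <- length(call_key)
  precision <- if (n_called) tp / n_called else NA_real_
  recall <- if (nrow(edits)) tp / nrow(edits) else NA_real_
  f1 <- if (!is.na(precision) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fn = nrow(edits) - tp, fp_breakdown = c(fp_breakdown))
}
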