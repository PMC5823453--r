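test_that("quality thresholds are strict inequalities at every boundary", {
  cfg <- threshold_config()
  # all six annotations exactly at the printed boundary -> pass
  at <- vrow(hrun = 5, total_depth = 10L, mq = 40, qd = 2,
             mq_rank_sum = -12.5, read_pos_rank_sum = -8)
  expect_true(apply_quality_filters(at, cfg)$passed)
  # one past each boundary -> fail with that reason
  cases <- list(
    list(vrow(hrun = 6), "hrun"),
    list(vrow(total_depth = 9L), "low_depth"),
    list(vrow(mq = 39.99), "low_mq"),
    list(vrow(qd = 1.99), "low_qd"),
    list(vrow(mq_rank_sum = -12.51), "mqranksum"),
    list(vrow(read_pos_rank_sum = -8.01), "readposranksum"))
  for (cs in cases) {
    verdict <- apply_quality_filters(cs[[1]], cfg)
    expect_false(verdict$passed)
    expect_equal(verdict$reason, cs[[2]])
  }
  # the documented first-failure order: HRun outranks depth
  both <- vrow(hrun = 6, total_depth = 5L, mq = 60)
  expect_equal(apply_quality_filters(both, cfg)$reason, "hrun")
  # missing annotations pass
  none <- vrow(hrun = NA, mq = NA, qd = NA, mq_rank_sum = NA,
               read_pos_rank_sum = NA)
  expect_true(apply_quality_filters(none, cfg)$passed)
})

test_that("random annotation vectors match a literal re-evaluation oracle", {
  set.seed(3)
  n <- 400L
  v <- vrow()[rep(1, n), ]
  v$hrun <- sample(0:8, n, TRUE)
  v$total_depth <- sample(5:60, n, TRUE)
  v$alt_depth <- pmin(v$total_depth, sample(0:30, n, TRUE))
  v$mq <- runif(n, 20, 70)
  v$qd <- runif(n, 0, 10)
  v$mq_rank_sum <- runif(n, -20, 5)
  v$read_pos_rank_sum <- runif(n, -12, 5)
  got <- apply_quality_filters(v)
  # independent oracle: the six inequalities, literally
  want <- !(v$hrun > 5 | v$total_depth < 10 | v$mq < 40 | v$qd < 2 |
              v$mq_rank_sum < -12.5 | v$read_pos_rank_sum < -8)
  expect_equal(got$passed, want)
})

test_that("allele filters fail in documented order with boundary semantics", {
  cfg <- threshold_config()
  expect_true(apply_allele_filters(
    vrow(total_depth = 10L, alt_depth = 3L), cfg)$passed)
  cases <- list(
    list(vrow(multi_allelic = TRUE, genotype = "hom_alt"), "multi_allelic"),
    list(vrow(genotype = "hom_alt"), "hom_alt"),
    list(vrow(total_depth = 9L, alt_depth = 3L), "low_depth"),
    list(vrow(total_depth = 30L, alt_depth = 2L), "few_alt_reads"),
    list(vrow(total_depth = 40L, alt_depth = 3L), "low_ratio"),  # 0.075
    list(vrow(total_depth = 20L, alt_depth = 20L), "full_ratio"))
  for (cs in cases) {
    verdict <- apply_allele_filters(cs[[1]], cfg)
    expect_false(verdict$passed)
    expect_equal(verdict$reason, cs[[2]])
  }
  # exactly 10% passes ("at least 10%")
  expect_true(apply_allele_filters(
    vrow(total_depth = 30L, alt_depth = 3L), cfg)$passed)
})

test_that("editing ratio is alt over total depth, undefined at zero depth", {
  expect_equal(editing_ratio(vrow(total_depth = 10L, alt_depth = 3L)), 0.3)
  expect_equal(editing_ratio(vrow(total_depth = 10L, alt_depth = 7L)), 0.7)
  expect_equal(editing_ratio(vrow(alt_depth = 0L)), 0)
  expect_error(editing_ratio(vrow(total_depth = 0L)), "zero total depth")
})

test_that("cascade assigns a single first-fail reason and balances counts", {
  set.seed(9)
  genome <- make_genome(c1 = rand_seq(20000))
  gms <- mini_gms()
  n <- 500L
  v <- vrow()[rep(1, n), ]
  v$pos <- sample(100:19900, n)
  v$ref <- substring(as.character(genome[["c1"]]), v$pos, v$pos)
  v$alt <- vapply(v$ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  v$total_depth <- sample(5:60, n, TRUE)
  v$alt_depth <- pmin(v$total_depth, sample(0:25, n, TRUE))
  v$genotype <- sample(c("het", "hom_alt"), n, TRUE, prob = c(0.9, 0.1))
  v$multi_allelic <- runif(n) < 0.05
  v$mq <- runif(n, 30, 70)
  rownames(v) <- NULL
  cfg <- threshold_config()
  res <- run_cascade(v, genome, gms, cfg)

  # bookkeeping: reason counts sum to rejected; one reason each
  expect_equal(sum(res$ledger) + nrow(res$passed), n)
  expect_true(all(res$verdicts$passed == (res$verdicts$reason == "none")))

  # pass-set equals the intersection of independently applied stage filters
  q_ok <- apply_quality_filters(v, cfg)$passed
  a_ok <- apply_allele_filters(v, cfg)$passed
  bid <- bidirectional_overlap(v$pos, v$contig, gms)
  ssrs <- find_ssrs(as.character(genome[["c1"]]), cfg)
  ssr_in <- in_ssr_zone(v$pos, ssrs, cfg)
  spl <- near_splice_junction(v$pos, v$contig, gms, cfg)
  want <- q_ok & a_ok & !bid & !ssr_in & !spl
  got <- res$verdicts$passed
  # uniqueness can only remove further sites (monotonicity of the cascade)
  expect_true(all(got <= want))
  res_nouniq <- run_cascade(v, genome, gms, cfg, skip_uniqueness = TRUE)
  expect_equal(res_nouniq$verdicts$passed, want)

  # all survivors sit in the legal ratio band [0.10, 1.0)
  ratio <- res$passed$alt_depth / res$passed$total_depth
  expect_true(all(ratio >= 0.10 & ratio < 1))

  # a variant failing depth inside an SSR reports only the first reason
  ssr1 <- ssrs[1, ]
  v2 <- vrow(pos = ssr1$start, total_depth = 5L, alt_depth = 2L)
  v2$ref <- substring(as.character(genome[["c1"]]), v2$pos, v2$pos)
  r2 <- run_cascade(v2, genome, gms, cfg, skip_uniqueness = TRUE)
  expect_equal(r2$verdicts$reason, "low_depth")
})

test_that("known-SNP stage runs first and writes a readable ledger", {
  genome <- make_genome(c1 = strrep("ACGT", 500))
  gms <- mini_gms()
  v <- rbind(vrow(pos = 101L, total_depth = 5L),  # also fails depth
             vrow(pos = 105L))
  v$ref <- substring(as.character(genome[["c1"]]), v$pos, v$pos)
  res <- run_cascade(v, genome, gms, known_snps = data.frame(contig = "c1",
                                                             pos = 101L),
                     skip_uniqueness = TRUE)
  expect_equal(res$verdicts$reason[1], "known_snp")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_filter_ledger(res$verdicts, tsv)
  led <- read.delim(tsv, quote = "")
  expect_equal(nrow(led), 2L)
  expect_true(all(c("reason", "values_used") %in% names(led)))
  expect_match(led$values_used[1], "\"dp\":5")
})
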