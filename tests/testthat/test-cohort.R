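# helper: classified candidate rows ready for recurrence grouping
crow <- function(pos, individual, tissue, cls = "A>G", ratio = 0.3) {
  data.frame(contig = "c1", pos = pos, ref = "A", alt = "G",
             strand = "+", strand_source = "gene", mismatch_class = cls,
             individual = individual, tissue = tissue,
             alt_depth = round(ratio * 40), total_depth = 40L,
             stringsAsFactors = FALSE)
}

test_that("recurrence keeps sites seen in two individuals, any tissue", {
  cand <- rbind(crow(100, "bull1", "liver"), crow(100, "bull2", "liver"),
                crow(200, "bull1", "liver"),
                crow(300, "bull1", "liver"), crow(300, "bull2", "brain"))
  sites <- recurrence_filter(cand)
  expect_equal(sites$pos, c(100, 300))
  expect_equal(sites$tissues[sites$pos == 100], "liver")
  expect_equal(sites$tissues[sites$pos == 300], "brain,liver")
  expect_equal(unique(sites$origin), "high_confidence")
  # unique key, no duplicates
  expect_false(anyDuplicated(paste(sites$contig, sites$pos, sites$ref_t,
                                   sites$alt_t)) > 0)
  # same-tissue recurrence flag drops the cross-tissue site
  strict <- recurrence_filter(cand, threshold_config(recurrence_same_tissue = TRUE))
  expect_equal(strict$pos, 100)
})

test_that("tissue specificity partitions the site set", {
  cand <- rbind(crow(1, "bull1", "brain"), crow(1, "bull2", "brain"),
                crow(2, "bull1", "lung"), crow(2, "bull2", "kidney"),
                crow(3, "bull1", "liver"), crow(3, "bull3", "liver"))
  sites <- recurrence_filter(cand)
  spec <- tissue_specific_sites(sites)
  expect_equal(sort(names(spec)), c("brain", "liver"))
  expect_equal(spec$brain$pos, 1)
  # partition: specific counts + multi-tissue count = total
  n_spec <- sum(vapply(spec, nrow, integer(1)))
  n_multi <- sum(lengths(strsplit(sites$tissues, ",")) > 1)
  expect_equal(n_spec + n_multi, nrow(sites))
})

test_that("shared-site counts match brute force", {
  set.seed(14)
  tissues <- paste0("t", 1:9)
  cand <- do.call(rbind, lapply(1:40, function(i) {
    ts <- sample(tissues, sample(1:9, 1))
    do.call(rbind, c(
      lapply(ts, function(t) crow(i, "bull1", t)),
      list(crow(i, "bull2", ts[1]))))
  }))
  sites <- recurrence_filter(cand)
  expect_equal(nrow(sites), 40L)
  sets <- strsplit(sites$tissues, ",")
  for (k in c(1, 2, 5, 9, 10))
    expect_equal(shared_site_counts(sites, k), sum(lengths(sets) >= k))
  expect_equal(shared_site_counts(sites, 1), nrow(sites))
  expect_equal(shared_site_counts(sites, 10), 0L)
  expect_error(shared_site_counts(sites, 0), ">= 1")
})

test_that("mismatch spectrum counts and the A-to-I fraction are exact", {
  # the published high-confidence split: 697 A>G of 794 candidates
  sp <- mismatch_spectrum(c(rep("A>G", 697), rep("C>T", 21), rep("G>A", 76)))
  expect_equal(sum(sp$count), 794L)
  expect_equal(attr(sp, "a_to_i_fraction"), 100 * 697 / 794)
  expect_equal(round(attr(sp, "a_to_i_fraction")), 88)
  expect_equal(sum(sp$percent), 100)

  expect_equal(attr(mismatch_spectrum(rep("A>G", 10)), "a_to_i_fraction"), 100)

  # tabulation oracle on uniform random classes
  set.seed(2)
  cls <- sample(mismatch_classes(), 1200, TRUE)
  sp2 <- mismatch_spectrum(cls)
  want <- table(factor(cls, levels = mismatch_classes()))
  expect_equal(sp2$count, as.integer(want))
})

test_that("site-tissue matrix averages support ratios per tissue", {
  cand <- rbind(crow(1, "bull1", "liver", ratio = 0.2),
                crow(1, "bull2", "liver", ratio = 0.4),
                crow(1, "bull1", "brain", ratio = 0.6))
  sites <- recurrence_filter(cand)
  m <- site_tissue_matrix(sites, c("brain", "liver", "lung"))
  expect_equal(m[1, "liver"], 0.3)
  expect_equal(m[1, "brain"], 0.6)
  expect_true(is.na(m[1, "lung"]))
})

test_that("two-tissue t-test equals the pooled-variance closed form", {
  cand <- rbind(
    crow(1, "bull1", "a", ratio = 0.2), crow(1, "bull2", "a", ratio = 0.2),
    crow(2, "bull1", "a", ratio = 0.3), crow(2, "bull2", "a", ratio = 0.3),
    crow(3, "bull1", "a", ratio = 0.4), crow(3, "bull2", "a", ratio = 0.4),
    crow(4, "bull1", "b", ratio = 0.6), crow(4, "bull2", "b", ratio = 0.6),
    crow(5, "bull1", "b", ratio = 0.7), crow(5, "bull2", "b", ratio = 0.7),
    crow(6, "bull1", "b", ratio = 0.8), crow(6, "bull2", "b", ratio = 0.8))
  sites <- recurrence_filter(cand)
  res <- compare_editing_ratios(sites, "a", "b")
  # hand computation: means .3/.7, each var .01, pooled sd .1,
  # se = .1*sqrt(1/3+1/3), t = -.4/se = -4.899, df = 4
  se <- 0.1 * sqrt(2 / 3)
  t_hand <- (0.3 - 0.7) / se
  expect_equal(res$t, t_hand, tolerance = 1e-8)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(t_hand, 4), tolerance = 1e-8)

  # identical vectors: t = 0, p = 1 (degenerate convention)
  cand2 <- rbind(
    crow(1, "bull1", "a", ratio = 0.5), crow(1, "bull2", "a", ratio = 0.5),
    crow(2, "bull1", "a", ratio = 0.5), crow(2, "bull2", "a", ratio = 0.5),
    crow(1, "bull1", "b", ratio = 0.5), crow(1, "bull2", "b", ratio = 0.5),
    crow(2, "bull1", "b", ratio = 0.5), crow(2, "bull2", "b", ratio = 0.5))
  res2 <- compare_editing_ratios(recurrence_filter(cand2), "a", "b")
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})

test_that("BH correction reproduces the hand-stepped q-values", {
  # m = 4, p = (.01,.02,.03,.04): q_i = min_{j>=i} p_j * m / j = 0.04 each
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # monotone non-decreasing in sorted p order; q >= p
  set.seed(4)
  p <- runif(50)
  q <- p.adjust(p, "BH")
  expect_true(all(q >= p))
  o <- order(p)
  expect_false(is.unsorted(q[o]))

  # all-pairs wrapper carries BH q and the 0.05 call
  cand <- do.call(rbind, lapply(1:6, function(i) rbind(
    crow(i, "bull1", "a", ratio = 0.1 + 0.05 * i),
    crow(i, "bull2", "a", ratio = 0.1 + 0.05 * i),
    crow(i + 10, "bull1", "b", ratio = 0.5 + 0.05 * i),
    crow(i + 10, "bull2", "b", ratio = 0.5 + 0.05 * i),
    crow(i + 20, "bull1", "c", ratio = 0.1 + 0.06 * i),
    crow(i + 20, "bull2", "c", ratio = 0.1 + 0.06 * i))))
  tests <- tissue_ratio_tests(recurrence_filter(cand))
  expect_equal(nrow(tests), 3L)
  expect_equal(tests$q, p.adjust(tests$p, "BH"))
})

test_that("expression correlation matches the definitional formula", {
  tpm <- matrix(c(2, 4, 6, 8, 10, 12, 14, 16, 18), 1,
                dimnames = list("ADAR", paste0("t", 1:9)))
  counts <- setNames((1:9) * 2, paste0("t", 1:9))
  expect_equal(expression_editing_correlation(tpm, counts, "ADAR")$pearson_r, 1)
  expect_equal(expression_editing_correlation(tpm, -counts, "ADAR")$pearson_r, -1)

  set.seed(6)
  expr <- runif(9, 1, 50)
  tpm2 <- matrix(expr, 1, dimnames = list("ADAR", paste0("t", 1:9)))
  y <- setNames(runif(9, 0, 100), paste0("t", 1:9))
  r <- expression_editing_correlation(tpm2, y, "ADAR")$pearson_r
  r_def <- sum((expr - mean(expr)) * (y - mean(y))) /
    sqrt(sum((expr - mean(expr))^2) * sum((y - mean(y))^2))
  expect_equal(r, r_def, tolerance = 1e-12)

  expect_error(expression_editing_correlation(tpm[, 1:2, drop = FALSE],
                                              counts[1:2], "ADAR"),
               "at least 3")
  expect_error(expression_editing_correlation(tpm, counts, "NOPE"), "absent")
})
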