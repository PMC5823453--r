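test_that("SSR finder reports maximal canonical repeats", {
  ssr <- find_ssrs("GGACACACTT")
  expect_equal(nrow(ssr), 1L)
  expect_equal(ssr$motif, "AC")
  expect_equal(c(ssr$start, ssr$end), c(3L, 8L))
  expect_equal(ssr$total_len, 6L)

  ssr2 <- find_ssrs("TTTTTT")
  expect_equal(ssr2$motif, "T")
  expect_equal(ssr2$total_len, 6L)

  # a poly-A run is reported once, not again as "AA"
  ssr3 <- find_ssrs("CCAAAAAAACC")
  expect_equal(nrow(ssr3), 1L)
  expect_equal(ssr3$motif, "A")

  # N breaks repeats
  expect_equal(nrow(find_ssrs("TTTNTTT")), 0L)
})

test_that("SSR finder agrees with the regex enumeration oracle", {
  set.seed(5)
  for (rep_i in 1:60) {
    # bias the alphabet occasionally to provoke repeats
    s <- if (rep_i %% 3 == 0)
      paste(sample(c("A", "C"), 200, TRUE), collapse = "")
    else rand_seq(200)
    got <- find_ssrs(s)[, c("start", "end", "motif")]
    want <- ssr_oracle(s)
    expect_equal(got, want, ignore_attr = TRUE,
                 label = paste("seq", rep_i))
  }
})

test_that("SSR masking zone extends three bases and is monotone in offset", {
  ssrs <- data.frame(start = 100L, end = 110L, motif = "A", copies = 11L,
                     total_len = 11L)
  expect_true(in_ssr_zone(97L, ssrs))
  expect_false(in_ssr_zone(96L, ssrs))
  expect_true(in_ssr_zone(105L, ssrs))
  expect_true(in_ssr_zone(113L, ssrs))
  expect_false(in_ssr_zone(114L, ssrs))
  # monotone: true at offset k stays true at k+1
  for (p in 90:120) {
    for (k in 0:5) {
      ck <- threshold_config(ssr_offset = k + 1L)
      ck1 <- threshold_config(ssr_offset = k + 2L)
      if (in_ssr_zone(p, ssrs, ck)) expect_true(in_ssr_zone(p, ssrs, ck1))
    }
  }
})

test_that("homopolymer run follows the GATK adjacency convention", {
  g <- make_genome(c1 = "TTTTTTACGCA")
  expect_equal(homopolymer_run(g, "c1", 7L, "T"), 6L)  # TTTTTT[A>T]C
  g2 <- make_genome(c1 = "GCAGGG")
  expect_equal(homopolymer_run(g2, "c1", 3L, "G"), 3L) # GC[A>G]GGG
  expect_equal(homopolymer_run(g2, "c1", 3L, "C"), 1L)
  expect_equal(homopolymer_run(g2, "c1", 3L, "T"), 0L)

  # random contexts vs a naive scan
  set.seed(8)
  g3 <- make_genome(c1 = paste(sample(c("A", "G"), 300, TRUE), collapse = ""))
  ch <- strsplit(as.character(g3[["c1"]]), "")[[1]]
  naive <- function(p, alt) {
    l <- 0L; i <- p - 1L
    while (i >= 1 && ch[i] == alt) { l <- l + 1L; i <- i - 1L }
    r <- 0L; i <- p + 1L
    while (i <= length(ch) && ch[i] == alt) { r <- r + 1L; i <- i + 1L }
    max(l, r)
  }
  for (p in sample(2:299, 50)) for (alt in c("A", "G"))
    expect_equal(homopolymer_run(g3, "c1", p, alt), naive(p, alt))

  # the vectorized batch recomputation agrees with the scalar scan
  pos <- sample(2:299, 80)
  alt <- sample(c("A", "G"), 80, TRUE)
  batch <- rnaeditome:::hrun_batch(g3, rep("c1", 80), pos, alt)
  expect_equal(batch, mapply(naive, pos, alt), ignore_attr = TRUE)
})

test_that("splice-junction zone covers five intronic bases on each side", {
  gms <- mini_gms() # intron 1001..1100
  expect_true(near_splice_junction(1003L, "c1", gms))
  expect_true(near_splice_junction(1001L, "c1", gms))
  expect_true(near_splice_junction(1005L, "c1", gms))
  expect_false(near_splice_junction(1006L, "c1", gms))
  expect_true(near_splice_junction(1096L, "c1", gms))
  expect_false(near_splice_junction(1095L, "c1", gms))
  expect_false(near_splice_junction(950L, "c1", gms))  # exonic
})

test_that("bidirectional transcription requires genes on both strands", {
  gms2 <- gene_model_set(
    genes = data.frame(gene_id = c("a", "b", "c"), symbol = NA,
                       biotype = "protein_coding", contig = "c1",
                       strand = c("+", "-", "+"),
                       start = c(100L, 150L, 1000L), end = c(400L, 450L, 1300L)),
    transcripts = data.frame(transcript_id = c("a.t", "b.t", "c.t"),
                             gene_id = c("a", "b", "c")),
    features = data.frame(transcript_id = c("a.t", "b.t", "c.t"),
                          type = "exon", start = c(100L, 150L, 1000L),
                          end = c(400L, 450L, 1300L), phase = NA_integer_))
  expect_true(bidirectional_overlap(200L, "c1", gms2))
  expect_false(bidirectional_overlap(1100L, "c1", gms2))
  expect_false(bidirectional_overlap(120L, "c1", gms2))  # only + gene there

  # two same-strand overlapping genes are not bidirectional
  gms3 <- gene_model_set(
    genes = data.frame(gene_id = c("x", "y"), symbol = NA,
                       biotype = "protein_coding", contig = "c1",
                       strand = "+", start = c(100L, 200L), end = c(500L, 600L)),
    transcripts = data.frame(transcript_id = c("x.t", "y.t"),
                             gene_id = c("x", "y")),
    features = data.frame(transcript_id = c("x.t", "y.t"), type = "exon",
                          start = c(100L, 200L), end = c(500L, 600L),
                          phase = NA_integer_))
  expect_false(bidirectional_overlap(300L, "c1", gms3))
})

test_that("flank uniqueness finds planted duplicates and honours strand", {
  set.seed(21)
  base <- rand_seq(30000)
  site <- 5000L
  window <- substr(base, site - 50L, site + 50L)
  # unique in a random genome
  g1 <- make_genome(c1 = base)
  expect_true(flank_uniqueness(g1, "c1", site))
  # verbatim copy at a second locus -> non-unique
  dup <- paste0(substr(base, 1, 20000), window,
                substr(base, 20102, nchar(base)))
  g2 <- make_genome(c1 = dup)
  expect_false(flank_uniqueness(g2, "c1", site))
  # reverse-complemented copy is also found
  dup_rc <- paste0(substr(base, 1, 20000), revcomp(window),
                   substr(base, 20102, nchar(base)))
  g3 <- make_genome(c1 = dup_rc)
  expect_false(flank_uniqueness(g3, "c1", site))
  # a 95%-identity copy (5 substitutions) -> still non-unique
  wch <- strsplit(window, "")[[1]]
  idx <- seq(10, 90, by = 20)
  for (i in idx) wch[i] <- c(A = "C", C = "G", G = "T", T = "A")[wch[i]]
  dup95 <- paste0(substr(base, 1, 20000), paste(wch, collapse = ""),
                  substr(base, 20102, nchar(base)))
  g4 <- make_genome(c1 = dup95)
  expect_false(flank_uniqueness(g4, "c1", site))
  # all-N window is conservatively non-unique
  gN <- make_genome(c1 = paste0(substr(base, 1, 4000), strrep("N", 200),
                                substr(base, 4201, nchar(base))))
  expect_false(flank_uniqueness(gN, "c1", 4100L))
})

test_that("uniqueness is invariant to reverse-complementing the genome", {
  set.seed(33)
  base <- rand_seq(20000)
  window <- substr(base, 7000 - 50, 7000 + 50)
  dup <- paste0(substr(base, 1, 15000), window, substr(base, 15102, 20000))
  for (seqs in list(base, dup)) {
    g <- make_genome(c1 = seqs)
    grc <- make_genome(c1 = revcomp(seqs))
    pos_rc <- nchar(seqs) - 7000 + 1
    expect_equal(flank_uniqueness(g, "c1", 7000L),
                 flank_uniqueness(grc, "c1", pos_rc))
  }
})

test_that("PSL ingestion applies the identity and coverage rule", {
  psl <- withr::local_tempfile(fileext = ".psl")
  # matches mismatches ... qname(col10); one perfect self hit for q1,
  # two near-perfect hits for q2, one low-identity hit for q3
  rows <- c(
    paste(c(101, 0, 0, 0, 0, 0, 0, 0, "+", "q1", 101, 0, 101, "c1", rep(0, 7)), collapse = "\t"),
    paste(c(101, 0, 0, 0, 0, 0, 0, 0, "+", "q2", 101, 0, 101, "c1", rep(0, 7)), collapse = "\t"),
    paste(c(96, 5, 0, 0, 0, 0, 0, 0, "+", "q2", 101, 0, 101, "c1", rep(0, 7)), collapse = "\t"),
    paste(c(60, 41, 0, 0, 0, 0, 0, 0, "+", "q3", 101, 0, 101, "c1", rep(0, 7)), collapse = "\t"))
  writeLines(rows, psl)
  res <- uniqueness_from_psl(psl)
  expect_true(res$unique[res$qname == "q1"])
  expect_false(res$unique[res$qname == "q2"])
  expect_false("q3" %in% res$qname[res$n_hits > 0])
})
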