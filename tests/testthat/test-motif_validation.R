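test_that("flank extraction is strand-aware with the edited A at centre", {
  set.seed(23)
  base <- rand_seq(2000)
  # force an A at 1000 and a T at 1500 (A on the minus strand)
  base <- paste0(substr(base, 1, 999), "A", substr(base, 1001, 1499), "T",
                 substr(base, 1501, 2000))
  g <- make_genome(c1 = base)
  plus <- data.frame(contig = "c1", pos = 1000L, strand = "+", ref_t = "A")
  fl <- extract_flanks(plus, g, flank = 50L)
  expect_equal(nchar(fl$seq), 101L)
  expect_false(fl$clipped)
  expect_equal(substr(fl$seq, 51, 51), "A")
  expect_equal(fl$seq, genome_slice(g, "c1", 950, 1050))

  minus <- data.frame(contig = "c1", pos = 1500L, strand = "-", ref_t = "A")
  fl2 <- extract_flanks(minus, g, flank = 50L)
  expect_equal(substr(fl2$seq, 51, 51), "A")
  expect_equal(fl2$seq, revcomp(genome_slice(g, "c1", 1450, 1550)))

  # clipped window near the contig start is flagged
  near <- data.frame(contig = "c1", pos = 20L, strand = "+",
                     ref_t = substr(base, 20, 20))
  expect_true(extract_flanks(near, g, flank = 50L)$clipped)

  # wrong centre base is a hard error (upstream classification bug)
  bad <- data.frame(contig = "c1", pos = 1001L, strand = "+", ref_t = "A")
  if (substr(base, 1001, 1001) != "A")
    expect_error(extract_flanks(bad, g, flank = 50L), "center base")
})

test_that("neighbour PFM counts, column sums and information content", {
  # two sites with identical TAG context (T at -1, G at +1)
  g <- make_genome(c1 = paste0(strrep("C", 30), "TAG", strrep("C", 30),
                               "TAG", strrep("C", 30)))
  sites <- data.frame(contig = "c1", pos = c(32L, 65L), strand = "+",
                      ref_t = "A", mismatch_class = "A>G",
                      stringsAsFactors = FALSE)
  pfm <- neighbor_pfm(sites, g, threshold_config(motif_flank = 1L))
  expect_equal(pfm$counts["T", "-1"], 2L)
  expect_equal(pfm$counts["G", "1"], 2L)
  expect_equal(pfm$counts["A", "0"], 2L)  # position 0 is pure A
  expect_equal(unname(colSums(pfm$counts)), rep(2L, 3))
  expect_equal(unname(pfm$info_content["0"]), 2)   # pure column: 2 bits
  expect_equal(pfm$g_fraction_p1, 1)
  expect_equal(pfm$g_fraction_m1, 0)

  # uniform random contexts: information content near zero off-centre
  set.seed(27)
  base <- rand_seq(60000)
  apos <- which(strsplit(base, "")[[1]] == "A")
  apos <- apos[apos > 10 & apos < 59990]
  sites2 <- data.frame(contig = "c1", pos = sample(apos, 800), strand = "+",
                       ref_t = "A", mismatch_class = "A>G",
                       stringsAsFactors = FALSE)
  pfm2 <- neighbor_pfm(sites2, make_genome(c1 = base))
  off <- setdiff(colnames(pfm2$counts), "0")
  expect_true(all(pfm2$info_content[off] < 0.05))
  expect_equal(unname(pfm2$info_content["0"]), 2)
  expect_equal(unname(colSums(pfm2$counts)), rep(800L, 21))
})

test_that("validation profiles carry the published thresholds", {
  est <- validation_profile("est")
  expect_equal(est$max_evalue, 1e-5)
  expect_true(is.na(est$min_identity))
  cons <- validation_profile("conservation")
  expect_equal(cons$max_evalue, 1e-3)
  expect_equal(cons$min_identity, 0.85)
  expect_equal(cons$min_alnlen, 50L)
})

test_that("reference matching counts verbatim hits and rejects weak ones", {
  set.seed(29)
  flank <- rand_seq(101)
  ref <- Biostrings::DNAStringSet(c(
    est1 = paste0(rand_seq(40), flank, rand_seq(60)),  # verbatim
    est2 = rand_seq(300),                              # unrelated
    est3 = rand_seq(250)))
  got <- match_reference(c(site1 = flank), ref, validation_profile("est"))
  expect_equal(got$n_hits, 1L)
  expect_equal(got$best_identity, 1)
  expect_equal(got$best_alnlen, 101L)
  expect_lt(got$best_evalue, 1e-20)

  # 80% identity copy fails the conservation profile (needs 0.85)
  fch <- strsplit(flank, "")[[1]]
  idx <- seq(3, 101, by = 5)
  for (i in idx) fch[i] <- c(A = "C", C = "G", G = "T", T = "A")[fch[i]]
  ref80 <- Biostrings::DNAStringSet(c(weak = paste(fch, collapse = "")))
  got80 <- match_reference(c(site1 = flank), ref80,
                           validation_profile("conservation"))
  expect_equal(got80$n_hits, 0L)

  # empty reference: zero counts with a warning
  expect_warning(z <- match_reference(c(site1 = flank),
                                      Biostrings::DNAStringSet()),
                 "empty reference")
  expect_equal(z$n_hits, 0L)
})

test_that("matching is order-invariant and monotone in thresholds", {
  set.seed(31)
  flanks <- setNames(vapply(1:5, function(i) rand_seq(101), ""),
                     paste0("s", 1:5))
  refs <- c(lapply(1:20, function(i) rand_seq(200)),
            lapply(flanks[1:3], function(f)
              paste0(rand_seq(30), f, rand_seq(30))))
  ref <- Biostrings::DNAStringSet(setNames(unlist(refs),
                                           paste0("r", seq_along(refs))))
  prof <- validation_profile("est")
  a <- match_reference(flanks, ref, prof)
  b <- match_reference(flanks, ref[sample(length(ref))], prof)
  expect_equal(a$n_hits, b$n_hits)
  expect_equal(a$n_hits[1:3], rep(1L, 3))
  expect_equal(a$n_hits[4:5], rep(0L, 3 - 1))

  # relaxing the e-value cutoff never loses hits
  strict <- prof; strict$max_evalue <- 1e-30
  loose <- prof; loose$max_evalue <- 1e-2
  expect_true(all(match_reference(flanks, ref, loose)$n_hits >=
                    match_reference(flanks, ref, strict)$n_hits))
  # lowering the identity floor never loses hits
  c1 <- validation_profile("conservation")
  c2 <- c1; c2$min_identity <- 0.5
  expect_true(all(match_reference(flanks, ref, c2)$n_hits >=
                    match_reference(flanks, ref, c1)$n_hits))
})

test_that("seeded matcher agrees with exhaustive Smith-Waterman decisions", {
  set.seed(37)
  flank <- rand_seq(101)
  # toy reference of 50 sequences: some contain diverged copies
  mk_copy <- function(rate) {
    ch <- strsplit(flank, "")[[1]]
    hit <- which(runif(101) < rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste0(rand_seq(20), paste(ch, collapse = ""), rand_seq(20))
  }
  refs <- c(vapply(1:40, function(i) rand_seq(150), ""),
            vapply(c(0, 0.02, 0.05, 0.10, 0.20, 0.30, 0.40, 0.5, 0.6, 0.7),
                   mk_copy, ""))
  ref <- Biostrings::DNAStringSet(setNames(refs, paste0("r", 1:50)))
  prof <- validation_profile("est")
  got <- match_reference(c(q = flank), ref, prof)

  # oracle: full Smith-Waterman (no seeding) of the flank against every
  # reference sequence, same scoring, same e-value rule
  lambda <- rnaeditome:::ka_lambda()
  dblen <- sum(nchar(refs))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  oracle_hits <- 0L
  for (r in refs) {
    al <- Biostrings::pairwiseAlignment(flank, r, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(al)
    if (sc <= 0) next
    ev <- 0.621 * 101 * dblen * exp(-lambda * sc)
    if (ev <= prof$max_evalue) oracle_hits <- oracle_hits + 1L
  }
  expect_equal(got$n_hits, oracle_hits)
})
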