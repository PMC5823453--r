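# Shared fixtures and independent oracles, built in code.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

make_genome <- function(...) {
  v <- c(...)
  Biostrings::DNAStringSet(v)
}

# A two-gene model: plus-strand coding gene with two exons (intron
# 1001-1100), and a minus-strand coding gene far downstream.
mini_gms <- function() {
  gene_model_set(
    genes = data.frame(
      gene_id = c("gP", "gM"), symbol = c("PLUS1", "MINUS1"),
      biotype = "protein_coding", contig = "c1",
      strand = c("+", "-"), start = c(901L, 5001L), end = c(1400L, 5600L),
      stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = c("tP", "tM"),
                             gene_id = c("gP", "gM"),
                             stringsAsFactors = FALSE),
    features = rbind(
      data.frame(transcript_id = "tP", type = "exon",
                 start = c(901L, 1101L), end = c(1000L, 1400L),
                 phase = NA_integer_),
      data.frame(transcript_id = "tP", type = "cds",
                 start = c(931L, 1101L), end = c(1000L, 1240L),
                 phase = c(0L, 2L)),
      data.frame(transcript_id = "tP", type = "utr5",
                 start = 901L, end = 930L, phase = NA_integer_),
      data.frame(transcript_id = "tP", type = "utr3",
                 start = 1241L, end = 1400L, phase = NA_integer_),
      data.frame(transcript_id = "tM", type = "exon",
                 start = c(5001L, 5301L), end = c(5200L, 5600L),
                 phase = NA_integer_)))
}

# variant row builder with passing defaults
vrow <- function(contig = "c1", pos = 100L, ref = "A", alt = "G",
                 total_depth = 40L, alt_depth = 10L, genotype = "het",
                 multi_allelic = FALSE, hrun = 1, mq = 60, qd = 20,
                 mq_rank_sum = 0, read_pos_rank_sum = 0,
                 individual = "bull1", tissue = "liver") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             total_depth = total_depth, alt_depth = alt_depth,
             genotype = genotype, multi_allelic = multi_allelic,
             hrun = hrun, mq = mq, qd = qd, mq_rank_sum = mq_rank_sum,
             read_pos_rank_sum = read_pos_rank_sum,
             individual = individual, tissue = tissue,
             stringsAsFactors = FALSE)
}

# --- independent SSR oracle ----------------------------------------------
# For each motif length m, mark every position where the sequence equals
# itself shifted by m (vectorized comparison + rle); each maximal TRUE run
# of length L is a perfect repeat spanning L + m bases. Then apply the
# span / primitivity / canonical-motif rules.
min_rotation <- function(m) {
  rots <- vapply(seq_len(nchar(m)), function(i)
    paste0(substr(m, i, nchar(m)), substr(m, 1, i - 1)), character(1))
  min(rots)
}
is_primitive_motif <- function(m) {
  L <- nchar(m)
  for (d in seq_len(L - 1)) {
    if (L %% d != 0) next
    if (m == paste(rep(substr(m, 1, d), L / d), collapse = "")) return(FALSE)
  }
  TRUE
}
ssr_oracle <- function(s, min_total = 6L, max_motif = 8L) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  rows <- list()
  for (m in seq_len(max_motif)) {
    if (n <= m) break
    eq <- ch[1:(n - m)] == ch[(m + 1):n] &
      ch[1:(n - m)] != "N" & ch[(m + 1):n] != "N"
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (k in which(r$values)) {
      st <- run_start[k]
      en <- st + r$lengths[k] + m - 1L
      motif <- substr(s, st, st + m - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_primitive_motif(motif)) next
      if (en - st + 1L < max(min_total, 2L * m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = en, motif = min_rotation(motif),
        stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, rows))
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      motif = character()))
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# --- independent sliding-window identity scan for flank uniqueness ------
# Exhaustive ungapped scan: counts loci where the full window matches the
# genome at >= min_identity over its whole length, on either strand.
# (Fixtures plant substitution-only duplicates, so gapless scanning is the
# exact truth for them.)
sliding_hits <- function(window, genome_seq, min_identity = 0.9) {
  L <- nchar(window)
  wch <- strsplit(window, "")[[1]]
  count_strand <- function(gs) {
    gch <- strsplit(gs, "")[[1]]
    n <- length(gch)
    if (n < L) return(integer(0))
    acc <- integer(n - L + 1L)
    for (w in seq_len(L))
      acc <- acc + (gch[w:(n - L + w)] == wch[w])
    which(acc / L >= min_identity)
  }
  fw <- count_strand(genome_seq)
  rv <- count_strand(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genome_seq))))
  # merge adjacent offsets into loci
  n_loci <- function(off) if (!length(off)) 0L else
    sum(c(TRUE, diff(off) > L %/% 2L))
  n_loci(fw) + n_loci(rv)
}
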