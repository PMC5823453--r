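# Flank self-uniqueness: BLAT-style near-duplicate screen for the 101-bp
# window around a candidate site, re-implemented as k-mer seeding plus
# Smith-Waterman verification against both strands of the assembly.

UNIQ_SEED_K <- 12L

#' Extract the flanking window around a site
#' @param genome `DNAStringSet`.
#' @param contig,pos site location.
#' @param flank bases on each side (default 50, i.e. a 101-bp window).
#' @return list with `seq` (character), `start`, `end`, `clipped` (logical,
#'   TRUE when the window ran into a contig end).
#' @export
flank_window <- function(genome, contig, pos, flank = 50L) {
  w <- length(genome[[contig]])
  s <- max(1L, pos - flank)
  e <- min(w, pos + flank)
  list(seq = genome_slice(genome, contig, s, e), start = s, end = e,
       clipped = (s != pos - flank) || (e != pos + flank))
}

#' Flank-uniqueness screen for candidate sites
#'
#' For each site the `2*uniq_flank + 1` bp window is searched against the
#' whole assembly (both strands) with exact k-mer seeding followed by local
#' Smith-Waterman verification of each seeded locus. A locus counts as a hit
#' when identity is at least `uniq_min_identity` over at least
#' `uniq_min_coverage` of the window length. A site is unique when exactly
#' one hit exists (its own locus). Windows that are entirely `N` are
#' conservatively non-unique.
#'
#' @param genome `DNAStringSet`.
#' @param sites data.frame with `contig` and `pos`.
#' @param config a [threshold_config()].
#' @return data.frame with columns `contig`, `pos`, `n_hits`, `clipped`,
#'   `unique`.
#' @export
flank_unique_sites <- function(genome, sites, config = threshold_config()) {
  n <- nrow(sites)
  out <- data.frame(contig = sites$contig, pos = sites$pos,
                    n_hits = integer(n), clipped = logical(n),
                    unique = logical(n), stringsAsFactors = FALSE)
  if (!n) return(out)
  k <- UNIQ_SEED_K
  windows <- vector("list", n)
  for (i in seq_len(n)) {
    fw <- flank_window(genome, sites$contig[i], sites$pos[i], config$uniq_flank)
    windows[[i]] <- fw
    out$clipped[i] <- fw$clipped
  }
  # collect seeds from every window
  seed_win <- integer(0); seed_off <- integer(0); seed_seq <- character(0)
  for (i in seq_len(n)) {
    sq <- windows[[i]]$seq
    L <- nchar(sq)
    if (L < k) next
    offs <- seq_len(L - k + 1L)
    km <- substring(sq, offs, offs + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    seed_win <- c(seed_win, rep.int(i, sum(keep)))
    seed_off <- c(seed_off, offs[keep])
    seed_seq <- c(seed_seq, km[keep])
  }
  if (!length(seed_seq)) {
    out$unique <- FALSE # all-N windows
    return(out)
  }
  ukm <- unique(seed_seq)
  idx_by_kmer <- split(seq_along(seed_seq), match(seed_seq, ukm))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(ukm))

  # candidate window-start diagonals per (window, strand-sequence)
  cand <- vector("list", n)
  for (i in seq_len(n)) cand[[i]] <- list()
  subjects <- list()
  for (ctg in names(genome)) {
    subjects[[paste0(ctg, "/+")]] <- genome[[ctg]]
    subjects[[paste0(ctg, "/-")]] <- Biostrings::reverseComplement(genome[[ctg]])
  }
  for (sk in names(subjects)) {
    mi <- Biostrings::matchPDict(pd, subjects[[sk]])
    st <- Biostrings::startIndex(mi)
    for (j in seq_along(st)) {
      hits <- st[[j]]
      if (is.null(hits) || !length(hits)) next
      for (sid in idx_by_kmer[[as.character(j)]]) {
        wi <- seed_win[sid]
        diag <- hits - seed_off[sid] + 1L
        cand[[wi]][[sk]] <- c(cand[[wi]][[sk]], diag)
      }
    }
  }

  for (i in seq_len(n)) {
    sq <- windows[[i]]$seq
    L <- nchar(sq)
    min_cov <- ceiling(config$uniq_min_coverage * L)
    hits <- 0L
    for (sk in names(cand[[i]])) {
      subj <- subjects[[sk]]
      W <- length(subj)
      starts <- sort(unique(cand[[i]][[sk]]))
      if (!length(starts)) next
      # cluster diagonals within half a window into loci
      grp <- cumsum(c(TRUE, diff(starts) > L %/% 2L))
      for (g in split(starts, grp)) {
        s0 <- max(1L, min(g) - 10L)
        e0 <- min(W, max(g) + L - 1L + 10L)
        seg <- as.character(Biostrings::subseq(subj, s0, e0))
        al <- sw_align_cpp(sq, seg)
        if (!is.na(al$identity) && al$identity >= config$uniq_min_identity &&
            al$aln_len >= min_cov)
          hits <- hits + 1L
      }
    }
    out$n_hits[i] <- hits
    out$unique[i] <- hits == 1L
  }
  out
}

#' @rdname flank_unique_sites
#' @param contig,pos single site coordinates.
#' @return `flank_uniqueness` returns a logical scalar.
#' @export
flank_uniqueness <- function(genome, contig, pos, config = threshold_config()) {
  flank_unique_sites(genome,
                     data.frame(contig = contig, pos = pos,
                                stringsAsFactors = FALSE),
                     config)$unique
}

#' Ingest an external aligner's PSL output as a uniqueness verdict
#'
#' Alternative to the built-in scan: given BLAT PSL hits of each window
#' against the assembly, a site is unique when exactly one hit reaches the
#' identity/coverage rule.
#'
#' @param psl_path PSL file (no header or with the 5-line header).
#' @param window_len length of the searched windows.
#' @param config a [threshold_config()].
#' @return data.frame with `qname`, `n_hits`, `unique`.
#' @export
uniqueness_from_psl <- function(psl_path, window_len = 101L,
                                config = threshold_config()) {
  ln <- readLines(psl_path)
  ln <- ln[grepl("^[0-9]", ln)]
  if (!length(ln))
    return(data.frame(qname = character(), n_hits = integer(), unique = logical()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  matches <- as.integer(vapply(f, `[[`, character(1), 1))
  mismatches <- as.integer(vapply(f, `[[`, character(1), 2))
  qname <- vapply(f, `[[`, character(1), 10)
  aln <- matches + mismatches
  ok <- aln >= ceiling(config$uniq_min_coverage * window_len) &
    matches / pmax(aln, 1L) >= config$uniq_min_identity
  tab <- table(qname[ok])
  data.frame(qname = names(tab), n_hits = as.integer(tab),
             unique = as.integer(tab) == 1L, stringsAsFactors = FALSE,
             row.names = NULL)
}
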