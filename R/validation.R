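# Flank-alignment validation against EST / known-editome sequence sets:
# seeded Smith-Waterman with Karlin-Altschul e-values (match +1, mismatch
# -2, gap open 5, gap extend 2 -- the classic nucleotide BLAST scheme).

VALID_MATCH <- 1; VALID_MISMATCH <- -2
VALID_GAP_OPEN <- 5; VALID_GAP_EXT <- 2
VALID_SEED_K <- 11L

# lambda for the ungapped scheme under uniform base composition:
# solve  P(match) e^{lambda s_match} + P(mismatch) e^{lambda s_mismatch} = 1
ka_lambda <- function(match = VALID_MATCH, mismatch = VALID_MISMATCH) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10))$root
}
# K for this scheme (standard tabulated constant for +1/-2)
KA_K <- 0.621

#' Validation matching profiles
#'
#' `est`: a hit supports a site when its e-value is at most 1e-5 (EST
#' corroboration). `conservation`: e-value at most 1e-3, identity at least
#' 0.85 and alignment length at least 50 (cross-species editome
#' comparison).
#' @param name `"est"` or `"conservation"`.
#' @return list with `name`, `max_evalue`, `min_identity`, `min_alnlen`
#'   (`NA` = criterion not applied).
#' @export
validation_profile <- function(name = c("est", "conservation")) {
  name <- match.arg(name)
  if (name == "est")
    list(name = "est", max_evalue = 1e-5, min_identity = NA_real_,
         min_alnlen = NA_integer_)
  else
    list(name = "conservation", max_evalue = 1e-3, min_identity = 0.85,
         min_alnlen = 50L)
}

#' Match site flanks against a reference sequence set
#'
#' Local alignment of each flank against each reference sequence: an exact
#' shared k-mer prefilter (k = 11) selects candidate pairs, each verified
#' by Smith-Waterman (+1/-2, gap open 5, extend 2). E-values follow
#' Karlin-Altschul with database-size correction, `E = K m N exp(-lambda
#' S)` with `N` the total reference length. A reference sequence supports a
#' site when e-value, identity (matches / alignment columns, gaps count)
#' and alignment length all satisfy the profile; absent criteria are
#' skipped.
#'
#' @param flanks character vector of flank sequences (names kept), e.g.
#'   `extract_flanks()$seq`.
#' @param reference a FASTA path or named `DNAStringSet`.
#' @param profile a [validation_profile()].
#' @return data.frame, one row per flank: `n_hits`, `best_score`,
#'   `best_identity`, `best_alnlen`, `best_evalue`.
#' @export
match_reference <- function(flanks, reference,
                            profile = validation_profile("est")) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  refs <- toupper(as.character(reference))
  n <- length(flanks)
  out <- data.frame(n_hits = integer(n), best_score = rep(NA_real_, n),
                    best_identity = rep(NA_real_, n),
                    best_alnlen = rep(NA_integer_, n),
                    best_evalue = rep(NA_real_, n))
  rownames(out) <- names(flanks)
  if (!length(refs)) {
    warning("empty reference; zero support counts")
    return(out)
  }
  db_len <- sum(nchar(refs))
  lambda <- ka_lambda()
  kmer_set <- function(s, k) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  }
  ref_kmers <- lapply(refs, kmer_set, k = VALID_SEED_K)
  for (i in seq_len(n)) {
    fk <- kmer_set(flanks[i], VALID_SEED_K)
    hits <- 0L
    best <- NULL
    for (j in seq_along(refs)) {
      if (!length(fk) || !any(fk %in% ref_kmers[[j]])) next
      al <- sw_align_cpp(flanks[i], refs[j],
                         VALID_MATCH, VALID_MISMATCH,
                         VALID_GAP_OPEN, VALID_GAP_EXT)
      if (al$score <= 0) next
      ev <- KA_K * nchar(flanks[i]) * db_len * exp(-lambda * al$score)
      ok <- ev <= profile$max_evalue &&
        (is.na(profile$min_identity) || al$identity >= profile$min_identity) &&
        (is.na(profile$min_alnlen) || al$aln_len >= profile$min_alnlen)
      if (ok) hits <- hits + 1L
      if (is.null(best) || al$score > best$score)
        best <- list(score = al$score, identity = al$identity,
                     alnlen = al$aln_len, evalue = ev)
    }
    out$n_hits[i] <- hits
    if (!is.null(best)) {
      out$best_score[i] <- best$score
      out$best_identity[i] <- best$identity
      out$best_alnlen[i] <- best$alnlen
      out$best_evalue[i] <- best$evalue
    }
  }
  out
}

#' Ingest external BLAST tabular output (outfmt 6) as support counts
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Applies the same profile thresholds as
#' [match_reference()] (identity read as pident/100).
#' @param path tabular BLAST output.
#' @param profile a [validation_profile()].
#' @return data.frame with `qseqid`, `n_hits`.
#' @export
support_from_blast_tab <- function(path, profile = validation_profile("est")) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[c(1, 3, 4, 11)] <- c("qseqid", "pident", "length", "evalue")
  ok <- df$evalue <= profile$max_evalue &
    (is.na(profile$min_identity) | df$pident / 100 >= profile$min_identity) &
    (is.na(profile$min_alnlen) | df$length >= profile$min_alnlen)
  tab <- table(df$qseqid[ok])
  data.frame(qseqid = names(tab), n_hits = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
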