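#' Extract transcribed-strand flanks around editing sites
#'
#' Returns the `2*flank + 1` nt window centred on each site, on the
#' transcribed strand (minus-strand sites are reverse-complemented so the
#' centre base is always the edited adenosine). Windows running into a
#' contig end are clipped and flagged.
#'
#' @param sites site table with `contig`, `pos`, `strand`, `ref_t`.
#' @param genome `DNAStringSet`.
#' @param flank bases on each side (default 50).
#' @return data.frame with `seq`, `clipped`, `center` (1-based index of the
#'   edited base within `seq`).
#' @export
extract_flanks <- function(sites, genome, flank = 50L) {
  n <- nrow(sites)
  out <- data.frame(seq = character(n), clipped = logical(n),
                    center = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fw <- flank_window(genome, sites$contig[i], sites$pos[i], flank)
    minus <- !is.na(sites$strand[i]) && sites$strand[i] == "-"
    sq <- if (minus) revcomp(fw$seq) else fw$seq
    center <- if (minus) fw$end - sites$pos[i] + 1L else sites$pos[i] - fw$start + 1L
    cb <- substr(sq, center, center)
    if (!is.na(sites$ref_t[i]) && cb != sites$ref_t[i])
      stop(sprintf("flank center base %s != transcribed-strand ref %s at %s:%d",
                   cb, sites$ref_t[i], sites$contig[i], sites$pos[i]))
    out$seq[i] <- sq
    out$clipped[i] <- fw$clipped
    out$center[i] <- center
  }
  out
}

#' Neighbour-preference position frequency matrix
#'
#' Base counts at positions -flank..+flank around the edited adenosine
#' (position 0), on the transcribed strand. Edge-clipped sites are excluded
#' column-wise, so column sums equal the number of contributing sites per
#' position. Information content per position is `2 - H` bits (Shannon
#' entropy of the base frequencies, no small-sample correction). The G
#' fraction at -1 and +1 summarises the characteristic depletion/enrichment
#' flanking ADAR targets.
#'
#' @param sites site table (A>G sites; others are dropped with a message).
#' @param genome `DNAStringSet`.
#' @param config a [threshold_config()] (`motif_flank`).
#' @return list with `counts` (4 x (2*flank+1) matrix, rows A/C/G/T),
#'   `freq`, `info_content` (bits per position), `g_fraction_m1`,
#'   `g_fraction_p1`, `n_sites`.
#' @export
neighbor_pfm <- function(sites, genome, config = threshold_config()) {
  ag <- sites[!is.na(sites$mismatch_class) & sites$mismatch_class == "A>G", ,
              drop = FALSE]
  if (nrow(ag) < nrow(sites))
    message("neighbor_pfm: using ", nrow(ag), " A>G sites of ", nrow(sites))
  if (!nrow(ag)) stop("no A>G sites")
  k <- config$motif_flank
  posn <- -k:k
  counts <- matrix(0L, 4L, length(posn),
                   dimnames = list(c("A", "C", "G", "T"), as.character(posn)))
  fl <- extract_flanks(ag, genome, flank = k)
  for (i in seq_len(nrow(fl))) {
    sq <- strsplit(fl$seq[i], "")[[1]]
    for (j in seq_along(posn)) {
      idx <- fl$center[i] + posn[j]
      if (idx < 1L || idx > length(sq)) next # edge-clipped at this column
      b <- sq[idx]
      if (b %in% rownames(counts))
        counts[b, j] <- counts[b, j] + 1L
    }
  }
  csum <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(csum, 1L), "/")
  ent <- apply(freq, 2L, function(p) {
    p <- p[p > 0]; -sum(p * log2(p))
  })
  ic <- 2 - ent
  list(counts = counts, freq = freq, info_content = ic,
       g_fraction_m1 = freq["G", as.character(-1L)],
       g_fraction_p1 = freq["G", as.character(1L)],
       n_sites = nrow(ag))
}

#' Write a position frequency matrix as TSV
#' @param pfm output of [neighbor_pfm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = as.integer(colnames(pfm$counts)),
                   t(pfm$counts), bits = round(pfm$info_content, 4))
  names(df)[2:5] <- rownames(pfm$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
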