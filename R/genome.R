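#' Read a genome assembly from FASTA
#'
#' Loads all contigs into a named [Biostrings::DNAStringSet], uppercasing
#' lowercase (soft-masked) bases. Contig names are the first whitespace
#' token of each FASTA header.
#'
#' @param path path to a FASTA file (uncompressed or gzipped).
#' @return a `DNAStringSet`, one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT", ">c2", "NNNN"), fa)
#' g <- read_genome(fa)
#' genome_slice(g, "c1", 2, 4)
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate contig name(s): ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  if (any(Biostrings::width(g) == 0L)) stop("empty contig sequence in ", path)
  # uppercase; DNAStringSet already rejects non-IUPAC characters on read,
  # but report any position outside the alphabet we operate on explicitly
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  af <- Biostrings::alphabetFrequency(g)
  extra <- af[, !colnames(af) %in% c("A", "C", "G", "T", "N"), drop = FALSE]
  if (any(extra > 0)) {
    i <- which(rowSums(extra) > 0)[1]
    bad <- colnames(extra)[which(extra[i, ] > 0)[1]]
    pos <- regexpr(bad, as.character(g[[i]]), fixed = TRUE)
    stop(sprintf("non-ACGTN character '%s' at %s:%d", bad, names(g)[i], pos))
  }
  g
}

#' Write a genome assembly to FASTA
#' @param genome a named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Extract a 1-based inclusive slice of a contig
#'
#' @param genome a named `DNAStringSet` from [read_genome()].
#' @param contig contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return a character scalar of exactly `end - start + 1` bases.
#' @export
genome_slice <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  w <- length(genome[[contig]])
  if (start < 1L || end > w || end < start)
    stop(sprintf("slice %s:%d-%d outside contig bounds (1-%d)", contig, start, end, w))
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

contig_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Complement / reverse-complement of a base vector or sequence string
#' @param x character vector of single bases (for `complement_base`) or of
#'   sequences (for `revcomp`).
#' @return character vector of the same length.
#' @export
complement_base <- function(x) unname(COMPLEMENT[x])

#' @rdname complement_base
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
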