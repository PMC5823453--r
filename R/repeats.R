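#' Read repeat annotations (RepeatMasker .out or BED)
#'
#' BED input (0-based half-open) is converted to the internal 1-based
#' inclusive convention at read time; the BED `name` column is interpreted
#' as `class/family` (e.g. `SINE/Bov-tA`). RepeatMasker `.out` tables are
#' parsed from their fixed column layout.
#'
#' @param path a `.bed` file or a RepeatMasker `.out` file (detected by
#'   extension).
#' @return a `GRanges` with metadata columns `repeat_class` (`SINE`, `LINE`,
#'   `DNA` or `other`) and `family`.
#' @export
read_repeats <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    bed <- rtracklayer::import(path, format = "bed")
    nm <- if (!is.null(bed$name)) as.character(bed$name) else rep("other/unknown", length(bed))
    cls <- sub("/.*$", "", nm)
    fam <- ifelse(grepl("/", nm), sub("^[^/]*/", "", nm), NA_character_)
  } else {
    # RepeatMasker .out: whitespace table after a 3-line header
    ln <- readLines(path)
    ln <- ln[-seq_len(min(3L, length(ln)))]
    ln <- ln[nzchar(trimws(ln))]
    if (!length(ln)) {
      return(GenomicRanges::GRanges(repeat_class = character(), family = character()))
    }
    f <- strsplit(trimws(ln), "\\s+")
    get <- function(i) vapply(f, `[[`, character(1), i)
    cf <- get(11) # "class/family"
    cls <- sub("/.*$", "", cf)
    fam <- get(10)
    bed <- GenomicRanges::GRanges(
      get(5), IRanges::IRanges(as.integer(get(6)), as.integer(get(7))),
      strand = ifelse(get(9) %in% c("C", "-"), "-", "+"))
  }
  cls <- ifelse(cls %in% c("SINE", "LINE", "DNA"), cls, "other")
  S4Vectors::mcols(bed) <- S4Vectors::DataFrame(repeat_class = cls, family = fam)
  bed
}

#' Write repeat intervals as BED6
#'
#' Converts from the internal 1-based inclusive coordinates to BED's
#' 0-based half-open on the way out; name column is `class/family`.
#' @param repeats a `GRanges` with `repeat_class` and `family` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeats_bed <- function(repeats, path) {
  fam <- repeats$family
  nm <- ifelse(is.na(fam), as.character(repeats$repeat_class),
               paste0(repeats$repeat_class, "/", fam))
  df <- data.frame(as.character(GenomicRanges::seqnames(repeats)),
                   GenomicRanges::start(repeats) - 1L,
                   GenomicRanges::end(repeats),
                   nm, 0L, as.character(GenomicRanges::strand(repeats)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
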