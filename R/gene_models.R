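#' Construct a gene-model set
#'
#' The internal gene-model container used by the strand resolver, the
#' bidirectional-transcription and splice-junction filters, and the region /
#' consequence annotators. Coordinates are 1-based inclusive throughout.
#'
#' @param genes data.frame with columns `gene_id`, `symbol`, `biotype`
#'   (`protein_coding`, `pseudogene` or `other`), `contig`, `strand`
#'   (`+`/`-`), `start`, `end`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param features data.frame with columns `transcript_id`, `type` (`exon`,
#'   `cds`, `utr5`, `utr3`), `start`, `end` and, for `cds` rows, `phase`
#'   (0/1/2 bases to skip before the first complete codon).
#'
#' @details A transcript is *complete* when it has CDS features whose total
#'   length is divisible by 3; incomplete transcripts are excluded from
#'   coding-consequence calls. Exons must be non-overlapping within a
#'   transcript; they are stored sorted by coordinate.
#'
#' @return An object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, transcripts, features) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " missing column(s): ", paste(miss, collapse = ", "))
  }
  need(genes, c("gene_id", "symbol", "biotype", "contig", "strand", "start", "end"), "genes")
  need(transcripts, c("transcript_id", "gene_id"), "transcripts")
  need(features, c("transcript_id", "type", "start", "end"), "features")
  if (!"phase" %in% names(features)) features$phase <- NA_integer_
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (!all(genes$biotype %in% c("protein_coding", "pseudogene", "other")))
    stop("biotype must be protein_coding, pseudogene or other")
  if (!all(features$type %in% c("exon", "cds", "utr5", "utr3")))
    stop("feature type must be exon, cds, utr5 or utr3")
  if (any(features$end < features$start) || any(genes$end < genes$start))
    stop("invalid interval (end < start)")
  orphan <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(orphan)) stop("transcript references unknown gene: ", orphan[1])

  features <- merge(features,
                    transcripts[, c("transcript_id", "gene_id")],
                    by = "transcript_id", sort = FALSE)
  features <- merge(features,
                    genes[, c("gene_id", "contig", "strand")],
                    by = "gene_id", sort = FALSE)
  features <- features[order(features$transcript_id, features$start), ]
  rownames(features) <- NULL

  # exon sanity + transcript completeness
  transcripts$complete <- vapply(transcripts$transcript_id, function(tx) {
    f <- features[features$transcript_id == tx, ]
    ex <- f[f$type == "exon", ]
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in transcript ", tx)
    cds <- f[f$type == "cds", ]
    nrow(cds) > 0L && sum(cds$end - cds$start + 1L) %% 3L == 0L
  }, logical(1))

  structure(list(genes = genes, transcripts = transcripts, features = features),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d genes, %d transcripts, %d features\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$features)))
  invisible(x)
}

normalize_biotype <- function(x) {
  x <- ifelse(is.na(x) | x == "", "protein_coding", x)
  ifelse(grepl("pseudogene", x), "pseudogene",
         ifelse(x == "protein_coding", "protein_coding", "other"))
}

#' Read gene models from GFF3 or GTF
#'
#' The dialect is auto-detected from the file extension (`.gtf` vs
#' `.gff`/`.gff3`). Hierarchy is rebuilt as gene -> transcript -> features;
#' exon, CDS and UTR intervals are converted to the internal 1-based
#' inclusive convention (native to both dialects). A transcript with no
#' parent gene raises a warning and a single-transcript gene is synthesized
#' around it.
#'
#' @param path GFF3 or GTF file.
#' @return a [gene_model_set()].
#' @export
read_gene_models <- function(path) {
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(seqnames = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = tolower(as.character(mc$type)),
                   stringsAsFactors = FALSE)
  if ("phase" %in% names(mc)) df$phase <- as.integer(mc$phase)
  else df$phase <- NA_integer_

  get_attr <- function(d, keys) {
    for (k in keys) if (k %in% names(mc)) {
      v <- mc[[k]]
      if (methods::is(v, "List") || is.list(v))
        v <- vapply(as.list(v),
                    function(z) if (length(z)) as.character(z)[1] else NA_character_,
                    character(1))
      return(as.character(v))
    }
    rep(NA_character_, nrow(d))
  }

  if (fmt == "gtf") {
    df$.gene <- get_attr(df, "gene_id")
    df$.tx <- get_attr(df, "transcript_id")
  } else {
    id <- get_attr(df, "ID")
    parent <- get_attr(df, "Parent")
    df$.id <- id
    df$.parent <- parent
  }
  df$.name <- get_attr(df, c("Name", "gene_name", "gene_symbol"))
  df$.biotype <- get_attr(df, c("biotype", "gene_biotype", "gene_type"))

  is_gene <- df$type %in% c("gene", "pseudogene")
  is_tx <- df$type %in% c("mrna", "transcript")
  type_map <- c(exon = "exon", cds = "cds",
                five_prime_utr = "utr5", three_prime_utr = "utr3",
                five_prime_utr_region = "utr5", utr5 = "utr5", utr3 = "utr3")

  if (fmt == "gtf") {
    gdf <- df[is_gene, ]
    genes <- data.frame(gene_id = gdf$.gene, symbol = gdf$.name,
                        biotype = normalize_biotype(gdf$.biotype),
                        contig = gdf$seqnames, strand = gdf$strand,
                        start = gdf$start, end = gdf$end,
                        stringsAsFactors = FALSE)
    tdf <- df[is_tx, ]
    transcripts <- data.frame(transcript_id = tdf$.tx, gene_id = tdf$.gene,
                              stringsAsFactors = FALSE)
    fdf <- df[df$type %in% names(type_map), ]
    features <- data.frame(transcript_id = fdf$.tx,
                           type = unname(type_map[fdf$type]),
                           start = fdf$start, end = fdf$end,
                           phase = suppressWarnings(as.integer(as.character(fdf$phase))),
                           stringsAsFactors = FALSE)
    # GTFs often carry no explicit gene rows: synthesize them from the
    # transcript (or exon) extent
    orphan <- setdiff(transcripts$gene_id, genes$gene_id)
    if (length(orphan)) {
      if (nrow(genes))
        warning("synthesizing gene row(s) for: ", paste(orphan, collapse = ", "))
      for (gid in orphan) {
        txs <- transcripts$transcript_id[transcripts$gene_id == gid]
        rows <- rbind(tdf[tdf$.tx %in% txs, c("seqnames", "strand", "start", "end", ".name", ".biotype")],
                      fdf[fdf$.tx %in% txs, c("seqnames", "strand", "start", "end", ".name", ".biotype")])
        genes <- rbind(genes, data.frame(
          gene_id = gid, symbol = rows$.name[1],
          biotype = normalize_biotype(rows$.biotype[1]),
          contig = rows$seqnames[1], strand = rows$strand[1],
          start = min(rows$start), end = max(rows$end),
          stringsAsFactors = FALSE))
      }
    }
  } else {
    gdf <- df[is_gene, ]
    genes <- data.frame(gene_id = gdf$.id, symbol = gdf$.name,
                        biotype = normalize_biotype(
                          ifelse(gdf$type == "pseudogene", "pseudogene", gdf$.biotype)),
                        contig = gdf$seqnames, strand = gdf$strand,
                        start = gdf$start, end = gdf$end,
                        stringsAsFactors = FALSE)
    tdf <- df[is_tx, ]
    transcripts <- data.frame(transcript_id = tdf$.id, gene_id = tdf$.parent,
                              stringsAsFactors = FALSE)
    fdf <- df[df$type %in% names(type_map), ]
    features <- data.frame(transcript_id = fdf$.parent,
                           type = unname(type_map[fdf$type]),
                           start = fdf$start, end = fdf$end,
                           phase = suppressWarnings(as.integer(as.character(fdf$phase))),
                           stringsAsFactors = FALSE)
    # orphan transcripts: synthesize a single-transcript gene
    orphan <- transcripts$transcript_id[is.na(transcripts$gene_id) |
                                          !transcripts$gene_id %in% genes$gene_id]
    if (length(orphan)) {
      warning("synthesizing gene(s) for orphan transcript(s): ",
              paste(orphan, collapse = ", "))
      for (tx in orphan) {
        row <- tdf[tdf$.id == tx, ][1, ]
        gid <- paste0("gene:", tx)
        genes <- rbind(genes, data.frame(
          gene_id = gid, symbol = row$.name,
          biotype = normalize_biotype(row$.biotype),
          contig = row$seqnames, strand = row$strand,
          start = row$start, end = row$end, stringsAsFactors = FALSE))
        transcripts$gene_id[transcripts$transcript_id == tx] <- gid
      }
    }
  }
  gene_model_set(genes, transcripts, features)
}

#' Write a gene-model set as GFF3
#' @param gms a [gene_model_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(gms, path) {
  lines <- "##gff-version 3"
  rev_type <- c(exon = "exon", cds = "CDS",
                utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")
  for (i in seq_len(nrow(gms$genes))) {
    g <- gms$genes[i, ]
    lines <- c(lines, sprintf(
      "%s\trnaeditome\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;biotype=%s",
      g$contig, g$start, g$end, g$strand, g$gene_id,
      ifelse(is.na(g$symbol), g$gene_id, g$symbol), g$biotype))
    txs <- gms$transcripts[gms$transcripts$gene_id == g$gene_id, ]
    for (tx in txs$transcript_id) {
      f <- gms$features[gms$features$transcript_id == tx, ]
      lines <- c(lines, sprintf(
        "%s\trnaeditome\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$contig, min(f$start), max(f$end), g$strand, tx, g$gene_id))
      lines <- c(lines, sprintf(
        "%s\trnaeditome\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;Parent=%s",
        g$contig, rev_type[f$type], f$start, f$end, g$strand,
        ifelse(f$type == "cds" & !is.na(f$phase), as.character(f$phase), "."),
        paste0(tx, ":", f$type, ":", seq_len(nrow(f))), tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

gene_granges <- function(gms) {
  g <- gms$genes
  GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start, g$end),
                         strand = g$strand, gene_id = g$gene_id,
                         symbol = g$symbol, biotype = g$biotype)
}

#' Intron intervals of every transcript
#'
#' Gaps between consecutive sorted exons, per transcript.
#' @param gms a [gene_model_set()].
#' @return data.frame with columns `transcript_id`, `gene_id`, `contig`,
#'   `strand`, `start`, `end` (1-based inclusive intron bounds).
#' @export
transcript_introns <- function(gms) {
  ex <- gms$features[gms$features$type == "exon", ]
  out <- lapply(split(ex, ex$transcript_id), function(f) {
    if (nrow(f) < 2L) return(NULL)
    f <- f[order(f$start), ]
    data.frame(transcript_id = f$transcript_id[1], gene_id = f$gene_id[1],
               contig = f$contig[1], strand = f$strand[1],
               start = f$end[-nrow(f)] + 1L, end = f$start[-1L] - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), gene_id = character(),
                      contig = character(), strand = character(),
                      start = integer(), end = integer())
  rownames(out) <- NULL
  out
}
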