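#' Read a bismark-coverage-style count table
#'
#' The coverage dialect is a headerless tab-separated file with columns
#' chrom, start, end, percent methylation, count methylated, count
#' unmethylated, one row per covered CpG.  The classic dialect is
#' 1-based inclusive (`start == end ==` the C coordinate); some
#' exporters write 0-based starts.  The dialect is selected explicitly
#' -- no autodetection.
#'
#' @param path File path.
#' @param zero_based `TRUE` when the start column is 0-based.
#' @return A data.frame with columns `chrom`, `pos` (1-based C
#'   coordinate), `count_meth`, `count_unmeth`, `count_total`.
#' @export
read_bismark_cov <- function(path, zero_based = FALSE) {
  df <- read.table(
    path, sep = "\t", header = FALSE,
    col.names = c("chrom", "start", "end", "pct", "count_meth", "count_unmeth"),
    colClasses = c("character", "integer", "integer", "numeric", "integer", "integer")
  )
  pos <- if (zero_based) df$start + 1L else df$start
  out <- data.frame(
    chrom = df$chrom, pos = pos,
    count_meth = df$count_meth, count_unmeth = df$count_unmeth,
    count_total = df$count_meth + df$count_unmeth,
    stringsAsFactors = FALSE
  )
  if (any(out$count_total < out$count_meth)) {
    stop("methylated counts exceed totals in ", path)
  }
  out
}

#' Write a bismark-coverage-style count table
#'
#' @param counts A count table as returned by [read_bismark_cov()].
#' @param path Output path.
#' @export
write_bismark_cov <- function(counts, path) {
  pct <- ifelse(
    counts$count_total > 0,
    100 * counts$count_meth / counts$count_total, 0
  )
  df <- data.frame(
    counts$chrom, counts$pos, counts$pos,
    pct, counts$count_meth,
    counts$count_total - counts$count_meth
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write fragments as BED4
#'
#' 0-based half-open coordinates with the fragment id in the name field.
#'
#' @param fragments `GRanges` of fragments.
#' @param path Output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  df <- data.frame(
    as.character(GenomicRanges::seqnames(fragments)),
    GenomicRanges::start(fragments) - 1L,
    GenomicRanges::end(fragments),
    fragments$fragment_id
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an annotation track as BED6
#'
#' The name field carries the interval label (for repeat tracks,
#' `"class/family"`).
#'
#' @param track `GRanges` with a `name` metadata column (or `class` and
#'   `family` columns, joined with `/`).
#' @param path Output path.
#' @export
write_track_bed <- function(track, path) {
  nm <- if (!is.null(track$name)) {
    track$name
  } else if (!is.null(track$class)) {
    paste0(track$class, "/", track$family)
  } else {
    rep(".", length(track))
  }
  strand <- as.character(GenomicRanges::strand(track))
  strand[strand == "*"] <- "."
  df <- data.frame(
    as.character(GenomicRanges::seqnames(track)),
    GenomicRanges::start(track) - 1L,
    GenomicRanges::end(track),
    nm, 0L, strand
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED track into GRanges
#'
#' Reads BED4/BED6; for repeat tracks a `"class/family"` name field is
#' split into `class` and `family` metadata columns.
#'
#' @param path File path.
#' @param repeat_names Split the name field at `/` into class/family.
#' @return A `GRanges` with `name` (and optionally `class`, `family`).
#' @export
read_track_bed <- function(path, repeat_names = FALSE) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    strand = if (ncol(df) >= 6) {
      ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*")
    } else "*"
  )
  gr$name <- if (ncol(df) >= 4) as.character(df[[4]]) else "."
  if (repeat_names) {
    parts <- strsplit(gr$name, "/", fixed = TRUE)
    gr$class <- vapply(parts, `[`, character(1), 1L)
    gr$family <- vapply(parts, function(p) p[min(2L, length(p))], character(1))
  }
  gr
}
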