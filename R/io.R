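# Readers/writers for the plain-text formats the pipeline touches.
# All interval types are kept 1-based closed internally; BED and bedGraph
# files use their native 0-based half-open convention and are converted
# exactly once, here.

#' Read a Bismark-style per-cytosine methylation file
#'
#' Auto-detects the dialect by column count: 7 columns is the cytosine
#' report (chrom, pos, strand, count_meth, count_unmeth, context,
#' tricontext); 6 columns is the coverage format (chrom, start, end,
#' percent, count_meth, count_unmeth). Only CpG-context records are
#' returned (the coverage format carries no context and is assumed to be
#' CpG-filtered upstream, as Bismark's `--CX`-less default produces).
#'
#' @param path tab-separated input file.
#' @param sample_id optional label attached as an attribute.
#' @return data.frame with columns `chrom`, `pos` (1-based cytosine
#'   position), `strand`, `count_meth`, `count_unmeth`.
#' @export
read_cytosine_report <- function(path, sample_id = NULL) {
  first <- readLines(path, n = 1L)
  .assert(length(first) == 1L, "empty cytosine file: %s", path)
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               colClasses = NA, quote = "", comment.char = ""),
    error = function(e) .stopf("malformed cytosine file %s: %s", path, conditionMessage(e)))
  if (ncol == 7L) {
    names(df) <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                   "context", "tricontext")
    bad <- which(!is.finite(df$pos) | !is.finite(df$count_meth) | !is.finite(df$count_unmeth))
    .assert(length(bad) == 0L, "malformed line %d in %s", if (length(bad)) bad[1] else 0L, path)
    df <- df[df$context %in% c("CG", "CpG"), c("chrom", "pos", "strand",
                                               "count_meth", "count_unmeth")]
  } else if (ncol == 6L) {
    names(df) <- c("chrom", "start", "end", "percent", "count_meth", "count_unmeth")
    bad <- which(!is.finite(df$start) | !is.finite(df$count_meth) | !is.finite(df$count_unmeth))
    .assert(length(bad) == 0L, "malformed line %d in %s", if (length(bad)) bad[1] else 0L, path)
    df <- data.frame(chrom = df$chrom, pos = df$start + 1L, strand = "+",
                     count_meth = df$count_meth, count_unmeth = df$count_unmeth,
                     stringsAsFactors = FALSE)
  } else {
    .stopf("unsupported cytosine dialect (%d columns) in %s", ncol, path)
  }
  .assert(all(df$count_meth >= 0 & df$count_unmeth >= 0),
          "negative count in %s", path)
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  df
}

#' Write CpG records as a Bismark cytosine report
#'
#' @param records data.frame as returned by [read_cytosine_report()].
#' @param path output file (7-column cytosine-report dialect, context
#'   `CG`, tricontext `CGN`).
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  out <- data.frame(records$chrom, records$pos, records$strand,
                    records$count_meth, records$count_unmeth, "CG", "CGN")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph signal track
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open,
#'   as in the file), `value`; sorted, with overlapping intervals on one
#'   chromosome rejected as ambiguous signal.
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "#")
  .assert(ncol(df) == 4L, "bedGraph must have 4 columns: %s", path)
  names(df) <- c("chrom", "start", "end", "value")
  .assert(all(df$end > df$start), "empty interval in %s", path)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  sp <- split(seq_len(nrow(df)), df$chrom)
  for (idx in sp) {
    if (length(idx) > 1L) {
      .assert(all(df$start[idx][-1] >= df$end[idx][-length(idx)]),
              "overlapping bedGraph intervals on %s in %s", df$chrom[idx[1]], path)
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a signal track as bedGraph
#'
#' Round-trips with [read_bedgraph()]: coordinates and scores are
#' preserved exactly.
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- data.frame(track$chrom, format(track$start, scientific = FALSE, trim = TRUE),
                    format(track$end, scientific = FALSE, trim = TRUE),
                    vapply(track$value, function(v) format(v, scientific = FALSE, trim = TRUE), ""))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (3 or more columns)
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start` (0-based), `end` (half-open),
#'   `name`, `score`; missing columns filled with `"."` / `0`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "#")
  .assert(ncol(df) >= 3L, "BED needs >= 3 columns: %s", path)
  out <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                    name = if (ncol(df) >= 4) df[[4]] else ".",
                    score = if (ncol(df) >= 5) df[[5]] else 0,
                    stringsAsFactors = FALSE)
  .assert(all(out$end > out$start), "empty interval in %s", path)
  out
}

#' Write intervals as BED
#'
#' @param records data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score` (and `strand` for BED6).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  cols <- list(records$chrom,
               format(records$start, scientific = FALSE, trim = TRUE),
               format(records$end, scientific = FALSE, trim = TRUE))
  if (!is.null(records$name) || !is.null(records$score)) {
    cols <- c(cols, list(records$name %||% ".",
                         vapply((records$score %||% 0), function(v)
                           format(v, scientific = FALSE, trim = TRUE), "")))
    if (!is.null(records$strand)) cols <- c(cols, list(records$strand))
  }
  write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a header-ed TSV table
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "")
}

#' Write a header-ed TSV table
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) .write_tsv(df, path)

# 1-based closed view of a bedGraph data.frame, for internal lookup.
.track_internal <- function(track) {
  data.frame(chrom = track$chrom, start1 = track$start + 1L, end1 = track$end,
             value = track$value, stringsAsFactors = FALSE)
}
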