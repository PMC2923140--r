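#' Construct a table of genomic intervals
#'
#' Genomic intervals are the universal currency of the package: peaks,
#' subpeaks, merged regions and randomized placements are all interval
#' tables. Coordinates are 0-based half-open throughout: `start` is the
#' first base of the interval and `end` is one past the last. Strand is
#' `"+"`, `"-"` or `"*"` (unstranded).
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start,end Integer vectors, `0 <= start < end`.
#' @param strand Character vector in `{"+", "-", "*"}`; recycled.
#' @param name Optional character vector of labels; recycled.
#' @param score Optional numeric vector; recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `score`, one row per interval.
#' @examples
#' gintervals("chr1", c(100L, 400L), c(200L, 650L))
#' @export
gintervals <- function(chrom, start, end, strand = "*", name = NA_character_,
                       score = NA_real_) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- as.character(rep_len(chrom, n))
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  strand <- as.character(rep_len(strand, n))
  name <- as.character(rep_len(name, n))
  score <- as.numeric(rep_len(score, n))
  if (n > 0L) {
    if (anyNA(start) || anyNA(end))
      stop("interval coordinates must be integers", call. = FALSE)
    if (any(!nzchar(chrom) | is.na(chrom)))
      stop("chromosome names must be non-empty", call. = FALSE)
    if (any(start < 0L))
      stop("interval start must be >= 0", call. = FALSE)
    if (any(start >= end))
      stop("intervals must satisfy start < end (empty intervals rejected)",
           call. = FALSE)
    if (!all(strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'", call. = FALSE)
  }
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             name = name, score = score, stringsAsFactors = FALSE)
}

#' @keywords internal
empty_gintervals <- function() {
  gintervals(character(0), integer(0), integer(0))
}

#' @keywords internal
as_gintervals <- function(x) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop("expected an interval table with chrom/start/end columns",
         call. = FALSE)
  gintervals(x$chrom, x$start, x$end,
             strand = if ("strand" %in% names(x)) x$strand else "*",
             name = if ("name" %in% names(x)) x$name else NA_character_,
             score = if ("score" %in% names(x)) x$score else NA_real_)
}

#' Sort an interval table by chromosome and start
#' @param x An interval table from [gintervals()].
#' @return The same table, rows ordered by `(chrom, start, end)`.
#' @export
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}
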