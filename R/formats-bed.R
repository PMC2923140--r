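#' Read a BED peak file
#'
#' Parses 3- to 6-column BED. BED coordinates are already 0-based
#' half-open and are taken verbatim. Column 4 becomes `name`, column 5
#' `score` (parsed as float, deliberately not range-checked: peak callers
#' emit arbitrary scores despite the nominal 0-1000 convention), column 6
#' `strand`. `track`, `browser` and `#` comment lines are skipped.
#' Input order is preserved.
#'
#' @param path Path to a BED file.
#' @return An interval table (see [gintervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_gintervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 lineno[which(nf < 3L)[1L]]), call. = FALSE)
  col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.integer(col(2L, NA)))
  end <- suppressWarnings(as.integer(col(3L, NA)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 lineno[which(bad)[1L]]), call. = FALSE)
  bad <- start >= end | start < 0L
  if (any(bad))
    stop(sprintf("BED parse error at line %d: start >= end or negative start",
                 lineno[which(bad)[1L]]), call. = FALSE)
  name <- col(4L, NA_character_)
  score <- suppressWarnings(as.numeric(col(5L, NA_character_)))
  strand <- col(6L, "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gintervals(col(1L, NA_character_), start, end,
             strand = strand, name = name, score = score)
}

#' Write an interval table as BED
#'
#' Emits as many columns as the data carry: 3 if no interval has a name,
#' score or strand; 6 if any does (missing names become `"."`, missing
#' scores `0`, missing strands `"."`). Round-trips through [read_bed()]
#' losslessly at base resolution.
#'
#' @param intervals Interval table from [gintervals()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  x <- as_gintervals(intervals)
  if (nrow(x) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  plain <- all(is.na(x$name)) && all(is.na(x$score)) && all(x$strand == "*")
  lines <- if (plain) {
    sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  } else {
    name <- ifelse(is.na(x$name), ".", x$name)
    score <- ifelse(is.na(x$score), "0", format_num(x$score))
    strand <- ifelse(x$strand == "*", ".", x$strand)
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
            name, score, strand)
  }
  writeLines(lines, path)
  invisible(path)
}

# print a numeric without scientific notation or trailing zeros
#' @keywords internal
format_num <- function(x) {
  out <- trimws(formatC(x, format = "fg", digits = 15))
  has_dot <- grepl(".", out, fixed = TRUE)
  out[has_dot] <- sub("\\.?0*$", "", out[has_dot])
  out
}
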