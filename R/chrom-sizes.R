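#' Load a chromosome-sizes table
#'
#' Either parses a two-column `name<TAB>length` file, or derives sizes
#' from loaded interval tables and transcript lists as the maximum end
#' coordinate observed per chromosome.
#'
#' @param ... Either a single file path, or any number of interval tables
#'   (from [gintervals()]) and transcript lists (from [read_gtf()]).
#' @return Named integer vector: chromosome name -> length in bases.
#' @export
load_chrom_sizes <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.character(args[[1L]]) &&
      length(args[[1L]]) == 1L) {
    path <- args[[1L]]
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(structure(integer(0), names = character(0)))
    fields <- strsplit(lines, "[ \t]+")
    if (any(lengths(fields) < 2L))
      stop("chrom.sizes parse error: expected 'name<TAB>length' lines",
           call. = FALSE)
    nm <- vapply(fields, `[[`, "", 1L)
    len <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    if (any(is.na(len) | len <= 0L))
      stop("chrom.sizes parse error: non-positive length", call. = FALSE)
    return(structure(len, names = nm))
  }
  sizes <- structure(integer(0), names = character(0))
  bump <- function(chrom, end) {
    for (cn in unique(chrom)) {
      m <- max(end[chrom == cn])
      sizes[cn] <<- max(m, sizes[cn][1L], na.rm = TRUE)
    }
  }
  for (a in args) {
    if (is.data.frame(a)) {
      if (nrow(a)) bump(a$chrom, a$end)
    } else if (is.list(a)) {
      if (length(a)) {
        sp <- transcript_spans(a)
        bump(sp$chrom, sp$end)
      }
    } else stop("cannot derive chromosome sizes from a ", class(a)[1L],
                call. = FALSE)
  }
  storage.mode(sizes) <- "integer"
  sizes
}

#' Write a chromosome-sizes table
#' @param sizes Named integer vector (chromosome -> length).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), sizes), path)
  invisible(path)
}
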