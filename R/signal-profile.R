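#' @title Signal profiles
#' @description A signal profile is a sparse per-chromosome map from
#'   0-based base position to read depth (a non-negative float; floats
#'   support tiling-array fluorescence tracks as well as integral read
#'   counts). Querying any interval yields a dense depth vector with 0 at
#'   uncovered bases.
#' @name signal_profile
NULL

#' Build a signal profile from positions and depths
#'
#' @param chrom,pos,depth Parallel vectors: chromosome name, 0-based base
#'   position, depth at that base. Later entries overwrite earlier ones at
#'   the same base (with a warning), matching the parser's last-writer-wins
#'   rule for colliding WIG blocks.
#' @return An object of class `"signal_profile"`.
#' @export
signal_profile <- function(chrom = character(0), pos = integer(0),
                           depth = numeric(0)) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(depth))
  if (any(depth < 0)) stop("signal depth must be >= 0", call. = FALSE)
  if (any(pos < 0)) stop("signal positions must be >= 0", call. = FALSE)
  chroms <- list()
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    p <- as.integer(pos[i])
    d <- as.numeric(depth[i])
    dup <- duplicated(p, fromLast = TRUE)
    if (any(dup)) {
      coll <- p[dup]
      keep <- !dup
      # only warn when the overwritten value actually differs
      old <- d[dup]
      new <- d[keep][match(coll, p[keep])]
      if (any(old != new))
        warning(sprintf(
          "signal values collide at %d base(s) on %s; keeping the last",
          sum(old != new), cn), call. = FALSE)
      p <- p[keep]
      d <- d[keep]
    }
    o <- order(p)
    chroms[[cn]] <- list(pos = p[o], depth = d[o])
  }
  structure(list(chroms = chroms), class = "signal_profile")
}

#' Query a signal profile over an interval
#'
#' @param profile A `"signal_profile"`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open span to query.
#' @return Numeric vector of length `end - start`; 0 at uncovered bases
#'   (an unknown chromosome yields all zeros).
#' @export
signal_query <- function(profile, chrom, start, end) {
  stopifnot(inherits(profile, "signal_profile"), start >= 0, end > start)
  out <- numeric(end - start)
  tr <- profile$chroms[[chrom]]
  if (is.null(tr)) return(out)
  lo <- findInterval(start - 1L, tr$pos) + 1L
  hi <- findInterval(end - 1L, tr$pos)
  if (lo > hi) return(out)
  idx <- lo:hi
  out[tr$pos[idx] - start + 1L] <- tr$depth[idx]
  out
}

#' @export
print.signal_profile <- function(x, ...) {
  nb <- vapply(x$chroms, function(tr) length(tr$pos), 0L)
  cat(sprintf("<signal_profile: %d chromosome(s), %d covered base(s)>\n",
              length(x$chroms), sum(nb)))
  invisible(x)
}

#' Read a WIG signal track
#'
#' Accepts any mix of `fixedStep` blocks, `variableStep` blocks and bare
#' bedGraph data lines (`chrom\tstart\tend\tvalue`) in one file. WIG
#' positions are 1-based and converted to the internal 0-based convention;
#' `span` and `step` are expanded to per-base depths. bedGraph intervals
#' are already 0-based half-open and taken verbatim. Where blocks collide
#' on a base, the later value wins.
#'
#' @param path Path to the signal file.
#' @return A `"signal_profile"`.
#' @export
read_wig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  chrom_v <- character(0); pos_v <- integer(0); depth_v <- numeric(0)
  # accumulate chunks, concatenating once at the end
  acc <- list(); nacc <- 0L
  push <- function(chrom, pos, depth) {
    nacc <<- nacc + 1L
    acc[[nacc]] <<- list(chrom = chrom, pos = pos, depth = depth)
  }
  mode <- NULL; cur_chrom <- NULL; cur_pos <- NA_integer_
  step <- 1L; span <- 1L
  i <- 0L
  for (line in lines) {
    i <- i + 1L
    line <- trimws(line)
    if (!nzchar(line) || grepl("^(track|browser|#)", line)) next
    if (grepl("^fixedStep", line) || grepl("^variableStep", line)) {
      kv <- wig_directive(line, i)
      mode <- kv$mode; cur_chrom <- kv$chrom
      span <- kv$span; step <- kv$step; cur_pos <- kv$start
      next
    }
    parts <- strsplit(line, "[ \t]+")[[1L]]
    if (length(parts) == 4L) {
      # bedGraph data line (fixedStep lines have 1 field, variableStep 2)
      s <- suppressWarnings(as.integer(parts[2L]))
      e <- suppressWarnings(as.integer(parts[3L]))
      v <- suppressWarnings(as.numeric(parts[4L]))
      if (is.na(s) || is.na(e) || is.na(v) || s < 0L || s >= e)
        stop(sprintf("WIG parse error at line %d: bad bedGraph record", i),
             call. = FALSE)
      if (v < 0) stop(sprintf(
        "WIG parse error at line %d: negative depth", i), call. = FALSE)
      push(parts[1L], s:(e - 1L), rep(v, e - s))
      next
    }
    if (identical(mode, "fixed")) {
      v <- suppressWarnings(as.numeric(parts[1L]))
      if (length(parts) != 1L || is.na(v))
        stop(sprintf("WIG parse error at line %d: expected one value", i),
             call. = FALSE)
      if (v < 0) stop(sprintf(
        "WIG parse error at line %d: negative depth", i), call. = FALSE)
      push(cur_chrom, cur_pos:(cur_pos + span - 1L), rep(v, span))
      cur_pos <- cur_pos + step
    } else if (identical(mode, "variable")) {
      p <- suppressWarnings(as.integer(parts[1L]))
      v <- suppressWarnings(as.numeric(parts[2L]))
      if (length(parts) != 2L || is.na(p) || is.na(v) || p < 1L)
        stop(sprintf("WIG parse error at line %d: expected 'pos value'", i),
             call. = FALSE)
      if (v < 0) stop(sprintf(
        "WIG parse error at line %d: negative depth", i), call. = FALSE)
      p0 <- p - 1L  # 1-based -> 0-based
      push(cur_chrom, p0:(p0 + span - 1L), rep(v, span))
    } else {
      stop(sprintf("WIG parse error at line %d: data before any directive", i),
           call. = FALSE)
    }
  }
  if (nacc > 0L) {
    chrom_v <- unlist(lapply(acc, function(a) rep(a$chrom, length(a$pos))))
    pos_v <- unlist(lapply(acc, `[[`, "pos"))
    depth_v <- unlist(lapply(acc, `[[`, "depth"))
  }
  signal_profile(chrom_v, pos_v, depth_v)
}

#' @keywords internal
wig_directive <- function(line, lineno) {
  mode <- if (grepl("^fixedStep", line)) "fixed" else "variable"
  kv <- regmatches(line, gregexpr("[A-Za-z]+=[^ \t]+", line))[[1L]]
  keys <- sub("=.*", "", kv)
  vals <- sub("^[^=]+=", "", kv)
  get <- function(k, default = NA) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  chrom <- get("chrom")
  if (is.na(chrom))
    stop(sprintf("WIG parse error at line %d: directive lacks chrom", lineno),
         call. = FALSE)
  span <- suppressWarnings(as.integer(get("span", "1")))
  if (is.na(span) || span < 1L)
    stop(sprintf("WIG parse error at line %d: bad span", lineno),
         call. = FALSE)
  if (mode == "fixed") {
    start1 <- suppressWarnings(as.integer(get("start")))
    step <- suppressWarnings(as.integer(get("step", "1")))
    if (is.na(start1) || start1 < 1L)
      stop(sprintf("WIG parse error at line %d: fixedStep needs start >= 1",
                   lineno), call. = FALSE)
    if (is.na(step) || step < 1L)
      stop(sprintf("WIG parse error at line %d: bad step", lineno),
           call. = FALSE)
    list(mode = mode, chrom = chrom, span = span, step = step,
         start = start1 - 1L)  # 1-based -> 0-based
  } else {
    list(mode = mode, chrom = chrom, span = span, step = 1L,
         start = NA_integer_)
  }
}

#' Write a signal profile as fixedStep WIG
#'
#' Covered bases are emitted as step-1 `fixedStep` blocks, one block per
#' run of contiguous coverage. Round-trips through [read_wig()].
#'
#' @param profile A `"signal_profile"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wig <- function(profile, path) {
  stopifnot(inherits(profile, "signal_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(profile$chroms)) {
    tr <- profile$chroms[[cn]]
    if (length(tr$pos) == 0L) next
    breaks <- c(0L, which(diff(tr$pos) != 1L), length(tr$pos))
    for (b in seq_len(length(breaks) - 1L)) {
      idx <- (breaks[b] + 1L):breaks[b + 1L]
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                         cn, tr$pos[idx[1L]] + 1L), con)
      writeLines(format_num(tr$depth[idx]), con)
    }
  }
  invisible(path)
}
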