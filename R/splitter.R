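#' Splitter configuration
#'
#' @param valley_factor Multiplier in `(0, 1]` applied to the lower of
#'   two adjacent local maxima; the valley between them must dip below
#'   the product for a subpeak division. Default 0.6, a midrange value
#'   that separates clearly distinct summits without fragmenting
#'   plateaus.
#' @param min_height Minimum summit depth for a subpeak to be retained;
#'   default 0 (no filtering).
#' @param summit_flank Bases on each side of a summit when emitting
#'   summit windows for sequence extraction; default 100.
#' @return A list of class `"splitter_config"`.
#' @export
splitter_config <- function(valley_factor = 0.6, min_height = 0,
                            summit_flank = 100L) {
  if (!is.numeric(valley_factor) || valley_factor <= 0 || valley_factor > 1)
    stop("valley_factor must be in (0, 1]", call. = FALSE)
  if (min_height < 0) stop("min_height must be >= 0", call. = FALSE)
  if (summit_flank < 0) stop("summit_flank must be >= 0", call. = FALSE)
  structure(list(valley_factor = valley_factor, min_height = min_height,
                 summit_flank = as.integer(summit_flank)),
            class = "splitter_config")
}

#' Local maxima of a depth vector
#'
#' A position is a local maximum iff its depth is greater than or equal
#' to both flanking non-equal depths; boundary positions compare only
#' inward. Each maximal plateau is represented once, at its leftmost
#' offset. Zero-depth positions are never maxima, so an all-zero vector
#' has none.
#'
#' @param depths Non-empty numeric vector of per-base depths.
#' @return Two-column matrix `(offset, height)` with 1-based offsets into
#'   `depths`, in increasing offset order; zero rows if no maxima.
#' @export
find_local_maxima <- function(depths) {
  stopifnot(length(depths) >= 1L, is.numeric(depths))
  # run-length encode plateaus, then compare each run with its neighbours
  r <- rle(depths)
  v <- r$values
  nr <- length(v)
  left_ok <- c(TRUE, v[-1L] > v[-nr])    # first run, or higher than left
  right_ok <- c(v[-nr] > v[-1L], TRUE)   # last run, or higher than right
  is_max <- left_ok & right_ok & v > 0
  run_start <- cumsum(c(1L, r$lengths[-nr]))
  cbind(offset = run_start[is_max], height = v[is_max])
}

#' Split one peak into subpeaks
#'
#' Local maxima of the depth profile over the peak are scanned left to
#' right. For each adjacent pair the lower height is multiplied by
#' `valley_factor` to obtain the depth required for subpeak division: if
#' the minimum depth on the open interval between the two maxima falls
#' below that threshold, the peak is cut at that minimum (the leftmost
#' deepest base on ties), the valley base joining the right-hand subpeak.
#' Maxima not separated by a qualifying valley merge into one subpeak.
#' Before `min_height` filtering the subpeaks tile the parent peak
#' exactly; filtering then drops subpeaks whose summit depth is below
#' `min_height`.
#'
#' @param peak One-row interval table.
#' @param signal A [signal_profile()].
#' @param cfg A [splitter_config()].
#' @param parent_id Label for the parent peak (defaults to its name).
#' @return Interval table of subpeaks with columns `parent_id`, `summit`
#'   (0-based genomic position of maximum depth) and `score` (= summit
#'   height); zero rows, with a warning, if the peak has no coverage.
#' @export
split_peak <- function(peak, signal, cfg = splitter_config(),
                       parent_id = NULL) {
  p <- as_gintervals(peak)
  stopifnot(nrow(p) == 1L)
  if (is.null(parent_id))
    parent_id <- if (!is.na(p$name)) p$name else "peak"
  d <- signal_query(signal, p$chrom, p$start, p$end)
  maxima <- find_local_maxima(d)
  if (nrow(maxima) == 0L) {
    warning(sprintf("peak %s %s:[%d,%d) has no signal coverage; no subpeaks",
                    parent_id, p$chrom, p$start, p$end), call. = FALSE)
    out <- empty_gintervals()
    out$parent_id <- character(0)
    out$summit <- integer(0)
    return(out)
  }
  cuts <- integer(0)  # offsets where a new subpeak begins
  if (nrow(maxima) > 1L) {
    for (k in seq_len(nrow(maxima) - 1L)) {
      m1 <- maxima[k, ]; m2 <- maxima[k + 1L, ]
      between <- (m1[["offset"]] + 1L):(m2[["offset"]] - 1L)
      if (m1[["offset"]] + 1L > m2[["offset"]] - 1L) next  # adjacent plateaus
      valley <- min(d[between])
      threshold <- cfg$valley_factor * min(m1[["height"]], m2[["height"]])
      if (valley < threshold) {
        cut <- between[which.max(d[between] == valley)]  # leftmost deepest
        cuts <- c(cuts, cut)
      }
    }
  }
  bounds <- c(1L, cuts, length(d) + 1L)
  n <- length(bounds) - 1L
  sp_start <- sp_end <- summit <- integer(n)
  height <- numeric(n)
  for (k in seq_len(n)) {
    lo <- bounds[k]; hi <- bounds[k + 1L] - 1L
    seg <- d[lo:hi]
    smt <- lo + which.max(seg) - 1L  # leftmost max on ties
    sp_start[k] <- p$start + lo - 1L
    sp_end[k] <- p$start + hi
    summit[k] <- p$start + smt - 1L
    height[k] <- d[smt]
  }
  keep <- height >= cfg$min_height
  if (!any(keep)) {
    out <- empty_gintervals()
    out$parent_id <- character(0)
    out$summit <- integer(0)
    return(out)
  }
  out <- gintervals(p$chrom, sp_start[keep], sp_end[keep],
                    name = paste0(parent_id, "/", seq_len(n)[keep]),
                    score = height[keep])
  out$parent_id <- rep(as.character(parent_id), sum(keep))
  out$summit <- summit[keep]
  out
}

#' Split every peak of a dataset
#'
#' @param peaks Interval table of peaks; `parent_id` is the peak name or,
#'   when unnamed, the 1-based ordinal in the file.
#' @param signal A [signal_profile()].
#' @param cfg A [splitter_config()].
#' @return Interval table of subpeaks as in [split_peak()], sorted by
#'   `(chrom, start)`.
#' @export
split_all <- function(peaks, signal, cfg = splitter_config()) {
  p <- as_gintervals(peaks)
  parts <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    pid <- if (!is.na(p$name[i])) p$name[i] else as.character(i)
    parts[[i]] <- split_peak(p[i, ], signal, cfg, parent_id = pid)
  }
  out <- if (length(parts)) do.call(rbind, parts) else {
    z <- empty_gintervals(); z$parent_id <- character(0)
    z$summit <- integer(0); z
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Summit windows for sequence extraction
#'
#' Each subpeak summit is expanded to
#' `[summit - flank, summit + flank + 1)`, clipped to chromosome bounds.
#'
#' @param subpeaks Output of [split_all()].
#' @param cfg A [splitter_config()] (supplies `summit_flank`).
#' @param sizes Chromosome sizes from [load_chrom_sizes()].
#' @return Interval table of windows, named `parent_id/ordinal`.
#' @export
summit_windows <- function(subpeaks, cfg = splitter_config(), sizes) {
  if (nrow(subpeaks) == 0L) return(empty_gintervals())
  len <- sizes[subpeaks$chrom]
  if (anyNA(len))
    stop("chromosome missing from sizes table: ",
         subpeaks$chrom[which(is.na(len))[1L]], call. = FALSE)
  if (any(subpeaks$summit >= len))
    stop("summit position beyond chromosome length", call. = FALSE)
  start <- pmax(0L, subpeaks$summit - cfg$summit_flank)
  end <- pmin(as.integer(len), subpeaks$summit + cfg$summit_flank + 1L)
  gintervals(subpeaks$chrom, start, end, name = subpeaks$name,
             score = subpeaks$score)
}
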