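#' Overlapping loci between two peak datasets
#'
#' Reports every pair of intervals from `s1` and `s2` intersecting by at
#' least one nucleotide, on either strand (strand is ignored). Each `s1`
#' locus is matched through a containment-list query on `s2`: a binary
#' search finds the run of `s2` primaries around the locus and descends
#' into their sublists, so an `s2` interval nested deep inside a much
#' larger one is still found.
#'
#' @param s1,s2 Interval tables (see [gintervals()]).
#' @return A list of class `"overlap_report"`: `pairs` (data.frame
#'   `i1`, `i2` of row indices into `s1` and `s2`), `n1_hit` / `n2_hit`
#'   (loci of each set with at least one partner), and the set sizes.
#' @export
overlap_pairs <- function(s1, s2) {
  a <- as_gintervals(s1)
  b <- as_gintervals(s2)
  idx <- build_index(b)
  i1 <- integer(0); i2 <- integer(0)
  for (i in seq_len(nrow(a))) {
    hits <- query_overlaps(idx, a$chrom[i], a$start[i], a$end[i])
    if (length(hits)) {
      i1 <- c(i1, rep.int(i, length(hits)))
      i2 <- c(i2, hits)
    }
  }
  structure(list(pairs = data.frame(i1 = i1, i2 = i2),
                 n1_hit = length(unique(i1)), n2_hit = length(unique(i2)),
                 n1 = nrow(a), n2 = nrow(b)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap: %d pair(s); %d/%d of set 1 and %d/%d of set 2 hit>\n",
    nrow(x$pairs), x$n1_hit, x$n1, x$n2_hit, x$n2))
  invisible(x)
}

#' Non-redundant union of several peak datasets
#'
#' Merges the intervals of all datasets wherever they intersect by at
#' least one base; each merged region records which datasets contributed
#' to it.
#'
#' @param datasets Named (or unnamed) list of interval tables.
#' @return Interval table of disjoint merged regions, sorted, with one
#'   logical membership column per dataset.
#' @export
merge_union <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  nm <- names(datasets)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("set", seq_along(datasets))
  all <- do.call(rbind, lapply(datasets, function(d)
    as_gintervals(d)[, c("chrom", "start", "end")]))
  if (nrow(all) == 0L) {
    out <- empty_gintervals()
    for (k in nm) out[[k]] <- logical(0)
    return(out)
  }
  merged <- list()
  for (cn in sort(unique(all$chrom))) {
    x <- all[all$chrom == cn, , drop = FALSE]
    # min.gapwidth = 0: merge on intersection only, never across adjacency
    ir <- IRanges::reduce(IRanges::IRanges(start = x$start + 1L, end = x$end),
                          min.gapwidth = 0L)
    merged[[cn]] <- gintervals(cn, IRanges::start(ir) - 1L, IRanges::end(ir))
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  for (k in seq_along(datasets)) {
    d <- as_gintervals(datasets[[k]])
    member <- logical(nrow(out))
    if (nrow(d)) {
      for (cn in unique(out$chrom)) {
        oi <- which(out$chrom == cn)
        di <- d$chrom == cn
        if (!any(di)) next
        ir_o <- IRanges::IRanges(start = out$start[oi] + 1L,
                                 end = out$end[oi])
        ir_d <- IRanges::IRanges(start = d$start[di] + 1L,
                                 end = d$end[di])
        member[oi] <- IRanges::countOverlaps(ir_o, ir_d) > 0L
      }
    }
    out[[nm[k]]] <- member
  }
  out
}

#' Randomization configuration for the overlap enrichment test
#'
#' @param sizes Chromosome sizes (named integer vector, see
#'   [load_chrom_sizes()]).
#' @param iterations Number of Monte-Carlo iterations; default 1000.
#' @param seed Optional integer seed; when given, results are
#'   reproducible.
#' @return A list of class `"randomization_config"`.
#' @export
randomization_config <- function(sizes, iterations = 1000L, seed = NULL) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("iterations must be >= 1", call. = FALSE)
  structure(list(sizes = sizes, iterations = iterations, seed = seed),
            class = "randomization_config")
}

#' Random peak placement preserving lengths and chromosomes
#'
#' Generates one artificial locus per input locus with the same
#' chromosome and the same length, the start drawn uniformly on
#' `[0, chrom_length - length]`. The output therefore matches the
#' experimental dataset's peak lengths and chromosomal distribution
#' exactly; placements are independent and may overlap each other.
#'
#' @param s Interval table.
#' @param cfg A [randomization_config()] (supplies sizes and seed).
#' @return Interval table of randomized loci, same row count and order.
#' @export
randomize_peaks <- function(s, cfg) {
  x <- as_gintervals(s)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  len <- x$end - x$start
  chrom_len <- cfg$sizes[x$chrom]
  if (anyNA(chrom_len))
    stop("chromosome missing from sizes table: ",
         x$chrom[which(is.na(chrom_len))[1L]], call. = FALSE)
  if (any(len > chrom_len))
    stop("interval longer than its chromosome", call. = FALSE)
  # uniform integer start on [0, chrom_len - len]
  start <- as.integer(floor(stats::runif(nrow(x)) * (chrom_len - len + 1)))
  start <- pmin(start, as.integer(chrom_len - len))  # guard runif() == 1
  gintervals(x$chrom, start, start + len, name = x$name)
}

# fast any-overlap hit counter: how many intervals of `x` intersect the
# union of `s2`; agreement with overlap_pairs()$n1_hit is tested
#' @keywords internal
hit_counter <- function(s2) {
  b <- as_gintervals(s2)
  per_chrom <- list()
  for (cn in unique(b$chrom)) {
    i <- b$chrom == cn
    ir <- IRanges::reduce(IRanges::IRanges(start = b$start[i] + 1L,
                                           end = b$end[i]),
                          min.gapwidth = 0L)
    per_chrom[[cn]] <- list(start = IRanges::start(ir) - 1L,
                            end = IRanges::end(ir))
  }
  function(chrom, start, end) {
    hits <- 0L
    for (cn in unique(chrom)) {
      u <- per_chrom[[cn]]
      if (is.null(u)) next
      i <- chrom == cn
      # an interval hits iff the last union block starting before its end
      # also ends after its start
      k <- findInterval(end[i] - 1L, u$start)
      ok <- k >= 1L & u$end[pmax(k, 1L)] > start[i]
      hits <- hits + sum(ok)
    }
    hits
  }
}

#' Monte-Carlo enrichment P-value of dataset overlap
#'
#' The observed statistic is the number of `s1` loci intersecting `s2`
#' by at least one base. Under the null, `s1` is replaced by artificial
#' datasets with matching peak lengths and chromosomal distribution
#' (see [randomize_peaks()]); the add-one estimator
#' `p = (1 + #\{i: n_i >= observed\}) / (iterations + 1)` guarantees
#' `p` in `(0, 1]`, so with 1000 iterations the smallest reportable
#' P-value is 1/1001.
#'
#' @param s1,s2 Interval tables; `s1` is the randomized set.
#' @param cfg A [randomization_config()].
#' @return A list of class `"overlap_pvalue"`: `observed` (hit count),
#'   `p_value`, `iterations`, `null_hits` (the Monte-Carlo draws).
#' @export
overlap_pvalue <- function(s1, s2, cfg) {
  stopifnot(inherits(cfg, "randomization_config"))
  x <- as_gintervals(s1)
  observed <- overlap_pairs(x, s2)$n1_hit
  count_hits <- hit_counter(s2)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  len <- x$end - x$start
  chrom_len <- cfg$sizes[x$chrom]
  if (anyNA(chrom_len))
    stop("chromosome missing from sizes table: ",
         x$chrom[which(is.na(chrom_len))[1L]], call. = FALSE)
  if (any(len > chrom_len))
    stop("interval longer than its chromosome", call. = FALSE)
  null_hits <- integer(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    start <- as.integer(floor(stats::runif(nrow(x)) * (chrom_len - len + 1)))
    start <- pmin(start, as.integer(chrom_len - len))
    null_hits[it] <- count_hits(x$chrom, start, start + len)
  }
  p <- (1 + sum(null_hits >= observed)) / (cfg$iterations + 1)
  structure(list(observed = observed, p_value = p,
                 iterations = cfg$iterations, null_hits = null_hits),
            class = "overlap_pvalue")
}

#' @export
print.overlap_pvalue <- function(x, ...) {
  cat(sprintf("<overlap enrichment: observed = %d, P = %.4g (%d iterations)>\n",
              x$observed, x$p_value, x$iterations))
  invisible(x)
}
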