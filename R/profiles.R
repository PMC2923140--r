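#' Distance profile of TSS annotations
#'
#' Bins peak-to-TSS distances into labelled upstream/downstream shells
#' around the TSS, with an innermost "within gene" class for peaks whose
#' centre falls inside the reported transcript. Defaults reproduce the
#' conventional proximal/distal breakdown: 0-1 kb, 1-10 kb and >10 kb on
#' each side.
#'
#' @param results Either a list of `"tss_result"` objects or a
#'   data.frame with columns `signed_distance` and `within_gene` (as
#'   produced by [annotate_peaks()] with `utility = "TSS"`).
#' @param edges Increasing positive distances delimiting the shells;
#'   default `c(1000, 10000)`.
#' @return A data.frame `bin`, `count`, `percent`; percentages sum to
#'   100 up to rounding (all-zero for empty input). Peaks with no
#'   annotation (`NA` distance) are counted in an `unannotated` bin.
#' @export
profile_distances <- function(results, edges = c(1000L, 10000L)) {
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0))
    stop("bin edges must be strictly increasing and positive", call. = FALSE)
  if (is.data.frame(results)) {
    d <- results$signed_distance
    wg <- results$within_gene
  } else {
    d <- vapply(results, function(r)
      if (is.null(r$transcript)) NA_integer_ else r$signed_distance, 0L)
    wg <- vapply(results, function(r)
      if (is.null(r$transcript)) NA else r$within_gene, NA)
  }
  shell_labels <- function(side) {
    lo <- c(0, edges[-length(edges)])
    lab <- sprintf("%s %s-%s", side, format_kb(lo), format_kb(edges))
    c(lab, sprintf("%s >%s", side, format_kb(edges[length(edges)])))
  }
  bins <- c(rev(shell_labels("upstream")), "within gene",
            shell_labels("downstream"), "unannotated")
  assign_bin <- function(dist, within) {
    if (is.na(dist)) return("unannotated")
    if (isTRUE(within)) return("within gene")
    side <- if (dist >= 0) "downstream" else "upstream"
    a <- abs(dist)
    shell <- findInterval(a, edges, left.open = TRUE) + 1L
    labs <- shell_labels(side)
    labs[min(shell, length(labs))]
  }
  lab <- vapply(seq_along(d), function(i) assign_bin(d[i], wg[i]), "")
  count <- vapply(bins, function(b) sum(lab == b), 0L)
  n <- length(d)
  data.frame(bin = bins, count = unname(count),
             percent = if (n) unname(100 * count / n) else rep(0, length(bins)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @keywords internal
format_kb <- function(x) {
  ifelse(x >= 1000 & x %% 1000 == 0, paste0(x / 1000, "kb"), paste0(x, "bp"))
}

#' Component profile of within-gene annotations
#'
#' Groups component classifications (see [classify_overlap()]) into the
#' conventional categories: 5' UTR, exonic CDS, 3' UTR, first intron,
#' last intron, and higher rank-order introns (ranks strictly between
#' first and last). A transcript's only intron counts as its first.
#' Upstream/downstream classes, when present, are kept as their own
#' categories.
#'
#' @param classes List of `"component_class"` objects, or a character
#'   vector of formatted components such as `"intron(2)"` together with
#'   `n_introns`.
#' @param n_introns Integer vector parallel to `classes` when `classes`
#'   is character.
#' @return A data.frame `component`, `count`, `percent`; counts conserve
#'   the input size.
#' @export
profile_components <- function(classes, n_introns = NULL) {
  if (is.character(classes)) {
    stopifnot(!is.null(n_introns), length(n_introns) == length(classes))
    parsed <- lapply(seq_along(classes), function(i) {
      m <- regmatches(classes[i], regexec("^intron\\((\\d+)\\)$", classes[i]))[[1]]
      if (length(m) == 2L)
        list(type = "intron", rank = as.integer(m[2L]),
             n_introns = n_introns[i])
      else list(type = classes[i], rank = NA_integer_,
                n_introns = n_introns[i])
    })
    classes <- parsed
  }
  cats <- c("5' UTR", "exon (CDS)", "3' UTR", "first intron",
            "higher rank-order introns", "last intron",
            "upstream", "downstream")
  lab <- vapply(classes, function(x) {
    switch(x$type,
           five_prime_utr = "5' UTR",
           three_prime_utr = "3' UTR",
           exon_cds = "exon (CDS)",
           upstream = "upstream",
           downstream = "downstream",
           intron = {
             if (x$rank == 1L) "first intron"
             else if (x$rank == x$n_introns) "last intron"
             else "higher rank-order introns"
           },
           stop("unknown component type: ", x$type, call. = FALSE))
  }, "")
  count <- vapply(cats, function(b) sum(lab == b), 0L)
  keep <- count > 0L | cats %in% cats[1:6]
  n <- length(lab)
  data.frame(component = cats[keep], count = unname(count[keep]),
             percent = if (n) unname(100 * count[keep] / n)
                       else rep(0, sum(keep)),
             stringsAsFactors = FALSE, row.names = NULL)
}
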