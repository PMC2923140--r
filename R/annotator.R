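#' @title Peak-to-gene annotation
#' @description Nearest-downstream-gene (NDG) and nearest-TSS queries
#'   against a containment-list index over transcripts. A gene is
#'   *downstream* of a peak when the peak lies upstream of the gene's TSS
#'   in the gene's own reading direction: forward-strand genes starting
#'   at or after the peak end, reverse-strand genes ending at or before
#'   the peak start. Peak strand is ignored throughout.
#' @name annotator
NULL

# centre of a half-open peak: floor of the midpoint (the left-of-centre
# base for even lengths)
#' @keywords internal
peak_center <- function(start, end) {
  as.integer(floor((start + end - 1) / 2))
}

# max end over reverse-strand entries in the subtree rooted at per-chrom
# position `p`, restricted to end <= limit; -Inf if none
#' @keywords internal
subtree_max_neg_end <- function(index, tr, p, limit) {
  best <- -Inf
  if (tr$end[p] <= limit && index$strand[tr$id[p]] == "-")
    best <- tr$end[p]
  for (ch in tr$children[[p]])
    best <- max(best, subtree_max_neg_end(index, tr, ch, limit))
  best
}

# id of a reverse-strand entry achieving end == target within the subtree
#' @keywords internal
subtree_find_neg_end <- function(index, tr, p, target) {
  if (tr$end[p] == target && index$strand[tr$id[p]] == "-")
    return(tr$id[p])
  for (ch in tr$children[[p]]) {
    hit <- subtree_find_neg_end(index, tr, ch, target)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

# min start over forward-strand entries in the subtree with start >= limit
#' @keywords internal
subtree_min_pos_start <- function(index, tr, p, limit) {
  best <- Inf
  if (tr$start[p] >= limit && index$strand[tr$id[p]] == "+")
    best <- tr$start[p]
  for (ch in tr$children[[p]])
    best <- min(best, subtree_min_pos_start(index, tr, ch, limit))
  best
}

#' @keywords internal
subtree_find_pos_start <- function(index, tr, p, target) {
  if (tr$start[p] == target && index$strand[tr$id[p]] == "+")
    return(tr$id[p])
  for (ch in tr$children[[p]]) {
    hit <- subtree_find_pos_start(index, tr, ch, target)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Nearest downstream genes of a peak
#'
#' Finds, per strand, the nearest transcript that does not overlap the
#' peak and whose transcription starts downstream of it: on the forward
#' strand the transcript with minimal `tx_start >= peak end`, on the
#' reverse strand the transcript with maximal `tx_end <= peak start`.
#' The search walks the primary containment list outward from the peak
#' and descends into sublists, so nested genes (a reverse gene hidden
#' inside a forward gene, or vice versa) are found exactly as a full
#' linear scan would. Transcripts intersecting the peak by at least one
#' base are reported separately with their component classification (see
#' [classify_overlap()]).
#'
#' @param peak One-row interval table.
#' @param index An `"nclist"` built over transcripts ([build_index()]).
#' @param bidir_window Distance threshold in bases for flagging a
#'   putative bidirectional promoter: the flag is set when downstream
#'   genes exist on both strands within this distance. Default 1000.
#' @return A list of class `"ndg_result"` with fields `peak`,
#'   `overlapping` (data.frame: transcript_id, gene_id, strand,
#'   component), `nearest_forward` / `nearest_reverse` (each `NULL` or
#'   `list(transcript, distance)`, the distance being the gap in bases
#'   between the facing peak and TSS-side boundaries), and
#'   `bidirectional_promoter`.
#' @export
nearest_downstream_genes <- function(peak, index, bidir_window = 1000L) {
  p <- as_gintervals(peak)
  stopifnot(nrow(p) == 1L, inherits(index, "nclist"))
  tr <- index$chroms[[p$chrom]]
  ov_ids <- if (is.null(tr)) integer(0) else
    query_overlaps(index, p$chrom, p$start, p$end)
  overlapping <- data.frame(transcript_id = character(0),
                            gene_id = character(0), strand = character(0),
                            component = character(0),
                            stringsAsFactors = FALSE)
  for (id in ov_ids) {
    t <- payload(index, id)
    overlapping <- rbind(overlapping, data.frame(
      transcript_id = t$transcript_id, gene_id = t$gene_id,
      strand = t$strand,
      component = format_component(classify_overlap(p, t)),
      stringsAsFactors = FALSE))
  }
  nearest_forward <- NULL
  nearest_reverse <- NULL
  if (!is.null(tr)) {
    ov_pos <- index$pos_of[ov_ids[index$chrom_of[ov_ids] == p$chrom]]
    ov_primary <- ov_pos[tr$parent[ov_pos] == 0L]

    # forward strand: minimise tx_start over + genes with start >= peak end
    prim_starts <- tr$start[tr$primary]
    best_start <- Inf
    # sublists of peak-overlapping primaries may hold fully-downstream genes
    for (q in ov_primary)
      best_start <- min(best_start,
                        subtree_min_pos_start(index, tr, q, p$end))
    i <- findInterval(p$end - 1L, prim_starts) + 1L  # first start >= p$end
    while (i <= length(prim_starts)) {
      q <- tr$primary[i]
      if (tr$start[q] >= best_start) break
      best_start <- min(best_start,
                        subtree_min_pos_start(index, tr, q, p$end))
      i <- i + 1L
    }
    if (is.finite(best_start)) {
      cand <- NULL
      for (q in c(ov_primary, tr$primary)) {
        cand <- subtree_find_pos_start(index, tr, q, best_start)
        if (!is.null(cand)) break
      }
      t <- payload(index, cand)
      nearest_forward <- list(transcript = t,
                              distance = t$tx_start - p$end)
    }

    # reverse strand: maximise tx_end over - genes with end <= peak start
    prim_ends <- tr$end[tr$primary]
    best_end <- -Inf
    for (q in ov_primary)
      best_end <- max(best_end, subtree_max_neg_end(index, tr, q, p$start))
    i <- findInterval(p$start, prim_ends)  # last primary with end <= p$start
    while (i >= 1L) {
      q <- tr$primary[i]
      if (tr$end[q] <= best_end) break
      best_end <- max(best_end, subtree_max_neg_end(index, tr, q, p$start))
      i <- i - 1L
    }
    if (is.finite(best_end)) {
      cand <- NULL
      for (q in c(ov_primary, rev(tr$primary))) {
        cand <- subtree_find_neg_end(index, tr, q, best_end)
        if (!is.null(cand)) break
      }
      t <- payload(index, cand)
      nearest_reverse <- list(transcript = t,
                              distance = p$start - t$tx_end)
    }
  }
  bidir <- !is.null(nearest_forward) && !is.null(nearest_reverse) &&
    nearest_forward$distance <= bidir_window &&
    nearest_reverse$distance <= bidir_window
  structure(list(peak = p, overlapping = overlapping,
                 nearest_forward = nearest_forward,
                 nearest_reverse = nearest_reverse,
                 bidirectional_promoter = bidir),
            class = "ndg_result")
}

#' @export
print.ndg_result <- function(x, ...) {
  fmt <- function(slot) {
    if (is.null(slot)) "none"
    else sprintf("%s (d=%d)", slot$transcript$transcript_id, slot$distance)
  }
  cat(sprintf("<ndg %s:[%d,%d) fwd=%s rev=%s overlap=%d bidir=%s>\n",
              x$peak$chrom, x$peak$start, x$peak$end,
              fmt(x$nearest_forward), fmt(x$nearest_reverse),
              nrow(x$overlapping), x$bidirectional_promoter))
  invisible(x)
}

#' Classify a peak against one transcript's components
#'
#' Classification is by the peak's central position: the centre base is
#' mapped into the transcript structure in transcription order. UTR
#' calls require a CDS; exonic hits on a transcript without CDS are
#' reported as `exon_cds`. A centre outside the transcript span is
#' `upstream` or `downstream` relative to the transcript's strand.
#' Intron ranks are 1-based in transcription order (rank 1 abuts the
#' first transcribed exon).
#'
#' @param peak One-row interval table (same chromosome as `t`).
#' @param t A [transcript()].
#' @return A list of class `"component_class"`: `type` (one of
#'   `five_prime_utr`, `three_prime_utr`, `exon_cds`, `intron`,
#'   `upstream`, `downstream`), `rank` (introns only) and `n_introns`.
#' @export
classify_overlap <- function(peak, t) {
  p <- as_gintervals(peak)
  stopifnot(nrow(p) == 1L, inherits(t, "transcript"))
  if (p$chrom != t$chrom)
    stop("peak and transcript are on different chromosomes", call. = FALSE)
  c0 <- peak_center(p$start, p$end)
  n_introns <- nrow(t$exons) - 1L
  cls <- function(type, rank = NA_integer_) {
    structure(list(type = type, rank = rank, n_introns = n_introns),
              class = "component_class")
  }
  if (c0 < t$tx_start)
    return(cls(if (t$strand == "+") "upstream" else "downstream"))
  if (c0 >= t$tx_end)
    return(cls(if (t$strand == "+") "downstream" else "upstream"))
  in_exon <- any(t$exons[, 1L] <= c0 & c0 < t$exons[, 2L])
  if (!in_exon) {
    genomic_rank <- sum(t$exons[, 2L] <= c0)  # introns before c0, left to right
    rank <- if (t$strand == "+") genomic_rank else n_introns - genomic_rank + 1L
    return(cls("intron", rank))
  }
  if (is.na(t$cds_start)) return(cls("exon_cds"))
  if (t$strand == "+") {
    if (c0 < t$cds_start) return(cls("five_prime_utr"))
    if (c0 >= t$cds_end) return(cls("three_prime_utr"))
  } else {
    if (c0 >= t$cds_end) return(cls("five_prime_utr"))
    if (c0 < t$cds_start) return(cls("three_prime_utr"))
  }
  cls("exon_cds")
}

#' @keywords internal
format_component <- function(x) {
  if (x$type == "intron") sprintf("intron(%d)", x$rank) else x$type
}

#' Nearest transcription start site of a peak
#'
#' Finds the transcript whose TSS is closest (in absolute distance) to
#' the peak's central position, scanning both directions so sense and
#' antisense initiation are both considered. Ties are broken by
#' lexicographically smallest `transcript_id`; all tied transcripts are
#' reported.
#'
#' @param peak One-row interval table.
#' @param index An `"nclist"` built over transcripts.
#' @return A list of class `"tss_result"`: `peak`, `transcript`,
#'   `signed_distance` (positive when the peak centre lies downstream of
#'   the TSS in the gene's transcription direction, negative upstream),
#'   `within_gene` (is the centre inside the reported transcript span),
#'   and `ties` (character vector of all transcript_ids at the minimal
#'   distance). Returns `NULL` fields if the chromosome has no
#'   transcripts.
#' @export
nearest_tss <- function(peak, index) {
  p <- as_gintervals(peak)
  stopifnot(nrow(p) == 1L, inherits(index, "nclist"))
  c0 <- peak_center(p$start, p$end)
  tss <- tss_table(index)[[p$chrom]]
  if (is.null(tss) || nrow(tss) == 0L)
    return(structure(list(peak = p, transcript = NULL,
                          signed_distance = NA_integer_,
                          within_gene = NA, ties = character(0)),
                     class = "tss_result"))
  # TSS positions are start-sorted: the closest lies beside the insertion
  # point, a bidirectional probe from the binary-search position
  i <- findInterval(c0, tss$pos)
  cand <- unique(pmin(pmax(c(i, i + 1L), 1L), nrow(tss)))
  dmin <- min(abs(tss$pos[cand] - c0))
  hits <- which(abs(tss$pos - c0) == dmin)
  ids <- vapply(hits, function(k) {
    payload(index, tss$id[k])$transcript_id
  }, "")
  pick <- hits[order(ids)][1L]
  t <- payload(index, tss$id[pick])
  signed <- if (t$strand == "+") c0 - tss_position(t) else tss_position(t) - c0
  structure(list(peak = p, transcript = t,
                 signed_distance = as.integer(signed),
                 within_gene = c0 >= t$tx_start && c0 < t$tx_end,
                 ties = sort(ids)),
            class = "tss_result")
}

#' @export
print.tss_result <- function(x, ...) {
  if (is.null(x$transcript)) {
    cat("<tss: no transcripts on this chromosome>\n")
  } else {
    cat(sprintf("<tss %s:[%d,%d) -> %s, signed distance %d>\n",
                x$peak$chrom, x$peak$start, x$peak$end,
                x$transcript$transcript_id, x$signed_distance))
  }
  invisible(x)
}

# per-chromosome start-sorted TSS tables; precomputed by build_index()
# for transcript payloads, derived on the fly otherwise
#' @keywords internal
tss_table <- function(index) {
  if (!is.null(index$tss)) return(index$tss)
  tabs <- list()
  for (cn in names(index$chroms)) {
    tr <- index$chroms[[cn]]
    pos <- vapply(tr$id, function(id) tss_position(payload(index, id)), 0L)
    o <- order(pos)
    tabs[[cn]] <- data.frame(pos = pos[o], id = tr$id[o])
  }
  tabs
}

#' Annotate many peaks at once
#'
#' @param peaks Interval table of peaks.
#' @param index An `"nclist"` over transcripts, or a list of transcripts.
#' @param utility `"NDG"` or `"TSS"`.
#' @param bidir_window Passed to [nearest_downstream_genes()].
#' @return For `"NDG"`: a data.frame with one row per peak (overlapping
#'   transcripts and components are `;`-joined). For `"TSS"`: one row
#'   per peak with transcript, gene, signed distance, within-gene flag
#'   and ties. Peaks on chromosomes absent from the annotation yield
#'   rows of `NA`, never an error.
#' @export
annotate_peaks <- function(peaks, index, utility = c("NDG", "TSS"),
                           bidir_window = 1000L) {
  utility <- match.arg(utility)
  if (!inherits(index, "nclist")) index <- build_index(index)
  p <- as_gintervals(peaks)
  rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    if (utility == "NDG") {
      r <- nearest_downstream_genes(p[i, ], index, bidir_window)
      rows[[i]] <- data.frame(
        chrom = p$chrom[i], start = p$start[i], end = p$end[i],
        name = p$name[i],
        overlap_transcripts = paste(r$overlapping$transcript_id,
                                    collapse = ";"),
        overlap_components = paste(r$overlapping$component, collapse = ";"),
        fwd_transcript = if (is.null(r$nearest_forward)) NA_character_
          else r$nearest_forward$transcript$transcript_id,
        fwd_distance = if (is.null(r$nearest_forward)) NA_integer_
          else r$nearest_forward$distance,
        rev_transcript = if (is.null(r$nearest_reverse)) NA_character_
          else r$nearest_reverse$transcript$transcript_id,
        rev_distance = if (is.null(r$nearest_reverse)) NA_integer_
          else r$nearest_reverse$distance,
        bidirectional_promoter = r$bidirectional_promoter,
        stringsAsFactors = FALSE)
    } else {
      r <- nearest_tss(p[i, ], index)
      rows[[i]] <- data.frame(
        chrom = p$chrom[i], start = p$start[i], end = p$end[i],
        name = p$name[i],
        transcript = if (is.null(r$transcript)) NA_character_
          else r$transcript$transcript_id,
        gene = if (is.null(r$transcript)) NA_character_
          else r$transcript$gene_id,
        signed_distance = r$signed_distance,
        within_gene = r$within_gene,
        ties = paste(r$ties, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
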