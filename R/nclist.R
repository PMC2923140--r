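#' Build a nested containment list index
#'
#' The index partitions each chromosome's intervals into a primary list
#' of positionally-independent loci — intervals not contained in any
#' other — plus, for every interval, a sublist of the intervals it
#' directly contains, recursively. Removing contained intervals makes end
#' order follow start order, so the primary list (and every sublist)
#' supports binary search on both boundaries. This is the engine behind
#' the downstream-gene, TSS and dataset-overlap queries.
#'
#' Containment means `P.start <= x.start` and `x.end <= P.end` with
#' `P != x`; each interval is attached to its minimal container. Ties on
#' identical spans resolve by input order: the first-encountered interval
#' becomes the container of later duplicates, so every interval has
#' exactly one home.
#'
#' @param x Either an interval table (see [gintervals()]) or a list of
#'   [transcript()] objects (indexed by transcript span).
#' @return An object of class `"nclist"`. Entries are identified by their
#'   1-based position in the input, returned as the `id` field of query
#'   results; `payload(index, id)` recovers the input row or transcript.
#' @export
build_index <- function(x) {
  if (is.data.frame(x)) {
    iv <- as_gintervals(x)
    payload <- x  # rows served lazily by payload()
    chrom <- iv$chrom; start <- iv$start; end <- iv$end; strand <- iv$strand
  } else if (is.list(x) && (length(x) == 0L || inherits(x[[1L]], "transcript"))) {
    payload <- x
    chrom <- vapply(x, `[[`, "", "chrom")
    start <- vapply(x, `[[`, 0L, "tx_start")
    end <- vapply(x, `[[`, 0L, "tx_end")
    strand <- vapply(x, `[[`, "", "strand")
  } else {
    stop("build_index() expects an interval table or a list of transcripts",
         call. = FALSE)
  }
  n <- length(start)
  chroms <- list()
  for (cn in unique(chrom)) {
    ids <- which(chrom == cn)
    s <- start[ids]; e <- end[ids]
    o <- order(s, -e, ids)  # start asc, end desc, input order breaks ties
    ids <- ids[o]; s <- s[o]; e <- e[o]
    m <- length(ids)
    parent <- integer(m)
    depth <- integer(m)
    stack <- integer(m)
    sp <- 0L
    for (k in seq_len(m)) {
      while (sp > 0L && e[stack[sp]] < e[k]) sp <- sp - 1L
      if (sp > 0L) parent[k] <- stack[sp]
      depth[k] <- sp
      sp <- sp + 1L
      stack[sp] <- k
    }
    children <- vector("list", m)
    has_p <- parent > 0L
    if (any(has_p)) {
      kids <- split(which(has_p), parent[has_p])
      children[as.integer(names(kids))] <- kids
    }
    primary <- which(!has_p)
    chroms[[cn]] <- list(id = ids, start = s, end = e, parent = parent,
                         depth = depth, children = children,
                         primary = primary)
  }
  pos_of <- integer(n)
  chrom_of <- character(n)
  for (cn in names(chroms)) {
    tr <- chroms[[cn]]
    pos_of[tr$id] <- seq_along(tr$id)
    chrom_of[tr$id] <- cn
  }
  idx <- structure(list(chroms = chroms, n = n, pos_of = pos_of,
                        chrom_of = chrom_of, strand = strand,
                        payload = payload, tss = NULL),
                   class = "nclist")
  if (n > 0L && !is.data.frame(payload) &&
      inherits(payload[[1L]], "transcript")) {
    tabs <- list()
    for (cn in names(chroms)) {
      tr <- chroms[[cn]]
      tp <- vapply(tr$id, function(i) tss_position(payload[[i]]), 0L)
      o <- order(tp)
      tabs[[cn]] <- data.frame(pos = tp[o], id = tr$id[o])
    }
    idx$tss <- tabs
  }
  idx
}

#' @export
print.nclist <- function(x, ...) {
  np <- sum(vapply(x$chroms, function(tr) length(tr$primary), 0L))
  cat(sprintf("<nclist: %d interval(s) on %d chromosome(s), %d primary>\n",
              x$n, length(x$chroms), np))
  invisible(x)
}

#' Recover the payload behind an index entry
#' @param index An `"nclist"`.
#' @param id Entry id (1-based input position).
#' @return The input row (one-row data.frame) or transcript.
#' @export
payload <- function(index, id) {
  stopifnot(inherits(index, "nclist"))
  if (length(id) != 1L || is.na(id) || id < 1L || id > index$n)
    stop("entry id not in this index: ", id, call. = FALSE)
  if (is.data.frame(index$payload)) index$payload[id, , drop = FALSE]
  else index$payload[[id]]
}

#' First primary entry starting strictly after a position
#'
#' Binary search over the primary list of one chromosome.
#'
#' @param index An `"nclist"`.
#' @param chrom Chromosome name; unknown chromosomes yield `NULL`.
#' @param pos 0-based position.
#' @return `list(id, start, end, strand)` of the primary entry with the
#'   smallest `start > pos`, or `NULL` if none.
#' @export
first_start_after <- function(index, chrom, pos) {
  stopifnot(inherits(index, "nclist"))
  tr <- index$chroms[[chrom]]
  if (is.null(tr)) return(NULL)
  starts <- tr$start[tr$primary]
  i <- findInterval(pos, starts) + 1L  # first start > pos (starts strict asc)
  if (i > length(starts)) return(NULL)
  p <- tr$primary[i]
  list(id = tr$id[p], start = tr$start[p], end = tr$end[p],
       strand = index$strand[tr$id[p]])
}

#' Containment chain of an index entry
#'
#' @param index An `"nclist"`.
#' @param id Entry id.
#' @return Integer vector of ancestor ids whose spans contain the
#'   entry's span, innermost first (empty for primary entries).
#' @export
containers_of <- function(index, id) {
  stopifnot(inherits(index, "nclist"))
  if (length(id) != 1L || is.na(id) || id < 1L || id > index$n ||
      index$pos_of[id] == 0L)
    stop("entry id not in this index: ", id, call. = FALSE)
  tr <- index$chroms[[index$chrom_of[id]]]
  out <- integer(0)
  p <- tr$parent[index$pos_of[id]]
  while (p != 0L) {
    out <- c(out, tr$id[p])
    p <- tr$parent[p]
  }
  out
}

#' All entries overlapping an interval
#'
#' The canonical containment-list overlap query: at each nesting level
#' the overlapping entries form a contiguous run (ends and starts are
#' both sorted once contained intervals are removed), located by binary
#' search; sublists of overlapping entries are searched recursively.
#'
#' @param index An `"nclist"`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open query span.
#' @return Integer vector of ids of entries intersecting the query by at
#'   least one base (any strand), in increasing start order.
#' @export
query_overlaps <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "nclist"), start < end)
  tr <- index$chroms[[chrom]]
  if (is.null(tr)) return(integer(0))
  hits <- integer(0)
  walk <- function(sibs) {
    if (length(sibs) == 0L) return()
    ends <- tr$end[sibs]
    i <- findInterval(start, ends) + 1L  # first sibling with end > start
    while (i <= length(sibs) && tr$start[sibs[i]] < end) {
      hits <<- c(hits, tr$id[sibs[i]])
      walk(tr$children[[sibs[i]]])
      i <- i + 1L
    }
  }
  walk(tr$primary)
  sort_by_start <- order(tr$start[index$pos_of[hits]], hits)
  hits[sort_by_start]
}

#' Flatten an index back to its entries
#'
#' Traverses the primary list and every sublist recursively; the result
#' is a permutation of the input set.
#'
#' @param index An `"nclist"`.
#' @return Interval table with columns `chrom`, `start`, `end`, `strand`
#'   plus `id` (input position) and `depth` (0 for primary entries).
#' @export
flatten_index <- function(index) {
  stopifnot(inherits(index, "nclist"))
  # depth-first pre-order of the containment forest coincides with the
  # (start asc, end desc) sort order the build uses, so the flattening
  # is just the per-chromosome arrays themselves
  parts <- lapply(names(index$chroms), function(cn) {
    tr <- index$chroms[[cn]]
    data.frame(chrom = cn, start = tr$start, end = tr$end,
               strand = index$strand[tr$id], id = tr$id, depth = tr$depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0L) {
    out <- empty_gintervals()
    out$id <- integer(0); out$depth <- integer(0)
    return(out)
  }
  out$name <- NA_character_
  out$score <- NA_real_
  out[, c("chrom", "start", "end", "strand", "name", "score", "id",
          "depth")]
}
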