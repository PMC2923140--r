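# Independent brute-force oracles. These re-derive expected answers from
# first principles (definition scans, all-pairs checks) and share no code
# with the implementations they check.

# local maxima by per-position definition scan: a position is a maximum
# iff its depth is >= both flanking non-equal depths (boundaries compare
# inward) and positive; plateaus are reported at their leftmost offset
oracle_maxima <- function(d) {
  n <- length(d)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (d[i] <= 0) next
    if (i > 1L && d[i - 1L] == d[i]) next  # not the leftmost of a plateau
    j <- i - 1L
    while (j >= 1L && d[j] == d[i]) j <- j - 1L
    left_ok <- j < 1L || d[j] < d[i]
    k <- i + 1L
    while (k <= n && d[k] == d[i]) k <- k + 1L
    right_ok <- k > n || d[k] < d[i]
    if (left_ok && right_ok) out <- c(out, i)
  }
  cbind(offset = out, height = d[out])
}

# subpeak boundaries (offsets where a new subpeak starts, 1-based within
# the peak) by direct evaluation of the valley rule at every maxima pair
oracle_split_bounds <- function(d, valley_factor) {
  m <- oracle_maxima(d)
  cuts <- integer(0)
  if (nrow(m) > 1L) {
    for (k in seq_len(nrow(m) - 1L)) {
      rng <- (m[k, "offset"] + 1L):(m[k + 1L, "offset"] - 1L)
      valley <- min(d[rng])
      if (valley < valley_factor * min(m[k, "height"], m[k + 1L, "height"])) {
        cuts <- c(cuts, rng[which(d[rng] == valley)[1L]])
      }
    }
  }
  c(1L, cuts, length(d) + 1L)
}

# quadratic all-pairs NDG scan over a transcript list
oracle_ndg <- function(peak, txs) {
  ov <- character(0)
  fwd <- NULL; fwd_d <- Inf
  rev_ <- NULL; rev_d <- Inf
  for (t in txs) {
    if (t$chrom != peak$chrom) next
    if (t$tx_start < peak$end && t$tx_end > peak$start) {
      ov <- c(ov, t$transcript_id)
      next
    }
    if (t$strand == "+" && t$tx_start >= peak$end) {
      d <- t$tx_start - peak$end
      if (d < fwd_d) { fwd <- t; fwd_d <- d }
    }
    if (t$strand == "-" && t$tx_end <= peak$start) {
      d <- peak$start - t$tx_end
      if (d < rev_d) { rev_ <- t; rev_d <- d }
    }
  }
  list(overlapping = sort(ov),
       fwd = if (is.null(fwd)) NA_character_ else fwd$transcript_id,
       fwd_d = if (is.null(fwd)) NA_integer_ else fwd_d,
       rev = if (is.null(rev_)) NA_character_ else rev_$transcript_id,
       rev_d = if (is.null(rev_)) NA_integer_ else rev_d)
}

# exhaustive nearest-TSS scan; ties resolved by smallest transcript_id
oracle_tss <- function(peak, txs) {
  c0 <- floor((peak$start + peak$end - 1) / 2)
  best_d <- Inf; best_id <- NULL; best_signed <- NA_integer_
  for (t in txs) {
    if (t$chrom != peak$chrom) next
    tss <- if (t$strand == "+") t$tx_start else t$tx_end - 1L
    d <- abs(tss - c0)
    if (d < best_d || (d == best_d && t$transcript_id < best_id)) {
      best_d <- d
      best_id <- t$transcript_id
      best_signed <- if (t$strand == "+") c0 - tss else tss - c0
    }
  }
  list(id = best_id, signed = as.integer(best_signed))
}

# quadratic all-pairs intersection test
oracle_pairs <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    j <- which(b$chrom == a$chrom[i] & b$start < a$end[i] &
                 b$end > a$start[i])
    if (length(j)) out <- rbind(out, cbind(i1 = i, i2 = j))
  }
  if (is.null(out)) out <- cbind(i1 = integer(0), i2 = integer(0))
  out[order(out[, "i1"], out[, "i2"]), , drop = FALSE]
}

# base-resolution bitmap union of datasets on a small genome
oracle_union_bitmap <- function(datasets, sizes) {
  lapply(stats::setNames(nm = names(sizes)), function(cn) {
    bits <- matrix(FALSE, nrow = sizes[[cn]], ncol = length(datasets))
    for (k in seq_along(datasets)) {
      d <- datasets[[k]]
      d <- d[d$chrom == cn, , drop = FALSE]
      for (i in seq_len(nrow(d)))
        bits[(d$start[i] + 1L):d$end[i], k] <- TRUE
    }
    bits
  })
}

# all containers of interval i by pairwise check; identical spans count
# as containers only when they appear earlier in the input (the
# first-encountered duplicate is the home of the others)
oracle_containers <- function(iv, i) {
  cand <- which(iv$chrom == iv$chrom[i] & iv$start <= iv$start[i] &
                  iv$end >= iv$end[i] & seq_len(nrow(iv)) != i)
  same <- iv$start[cand] == iv$start[i] & iv$end[cand] == iv$end[i]
  cand[!same | cand < i]
}

# --- random-case generators (fixed seeds set by the calling tests) ---

random_interval_set <- function(n, chroms = c("c1", "c2"), max_pos = 5000L,
                                max_len = 400L, nested_frac = 0.2) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  iv <- gintervals(chrom, start, start + len)
  n_nest <- floor(n * nested_frac)
  if (n_nest > 0 && n > 0) {
    host <- sample.int(n, n_nest, replace = TRUE)
    w <- iv$end[host] - iv$start[host]
    keep <- w >= 3L
    host <- host[keep]
    if (length(host)) {
      s2 <- iv$start[host] + 1L
      e2 <- pmax(s2 + 1L, iv$end[host] - 1L)
      iv <- rbind(iv, gintervals(iv$chrom[host], s2, e2))
    }
  }
  iv
}

random_transcript_set <- function(n, chroms = c("c1", "c2"),
                                  max_pos = 50000L) {
  txs <- vector("list", n)
  for (i in seq_len(n)) {
    if (i > 1L && stats::runif(1) < 0.25) {
      # nest inside or duplicate the span region of an earlier transcript
      host <- txs[[sample.int(i - 1L, 1L)]]
      chrom <- host$chrom
      w <- host$tx_end - host$tx_start
      if (w >= 10L) {
        start <- host$tx_start + sample.int(w - 5L, 1L)
        end <- min(host$tx_end, start + sample.int(w, 1L))
        if (end <= start) end <- start + 1L
      } else {
        start <- host$tx_start
        end <- host$tx_end
      }
    } else {
      chrom <- sample(chroms, 1L)
      start <- sample.int(max_pos, 1L) - 1L
      end <- start + sample.int(2000L, 1L)
    }
    n_ex <- sample.int(3L, 1L)
    w <- end - start
    if (n_ex > 1L && w >= 2L * n_ex) {
      cuts <- sort(sample((start + 1L):(end - 1L), 2L * n_ex - 2L))
      bounds <- c(start, cuts, end)
      k <- seq(1L, 2L * n_ex - 1L, by = 2L)
      exons <- cbind(bounds[k], bounds[k + 1L])
      if (any(exons[, 1L] >= exons[, 2L])) exons <- cbind(start, end)
    } else {
      exons <- cbind(start, end)
    }
    txs[[i]] <- transcript(sprintf("g%04d", i), sprintf("t%04d", i),
                           chrom, sample(c("+", "-"), 1L), exons,
                           tx_start = start, tx_end = end)
  }
  txs
}

random_peak_set <- function(n, chroms = c("c1", "c2"), max_pos = 50000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  gintervals(sample(chroms, n, replace = TRUE), start,
             start + sample.int(800L, n, replace = TRUE))
}
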