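#' Specification for synthetic test data
#'
#' Describes a small artificial genome, an Ensembl-style transcript
#' annotation, and a set of enrichment peaks with multimodal signal
#' profiles, all with known ground truth. Signal bumps are triangular
#' (linear rise and fall): valley depths and summit heights are then
#' exact, so the separability of every adjacent summit pair at a given
#' valley factor is known analytically rather than empirically.
#'
#' @param seed Integer seed driving all randomness.
#' @param chromosomes Named integer vector: chromosome name -> length.
#' @param n_transcripts Number of transcripts to generate.
#' @param p_nested Probability that a transcript is placed strictly
#'   inside a previously placed one (exercises containment sublists).
#' @param exon_range Integer range (min, max) of exons per transcript.
#' @param n_peaks Number of enrichment peaks.
#' @param summits_range Range (min, max) of planted summits per peak.
#' @param height_range Range (min, max) of summit heights.
#' @param valley_fraction Valley depth as a fraction of the lower of the
#'   two flanking summit heights; a pair is separable at `valley_factor`
#'   iff `valley_fraction < valley_factor`.
#' @param background Depth at peak edges (outside bump slopes).
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed = 1L,
                           chromosomes = c(chrS1 = 200000L, chrS2 = 150000L),
                           n_transcripts = 40L, p_nested = 0.2,
                           exon_range = c(1L, 5L),
                           n_peaks = 30L, summits_range = c(1L, 4L),
                           height_range = c(10, 60),
                           valley_fraction = 0.25, background = 1) {
  stopifnot(all(chromosomes > 0L), n_transcripts >= 0L, n_peaks >= 0L,
            p_nested >= 0, p_nested <= 1,
            valley_fraction >= 0, valley_fraction <= 1, background >= 0)
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 n_transcripts = as.integer(n_transcripts),
                 p_nested = p_nested, exon_range = as.integer(exon_range),
                 n_peaks = as.integer(n_peaks),
                 summits_range = as.integer(summits_range),
                 height_range = height_range,
                 valley_fraction = valley_fraction,
                 background = background),
            class = "synthetic_spec")
}

#' Generate a synthetic transcript annotation
#'
#' Transcripts carry exon and CDS structure on both strands; with
#' probability `p_nested` a transcript is placed strictly inside an
#' earlier one, so the resulting containment index has non-trivial
#' sublists. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param gtf Optional path; when given, the annotation is also written
#'   as GTF.
#' @return List of [transcript()] objects (invisibly writes `gtf`).
#' @export
make_annotation <- function(spec, gtf = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  txs <- list()
  spans <- list()  # per transcript: (chrom, start, end)
  for (i in seq_len(spec$n_transcripts)) {
    nest_in <- 0L
    if (length(spans) > 0L && stats::runif(1) < spec$p_nested) {
      wide <- which(vapply(spans, function(s) s$end - s$start >= 400L, NA))
      if (length(wide)) nest_in <- wide[sample.int(length(wide), 1L)]
    }
    if (nest_in > 0L) {
      host <- spans[[nest_in]]
      chrom <- host$chrom
      width <- sample(200:max(200L, floor((host$end - host$start) / 2)), 1L)
      start <- host$start + sample.int(host$end - host$start - width - 1L, 1L)
    } else {
      # rejection-sample so that unintended containment never occurs:
      # sublist structure is controlled by p_nested alone
      for (try in 1:200) {
        chrom <- sample(names(spec$chromosomes), 1L)
        clen <- spec$chromosomes[[chrom]]
        width <- sample(500:3000, 1L)
        start <- sample.int(clen - width, 1L) - 1L
        contained <- vapply(spans, function(s) {
          s$chrom == chrom &&
            ((s$start <= start && start + width <= s$end) ||
               (start <= s$start && s$end <= start + width))
        }, NA)
        if (!any(contained)) break
      }
    }
    end <- start + width
    n_exons <- sample(spec$exon_range[1L]:spec$exon_range[2L], 1L)
    # cut the span into 2*n_exons - 1 alternating exon/intron blocks
    if (n_exons == 1L) {
      exons <- cbind(start, end)
    } else {
      cuts <- sort(sample((start + 1L):(end - 1L), 2L * n_exons - 2L))
      bounds <- c(start, cuts, end)
      k <- seq(1L, 2L * n_exons - 1L, by = 2L)
      exons <- cbind(bounds[k], bounds[k + 1L])
      if (any(exons[, 1L] >= exons[, 2L])) {  # degenerate cut; single exon
        exons <- cbind(start, end)
      }
    }
    has_cds <- stats::runif(1) < 0.7
    cds <- c(NA_integer_, NA_integer_)
    if (has_cds && sum(exons[, 2L] - exons[, 1L]) >= 6L) {
      exl <- exons[, 2L] - exons[, 1L]
      first <- exons[1L, ]; last <- exons[nrow(exons), ]
      cs <- first[1L] + sample.int(max(1L, exl[1L] - 1L), 1L) - 1L
      ce <- last[2L] - sample.int(max(1L, exl[length(exl)] - 1L), 1L) + 1L
      if (cs < ce) cds <- c(cs, min(ce, end))
    }
    txs[[i]] <- transcript(
      gene_id = sprintf("G%04d", i), transcript_id = sprintf("T%04d", i),
      chrom = chrom, strand = sample(c("+", "-"), 1L),
      exons = exons, tx_start = start, tx_end = end,
      cds_start = cds[1L], cds_end = cds[2L])
    spans[[i]] <- list(chrom = chrom, start = start, end = end)
  }
  if (!is.null(gtf)) write_gtf(txs, gtf)
  invisible(txs)
}

#' Generate peaks, a multimodal signal track, and their ground truth
#'
#' Every peak carries `k` planted triangular bumps (with `k` drawn from
#' `summits_range`) separated by valleys whose depth is exactly
#' `valley_fraction` times the lower of the two flanking summit heights.
#' The truth table records each planted summit and whether each
#' adjacent pair is separable at a given valley factor.
#'
#' @param spec A [synthetic_spec()].
#' @param valley_factor The splitting parameter the `separable` column
#'   refers to; default 0.6.
#' @return A list: `peaks` (interval table), `signal`
#'   (a [signal_profile()]), `truth` (data.frame: peak name, summit
#'   position, height, n_summits, separable_from_next).
#' @export
make_signal <- function(spec, valley_factor = 0.6) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  peaks <- empty_gintervals()
  chrom_v <- character(0); pos_v <- integer(0); depth_v <- numeric(0)
  truth <- list()
  cursor <- stats::setNames(rep(1000L, length(spec$chromosomes)),
                            names(spec$chromosomes))
  for (i in seq_len(spec$n_peaks)) {
    chrom <- sample(names(spec$chromosomes), 1L)
    k <- sample(spec$summits_range[1L]:spec$summits_range[2L], 1L)
    heights <- stats::runif(k, spec$height_range[1L], spec$height_range[2L])
    # lay out: edge, k summits spaced 60-120 bases apart, edge
    gaps <- sample(60:120, k + 1L, replace = TRUE)
    offs <- cumsum(gaps)[seq_len(k)]
    width <- sum(gaps) + 1L
    start <- cursor[[chrom]]
    if (start + width + 1000L > spec$chromosomes[[chrom]])
      stop("synthetic chromosome too short for requested peaks",
           call. = FALSE)
    cursor[[chrom]] <- start + width + sample(500:1500, 1L)
    name <- sprintf("peak%03d", i)
    peaks <- rbind(peaks, gintervals(chrom, start, start + width,
                                     name = name))
    # piecewise-linear profile through edges, summits and valleys
    xs <- c(0L, offs, width - 1L)
    ys <- c(spec$background, heights, spec$background)
    if (k > 1L) {
      vx <- integer(k - 1L); vy <- numeric(k - 1L)
      for (j in seq_len(k - 1L)) {
        vx[j] <- as.integer(floor((offs[j] + offs[j + 1L]) / 2))
        vy[j] <- spec$valley_fraction * min(heights[j], heights[j + 1L])
      }
      xs <- c(0L, as.vector(rbind(offs[-k], vx)), offs[k], width - 1L)
      ys <- c(spec$background,
              as.vector(rbind(heights[-k], vy)), heights[k],
              spec$background)
    }
    d <- stats::approx(xs, ys, xout = 0:(width - 1L))$y
    chrom_v <- c(chrom_v, rep(chrom, width))
    pos_v <- c(pos_v, start + 0:(width - 1L))
    depth_v <- c(depth_v, d)
    truth[[i]] <- data.frame(
      peak = name, chrom = chrom, summit = start + offs,
      height = heights, n_summits = k,
      separable_from_next = c(rep(spec$valley_fraction < valley_factor,
                                  k - 1L), NA),
      stringsAsFactors = FALSE)
  }
  list(peaks = peaks,
       signal = signal_profile(chrom_v, pos_v, depth_v),
       truth = do.call(rbind, c(truth,
                                list(make.row.names = FALSE))))
}

#' Generate a random genome FASTA
#'
#' @param spec A [synthetic_spec()].
#' @param path Output FASTA path.
#' @return Invisibly, a `DNAStringSet` of the genome.
#' @export
make_genome <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  seqs <- vapply(spec$chromosomes, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(spec$chromosomes)
  if (!is.null(path)) Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(genome)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits `genome.fa`, `genes.gtf`, `peaks.bed`, `signal.wig`,
#' `truth.tsv` and `chrom.sizes`, all regenerated deterministically from
#' the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @param valley_factor Passed to [make_signal()].
#' @return Invisibly, the list of generated objects.
#' @export
write_synthetic_dataset <- function(spec, dir, valley_factor = 0.6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txs <- make_annotation(spec, gtf = file.path(dir, "genes.gtf"))
  sig <- make_signal(spec, valley_factor = valley_factor)
  genome <- make_genome(spec, path = file.path(dir, "genome.fa"))
  write_bed(sig$peaks, file.path(dir, "peaks.bed"))
  write_wig(sig$signal, file.path(dir, "signal.wig"))
  utils::write.table(sig$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_chrom_sizes(spec$chromosomes, file.path(dir, "chrom.sizes"))
  invisible(list(transcripts = txs, peaks = sig$peaks, signal = sig$signal,
                 truth = sig$truth, genome = genome))
}
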