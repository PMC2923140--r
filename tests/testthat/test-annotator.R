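tx <- function(id, chrom, strand, start, end, ...) {
  transcript(gene_id = paste0("g_", id), transcript_id = id, chrom = chrom,
             strand = strand, exons = cbind(start, end),
             tx_start = start, tx_end = end, ...)
}

test_that("nearest downstream genes: distances are boundary-to-TSS gaps", {
  idx <- build_index(list(tx("fwd", "c1", "+", 300L, 400L),
                          tx("rev", "c1", "-", 10L, 60L)))
  r <- nearest_downstream_genes(gintervals("c1", 100L, 200L), idx)
  expect_equal(r$nearest_forward$transcript$transcript_id, "fwd")
  expect_equal(r$nearest_forward$distance, 100L)
  expect_equal(r$nearest_reverse$transcript$transcript_id, "rev")
  expect_equal(r$nearest_reverse$distance, 40L)
  expect_equal(nrow(r$overlapping), 0L)
  # both downstream genes sit within the default 1 kb promoter window
  expect_true(r$bidirectional_promoter)
})

test_that("overlapping transcripts are excluded from the nearest slots", {
  idx <- build_index(list(tx("host", "c1", "+", 50L, 500L)))
  r <- nearest_downstream_genes(gintervals("c1", 100L, 200L), idx)
  expect_equal(r$overlapping$transcript_id, "host")
  expect_null(r$nearest_forward)
  expect_null(r$nearest_reverse)
})

test_that("reverse candidates hidden in containment chains are found", {
  # a - transcript containing a + transcript; peak lies downstream of both
  idx <- build_index(list(tx("neg_host", "c1", "-", 0L, 500L),
                          tx("pos_inner", "c1", "+", 100L, 150L)))
  r <- nearest_downstream_genes(gintervals("c1", 600L, 700L), idx)
  expect_equal(r$nearest_reverse$transcript$transcript_id, "neg_host")
  expect_equal(r$nearest_reverse$distance, 100L)
  expect_null(r$nearest_forward)

  # the mirror case: a - gene nested inside a + gene is the nearest
  # reverse gene even though its container overlaps the peak
  idx2 <- build_index(list(tx("pos_host", "c1", "+", 0L, 800L),
                           tx("neg_inner", "c1", "-", 100L, 400L),
                           tx("far_neg", "c1", "-", 0L, 50L)))
  r2 <- nearest_downstream_genes(gintervals("c1", 450L, 600L), idx2)
  expect_equal(r2$overlapping$transcript_id, "pos_host")
  expect_equal(r2$nearest_reverse$transcript$transcript_id, "neg_inner")
  expect_equal(r2$nearest_reverse$distance, 50L)
})

test_that("bidirectional promoters are flagged within the window", {
  idx <- build_index(list(tx("f", "c1", "+", 1200L, 2000L),
                          tx("r", "c1", "-", 100L, 900L)))
  peak <- gintervals("c1", 1000L, 1100L)
  expect_true(nearest_downstream_genes(peak, idx)$bidirectional_promoter)
  expect_false(nearest_downstream_genes(
    peak, idx, bidir_window = 50L)$bidirectional_promoter)
})

test_that("peaks on unannotated chromosomes give none-results", {
  idx <- build_index(list(tx("t", "c1", "+", 0L, 100L)))
  r <- nearest_downstream_genes(gintervals("cZ", 0L, 10L), idx)
  expect_null(r$nearest_forward)
  expect_null(r$nearest_reverse)
  expect_equal(nrow(r$overlapping), 0L)
  tt <- nearest_tss(gintervals("cZ", 0L, 10L), idx)
  expect_null(tt$transcript)
  res <- annotate_peaks(gintervals("cZ", 0L, 10L), idx, "TSS")
  expect_true(is.na(res$transcript))
})

test_that("NDG equals the quadratic all-pairs scan on random sets", {
  set.seed(401)
  for (rep in 1:40) {
    txs <- random_transcript_set(sample.int(300L, 1L) + 10L)
    idx <- build_index(txs)
    peaks <- random_peak_set(15L)
    for (i in seq_len(nrow(peaks))) {
      got <- nearest_downstream_genes(peaks[i, ], idx)
      want <- oracle_ndg(peaks[i, ], txs)
      expect_equal(sort(got$overlapping$transcript_id), want$overlapping)
      got_fwd_d <- if (is.null(got$nearest_forward)) NA_integer_
        else got$nearest_forward$distance
      got_rev_d <- if (is.null(got$nearest_reverse)) NA_integer_
        else got$nearest_reverse$distance
      expect_equal(got_fwd_d, want$fwd_d)
      expect_equal(got_rev_d, want$rev_d)
    }
  }
})

test_that("mirroring coordinates and strands swaps forward and reverse", {
  set.seed(402)
  L <- 100000L
  txs <- random_transcript_set(120L)
  mirrored <- lapply(txs, function(t) {
    transcript(t$gene_id, t$transcript_id, t$chrom,
               if (t$strand == "+") "-" else "+",
               exons = cbind(L - t$exons[, 2L], L - t$exons[, 1L]),
               tx_start = L - t$tx_end, tx_end = L - t$tx_start)
  })
  idx <- build_index(txs)
  midx <- build_index(mirrored)
  peaks <- random_peak_set(25L)
  for (i in seq_len(nrow(peaks))) {
    a <- nearest_downstream_genes(peaks[i, ], idx)
    b <- nearest_downstream_genes(
      gintervals(peaks$chrom[i], L - peaks$end[i], L - peaks$start[i]),
      midx)
    fd <- function(s) if (is.null(s)) NA_integer_ else s$distance
    expect_equal(fd(a$nearest_forward), fd(b$nearest_reverse))
    expect_equal(fd(a$nearest_reverse), fd(b$nearest_forward))
  }
})

test_that("component classification walks the gene structure", {
  t_plus <- transcript("g", "t", "c1", "+",
                       exons = rbind(c(0L, 100L), c(200L, 300L)),
                       cds_start = 50L, cds_end = 250L)
  cls <- function(peak_start, peak_end, t) {
    classify_overlap(gintervals("c1", peak_start, peak_end), t)
  }
  # center 20 -> 5' UTR; 150 -> intron 1; 60 -> CDS; 270 -> 3' UTR
  expect_equal(cls(0L, 41L, t_plus)$type, "five_prime_utr")
  expect_equal(cls(100L, 201L, t_plus)$type, "intron")
  expect_equal(cls(100L, 201L, t_plus)$rank, 1L)
  expect_equal(cls(50L, 71L, t_plus)$type, "exon_cds")
  expect_equal(cls(260L, 281L, t_plus)$type, "three_prime_utr")
  # outside the span
  expect_equal(cls(310L, 320L, t_plus)$type, "downstream")

  # same structure on -: UTR polarity and intron ranks flip
  t_minus <- transcript("g", "t", "c1", "-",
                        exons = rbind(c(0L, 100L), c(200L, 300L)),
                        cds_start = 50L, cds_end = 250L)
  expect_equal(cls(260L, 281L, t_minus)$type, "five_prime_utr")
  expect_equal(cls(0L, 41L, t_minus)$type, "three_prime_utr")
  expect_equal(cls(310L, 320L, t_minus)$type, "upstream")

  # no CDS: exon hits are exon_cds
  t_nocds <- transcript("g", "t", "c1", "+", exons = cbind(0L, 100L))
  expect_equal(cls(10L, 21L, t_nocds)$type, "exon_cds")

  # intron ranks count in transcription order
  t3 <- transcript("g", "t", "c1", "-",
                   exons = rbind(c(0L, 10L), c(20L, 30L), c(40L, 50L)))
  expect_equal(cls(10L, 21L, t3)$rank, 2L)   # genomically first intron
  expect_equal(cls(30L, 41L, t3)$rank, 1L)   # abuts the first - exon
  expect_error(cls_bad <- classify_overlap(gintervals("c2", 0L, 10L), t3),
               "chromosome")
})

test_that("classification is total over transcript-spanning centers", {
  set.seed(403)
  txs <- random_transcript_set(50L)
  for (t in txs) {
    for (c0 in seq(t$tx_start - 2L, t$tx_end + 1L, by = 7L)) {
      got <- classify_overlap(gintervals(t$chrom, max(0L, c0), c0 + 1L), t)
      expect_true(got$type %in% c("five_prime_utr", "three_prime_utr",
                                  "exon_cds", "intron", "upstream",
                                  "downstream"))
      if (got$type == "intron") {
        expect_gte(got$rank, 1L)
        expect_lte(got$rank, nrow(t$exons) - 1L)
      }
    }
  }
})

test_that("nearest_tss matches the exhaustive scan and tie convention", {
  # center/TSS coincidence constructed exactly
  idx <- build_index(list(tx("t0", "c1", "+", 99L, 400L)))
  r <- nearest_tss(gintervals("c1", 90L, 110L), idx)
  expect_equal(r$signed_distance, 0L)
  expect_true(r$within_gene)

  # two + TSSs at 0 and 500, center 200: nearest is 0, peak downstream
  idx2 <- build_index(list(tx("a", "c1", "+", 0L, 2000L),
                           tx("b", "c1", "+", 500L, 2000L)))
  r2 <- nearest_tss(gintervals("c1", 195L, 206L), idx2)
  expect_equal(r2$transcript$transcript_id, "a")
  expect_equal(r2$signed_distance, 200L)

  # equidistant transcripts: smallest id wins, all ties reported
  idx3 <- build_index(list(tx("zz", "c1", "+", 300L, 400L),
                           tx("aa", "c1", "-", 0L, 101L)))
  r3 <- nearest_tss(gintervals("c1", 200L, 201L), idx3)
  expect_equal(r3$transcript$transcript_id, "aa")
  expect_equal(sort(r3$ties), c("aa", "zz"))

  set.seed(404)
  for (rep in 1:20) {
    txs <- random_transcript_set(500L)
    idx <- build_index(txs)
    peaks <- random_peak_set(25L)
    for (i in seq_len(nrow(peaks))) {
      got <- nearest_tss(peaks[i, ], idx)
      want <- oracle_tss(peaks[i, ], txs)
      expect_equal(got$transcript$transcript_id, want$id)
      expect_equal(got$signed_distance, want$signed)
    }
  }
})

test_that("distance profiles partition signed distances into shells", {
  empty <- profile_distances(data.frame(signed_distance = integer(0),
                                        within_gene = logical(0)))
  expect_true(all(empty$count == 0L))

  zeros <- profile_distances(data.frame(signed_distance = rep(0L, 10L),
                                        within_gene = rep(TRUE, 10L)))
  expect_equal(zeros$percent[zeros$bin == "within gene"], 100)

  # uniform on [-20k, 20k]: shell masses match the analytic proportions
  set.seed(405)
  d <- sample(-20000:20000, 40000L, replace = TRUE)
  prof <- profile_distances(data.frame(signed_distance = d,
                                       within_gene = FALSE))
  expect_equal(sum(prof$percent), 100, tolerance = 1e-9)
  get <- function(b) prof$percent[prof$bin == b]
  expect_equal(get("downstream 0bp-1kb"), 100 * 1001 / 40001,
               tolerance = 0.15)
  expect_equal(get("upstream 0bp-1kb"), 100 * 1000 / 40001,
               tolerance = 0.15)
  expect_equal(get("downstream 1kb-10kb"), 100 * 9000 / 40001,
               tolerance = 0.05)
  expect_equal(get("upstream >10kb"), 100 * 10000 / 40001,
               tolerance = 0.05)
  expect_error(profile_distances(data.frame(signed_distance = 1L,
                                            within_gene = FALSE),
                                 edges = c(10L, 5L)), "increasing")
})

test_that("component profiles group intron ranks as first/higher/last", {
  ic <- function(rank, n) {
    structure(list(type = "intron", rank = rank, n_introns = n),
              class = "component_class")
  }
  uc <- function(type) {
    structure(list(type = type, rank = NA_integer_, n_introns = 2L),
              class = "component_class")
  }
  empty <- profile_components(list())
  expect_true(all(empty$count == 0L))
  first_only <- profile_components(rep(list(ic(1L, 3L)), 10L))
  expect_equal(first_only$percent[first_only$component == "first intron"],
               100)
  mix <- profile_components(c(rep(list(ic(1L, 4L)), 3L),
                              rep(list(ic(2L, 4L)), 2L),
                              rep(list(ic(3L, 4L)), 1L),
                              rep(list(ic(4L, 4L)), 2L),
                              rep(list(uc("five_prime_utr")), 1L),
                              rep(list(uc("exon_cds")), 1L)))
  g <- function(b) mix$count[mix$component == b]
  expect_equal(g("first intron"), 3L)
  expect_equal(g("higher rank-order introns"), 3L)
  expect_equal(g("last intron"), 2L)
  expect_equal(g("5' UTR"), 1L)
  expect_equal(sum(mix$count), 10L)
  # formatted-string interface used by the command line
  mix2 <- profile_components(c("intron(1)", "intron(2)", "exon_cds"),
                             n_introns = c(2L, 2L, NA))
  expect_equal(sum(mix2$count), 3L)
})
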