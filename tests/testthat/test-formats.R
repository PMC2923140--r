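test_that("read_bed parses 3- and 6-column records verbatim", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=demo",
               "# a comment",
               "chr1\t100\t200",
               "chr1\t100\t200\tp1\t7.5\t-"), path)
  x <- read_bed(path)
  expect_equal(nrow(x), 2L)
  expect_equal(x$chrom, c("chr1", "chr1"))
  expect_equal(x$start, c(100L, 100L))
  expect_equal(x$end, c(200L, 200L))
  expect_equal(x$strand, c("*", "-"))
  expect_equal(x$name[2L], "p1")
  expect_equal(x$score[2L], 7.5)
})

test_that("read_bed rejects malformed lines with their line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t200\t100", path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("chr1\t10\t20", "chr1\tx\t30"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t10\t20", "chr1\t5"), path)
  expect_error(read_bed(path), "line 2")
})

test_that("BED round-trip reproduces coordinates, names and strands", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(empty_intervals <- gintervals(character(0), integer(0),
                                          integer(0)), path)
  expect_equal(nrow(read_bed(path)), 0L)

  set.seed(41)
  n <- 1000L
  start <- sample.int(1e6L, n)
  x <- gintervals(sample(paste0("chr", 1:5), n, replace = TRUE),
                  start, start + sample.int(5000L, n),
                  strand = sample(c("+", "-", "*"), n, replace = TRUE),
                  name = sprintf("p%04d", seq_len(n)),
                  score = round(stats::runif(n, 0, 100), 3))
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(y$chrom, x$chrom)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$strand, x$strand)
  expect_equal(y$name, x$name)
  expect_equal(y$score, x$score)
})

test_that("WIG dialects convert coordinates to 0-based and expand spans", {
  path <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=11 step=1", "5", "5", "7"), path)
  sig <- read_wig(path)
  expect_equal(signal_query(sig, "chr1", 10L, 13L), c(5, 5, 7))
  expect_equal(signal_query(sig, "chr1", 0L, 10L), rep(0, 10))

  writeLines(c("variableStep chrom=chr1 span=2", "11 4"), path)
  sig <- read_wig(path)
  expect_equal(signal_query(sig, "chr1", 10L, 12L), c(4, 4))
  expect_equal(signal_query(sig, "chr1", 12L, 13L), 0)

  writeLines("chr1\t10\t13\t6", path)
  sig <- read_wig(path)
  expect_equal(signal_query(sig, "chr1", 10L, 13L), c(6, 6, 6))

  # all three dialects in one file, non-colliding: union of the parts
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "1", "2",
               "variableStep chrom=chr2 span=1", "5 9",
               "chr3\t0\t2\t3"), path)
  sig <- read_wig(path)
  expect_equal(signal_query(sig, "chr1", 0L, 2L), c(1, 2))
  expect_equal(signal_query(sig, "chr2", 4L, 5L), 9)
  expect_equal(signal_query(sig, "chr3", 0L, 2L), c(3, 3))
})

test_that("WIG parse errors and collisions behave as documented", {
  path <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1", "-4"), path)
  expect_error(read_wig(path), "negative depth")
  writeLines("5 5", path)  # data before any directive
  expect_error(read_wig(path), "parse error")
  writeLines("fixedStep start=1", path)
  expect_error(read_wig(path), "chrom")
  # colliding blocks: last writer wins, with a warning
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "5",
               "fixedStep chrom=chr1 start=1 step=1", "9"), path)
  expect_warning(sig <- read_wig(path), "collide")
  expect_equal(signal_query(sig, "chr1", 0L, 1L), 9)
})

test_that("WIG write/read round-trips at base resolution", {
  set.seed(42)
  pos <- sort(sample.int(5000L, 600L)) - 1L
  depth <- round(stats::runif(600L, 0.5, 50), 4)
  sig <- signal_profile(rep("chr9", 600L), pos, depth)
  path <- withr::local_tempfile(fileext = ".wig")
  write_wig(sig, path)
  sig2 <- read_wig(path)
  expect_equal(signal_query(sig2, "chr9", 0L, 5000L),
               signal_query(sig, "chr9", 0L, 5000L))
})

test_that("read_gtf converts 1-based inclusive spans and groups exons", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    path)
  txs <- read_gtf(path)
  expect_length(txs, 1L)
  expect_equal(txs[[1L]]$tx_start, 99L)
  expect_equal(txs[[1L]]$tx_end, 200L)
  expect_equal(unname(txs[[1L]]$exons), cbind(99L, 200L),
               ignore_attr = TRUE)

  # out-of-order exons and a CDS: exons sorted, CDS span is the hull
  writeLines(c(
    'chr1\tsrc\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t150\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t300\t350\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    path)
  t <- read_gtf(path)[[1L]]
  expect_equal(t$exons[, 1L], c(99L, 299L))
  expect_equal(t$exons[, 2L], c(200L, 400L))
  expect_equal(t$cds_start, 149L)
  expect_equal(t$cds_end, 350L)
})

test_that("read_gtf rejects strandless or id-less gene models", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t100\t200\t.\t.\t.\tgene_id "g1"; transcript_id "t1";',
             path)
  expect_error(read_gtf(path), "strand")
  writeLines('chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1";', path)
  expect_error(read_gtf(path), "transcript_id")
})

test_that("GTF round-trip shifts start by one and keeps end, per record", {
  set.seed(43)
  txs <- random_transcript_set(60L)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(txs, path)
  raw <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  back <- read_gtf(path)
  by_id <- stats::setNames(back, vapply(back, `[[`, "", "transcript_id"))
  for (t in txs) {
    b <- by_id[[t$transcript_id]]
    expect_equal(b$tx_start, t$tx_start)
    expect_equal(b$tx_end, t$tx_end)
    expect_equal(b$exons, t$exons, ignore_attr = TRUE)
    expect_equal(b$strand, t$strand)
  }
  # per-record off-by-one: file start = internal start + 1, end unchanged
  ex <- raw[raw$V3 == "exon", ]
  internal <- do.call(rbind, lapply(txs, function(t)
    data.frame(id = t$transcript_id, s = t$exons[, 1L], e = t$exons[, 2L])))
  internal <- internal[order(internal$id, internal$s), ]
  tid <- gsub('.*transcript_id "([^"]+)".*', "\\1", ex$V9)
  ex <- ex[order(tid, ex$V4), ]
  expect_equal(ex$V4, internal$s + 1L)
  expect_equal(ex$V5, internal$e)
})

test_that("extract_sequence honours bounds and strand", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 test", "ACGTACGT"), path)
  genome <- read_genome(path)
  expect_equal(extract_sequence(genome, gintervals("chr1", 2L, 5L)), "GTA")
  expect_equal(extract_sequence(genome,
                                gintervals("chr1", 2L, 5L, strand = "-")),
               "TAC")
  expect_equal(extract_sequence(genome, gintervals("chr1", 0L, 8L)),
               "ACGTACGT")
  expect_error(extract_sequence(genome, gintervals("chr2", 0L, 3L)),
               "chromosome")
  expect_error(extract_sequence(genome, gintervals("chr1", 5L, 9L)),
               "exceeds")
})

test_that("load_chrom_sizes parses files and derives maxima from sets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000", "chr2\t500"), path)
  expect_equal(load_chrom_sizes(path), c(chr1 = 1000L, chr2 = 500L))
  writeLines("chr1\t0", path)
  expect_error(load_chrom_sizes(path), "non-positive")

  iv <- gintervals(c("chr2", "chr2"), c(0L, 400L), c(500L, 900L))
  expect_equal(load_chrom_sizes(iv), c(chr2 = 900L))
  expect_equal(length(load_chrom_sizes(gintervals(character(0), integer(0),
                                                  integer(0)))), 0L)
})
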