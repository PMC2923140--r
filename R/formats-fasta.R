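#' Load a genome FASTA into memory
#'
#' @param path Path to a FASTA file.
#' @return A `Biostrings::DNAStringSet` keyed by sequence name (the first
#'   whitespace-delimited token of each header).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("[ \t].*$", "", names(genome))
  genome
}

#' Extract the sequence of a genomic interval
#'
#' Returns the `end - start` bases of the interval; minus-strand
#' intervals are reverse-complemented.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param interval One-row interval table (see [gintervals()]).
#' @return A character scalar of DNA sequence.
#' @export
extract_sequence <- function(genome, interval) {
  x <- as_gintervals(interval)
  stopifnot(nrow(x) == 1L)
  if (!x$chrom %in% names(genome))
    stop("chromosome not in genome: ", x$chrom, call. = FALSE)
  if (x$end > length(genome[[x$chrom]]))
    stop(sprintf("interval %s:[%d,%d) exceeds chromosome length %d",
                 x$chrom, x$start, x$end, length(genome[[x$chrom]])),
         call. = FALSE)
  seq <- Biostrings::subseq(genome[[x$chrom]], start = x$start + 1L,
                            end = x$end)
  if (x$strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}

#' Write summit-window sequences as FASTA
#'
#' Headers follow `chrom:start-end|name`.
#'
#' @param genome A `DNAStringSet`.
#' @param windows Interval table of summit windows.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_window_fasta <- function(genome, windows, path) {
  w <- as_gintervals(windows)
  seqs <- character(nrow(w))
  for (i in seq_len(nrow(w))) seqs[i] <- extract_sequence(genome, w[i, ])
  headers <- sprintf("%s:%d-%d|%s", w$chrom, w$start, w$end,
                     ifelse(is.na(w$name), ".", w$name))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- headers
  Biostrings::writeXStringSet(out, path, width = 70L)
  invisible(path)
}
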