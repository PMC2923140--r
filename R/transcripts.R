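#' Construct a transcript gene model
#'
#' A transcript is a stranded gene model on one chromosome: an ordered set
#' of exons, an optional CDS span (from which UTRs are inferred), and the
#' transcript span. All coordinates are 0-based half-open. Strand is
#' required: the transcription start site (TSS) is `tx_start` on the
#' forward strand and `tx_end - 1` on the reverse strand.
#'
#' @param gene_id,transcript_id Identifier strings.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"` (unstranded transcripts are rejected:
#'   downstream-gene and TSS queries are undefined without a strand).
#' @param exons Two-column matrix (or list of pairs) of exon
#'   `(start, end)` spans; may be unsorted on input.
#' @param tx_start,tx_end Transcript span; defaults to the hull of the
#'   exons.
#' @param cds_start,cds_end Optional CDS span.
#' @return An object of class `"transcript"`.
#' @examples
#' transcript("g1", "t1", "chr1", "+", exons = rbind(c(0, 100), c(200, 300)),
#'            cds_start = 50, cds_end = 250)
#' @export
transcript <- function(gene_id, transcript_id, chrom, strand, exons,
                       tx_start = NULL, tx_end = NULL,
                       cds_start = NA_integer_, cds_end = NA_integer_) {
  if (!strand %in% c("+", "-"))
    stop("transcript strand must be '+' or '-'", call. = FALSE)
  if (is.list(exons)) exons <- do.call(rbind, exons)
  exons <- matrix(as.integer(exons), ncol = 2L)
  if (nrow(exons) == 0L) stop("a transcript needs >= 1 exon", call. = FALSE)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("exon start must be < end", call. = FALSE)
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons of one transcript must not overlap", call. = FALSE)
  tx_start <- as.integer(if (is.null(tx_start)) min(exons[, 1L]) else tx_start)
  tx_end <- as.integer(if (is.null(tx_end)) max(exons[, 2L]) else tx_end)
  if (tx_start > min(exons[, 1L]) || tx_end < max(exons[, 2L]))
    stop("exons must lie within the transcript span", call. = FALSE)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (!is.na(cds_start) || !is.na(cds_end)) {
    if (is.na(cds_start) || is.na(cds_end))
      stop("CDS needs both start and end", call. = FALSE)
    if (cds_start < tx_start || cds_end > tx_end || cds_start >= cds_end)
      stop("CDS span must satisfy tx_start <= cds_start < cds_end <= tx_end",
           call. = FALSE)
  }
  structure(
    list(gene_id = as.character(gene_id),
         transcript_id = as.character(transcript_id),
         chrom = as.character(chrom), strand = strand,
         tx_start = tx_start, tx_end = tx_end,
         cds_start = cds_start, cds_end = cds_end,
         exons = exons),
    class = "transcript")
}

#' Transcription start site of a transcript
#' @param t A `"transcript"` object.
#' @return 0-based genomic position of the TSS.
#' @export
tss_position <- function(t) {
  if (t$strand == "+") t$tx_start else t$tx_end - 1L
}

#' @export
print.transcript <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "no CDS"
         else sprintf("CDS [%d,%d)", x$cds_start, x$cds_end)
  cat(sprintf("<transcript %s (%s) %s:%d-%d %s, %d exon(s), %s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$tx_start, x$tx_end,
              x$strand, nrow(x$exons), cds))
  invisible(x)
}

#' Summarize a list of transcripts as an interval table
#' @param txs List of `"transcript"` objects.
#' @return Interval table of transcript spans (name = transcript_id).
#' @export
transcript_spans <- function(txs) {
  if (length(txs) == 0L) return(empty_gintervals())
  gintervals(vapply(txs, `[[`, "", "chrom"),
             vapply(txs, `[[`, 0L, "tx_start"),
             vapply(txs, `[[`, 0L, "tx_end"),
             strand = vapply(txs, `[[`, "", "strand"),
             name = vapply(txs, `[[`, "", "transcript_id"))
}
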