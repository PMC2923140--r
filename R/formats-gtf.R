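#' Read gene models from a GTF file
#'
#' Parses `exon`, `CDS` and (optionally) `transcript` feature lines. GTF
#' coordinates are 1-based inclusive; they are converted to the internal
#' 0-based half-open convention at the parser boundary (`start - 1`,
#' `end`). Exons are grouped by `transcript_id` and sorted; the transcript
#' span is the hull of its exons unless an explicit `transcript` line is
#' present; the CDS span is the hull of the transcript's CDS lines.
#'
#' @param path Path to a GTF file.
#' @return A list of [transcript()] objects, in order of first appearance.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop(sprintf("GTF parse error at line %d: fewer than 9 columns",
                 lineno[which(nf < 9L)[1L]]), call. = FALSE)
  feat <- vapply(fields, `[[`, "", 3L)
  use <- feat %in% c("exon", "CDS", "transcript")
  fields <- fields[use]
  lineno <- lineno[use]
  feat <- feat[use]
  if (length(fields) == 0L) return(list())
  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  strand <- vapply(fields, `[[`, "", 7L)
  attrs <- vapply(fields, `[[`, "", 9L)
  bad <- is.na(start1) | is.na(end1) | start1 < 1L | end1 < start1
  if (any(bad))
    stop(sprintf("GTF parse error at line %d: bad coordinates",
                 lineno[which(bad)[1L]]), call. = FALSE)
  bad <- !strand %in% c("+", "-")
  if (any(bad))
    stop(sprintf(
      "GTF parse error at line %d: strand must be '+' or '-' for gene models",
      lineno[which(bad)[1L]]), call. = FALSE)
  tid <- gtf_attr(attrs, "transcript_id")
  gid <- gtf_attr(attrs, "gene_id")
  bad <- is.na(tid)
  if (any(bad))
    stop(sprintf("GTF parse error at line %d: missing transcript_id",
                 lineno[which(bad)[1L]]), call. = FALSE)
  gid[is.na(gid)] <- tid[is.na(gid)]
  start0 <- start1 - 1L  # 1-based inclusive -> 0-based half-open
  end0 <- end1
  out <- list()
  for (t in unique(tid)) {
    i <- which(tid == t)
    ex <- i[feat[i] == "exon"]
    if (length(ex) == 0L)
      stop(sprintf("GTF parse error: transcript '%s' has no exon lines", t),
           call. = FALSE)
    if (length(unique(chrom[i])) > 1L || length(unique(strand[i])) > 1L)
      stop(sprintf(
        "GTF parse error: transcript '%s' spans chromosomes or strands", t),
        call. = FALSE)
    cds <- i[feat[i] == "CDS"]
    txl <- i[feat[i] == "transcript"]
    out[[t]] <- transcript(
      gene_id = gid[i[1L]], transcript_id = t,
      chrom = chrom[i[1L]], strand = strand[i[1L]],
      exons = cbind(start0[ex], end0[ex]),
      tx_start = if (length(txl)) min(start0[txl]) else NULL,
      tx_end = if (length(txl)) max(end0[txl]) else NULL,
      cds_start = if (length(cds)) min(start0[cds]) else NA_integer_,
      cds_end = if (length(cds)) max(end0[cds]) else NA_integer_)
  }
  unname(out)
}

#' @keywords internal
gtf_attr <- function(attrs, key) {
  pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m), function(g) {
    if (length(g) >= 2L) g[2L] else NA_character_
  }, "")
}

#' Write gene models as GTF
#'
#' Inverse of [read_gtf()]: internal 0-based half-open spans become
#' 1-based inclusive records (`start + 1`, `end`). One `exon` line per
#' exon and one `CDS` line per exon/CDS intersection.
#'
#' @param txs List of [transcript()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(txs, path) {
  rows <- character(0)
  fmt <- function(t, feature, s0, e0) {
    sprintf(
      "%s\tpeaktools\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      t$chrom, feature, s0 + 1L, e0, t$strand, t$gene_id, t$transcript_id)
  }
  for (t in txs) {
    rows <- c(rows, fmt(t, "transcript", t$tx_start, t$tx_end))
    for (k in seq_len(nrow(t$exons))) {
      s <- t$exons[k, 1L]; e <- t$exons[k, 2L]
      rows <- c(rows, fmt(t, "exon", s, e))
      if (!is.na(t$cds_start)) {
        cs <- max(s, t$cds_start); ce <- min(e, t$cds_end)
        if (cs < ce) rows <- c(rows, fmt(t, "CDS", cs, ce))
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}
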