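#' Minimal SAM ingest and export
#'
#' `read_sam()` parses a plain-text SAM file into the package's
#' alignment table: unmapped records (flag 0x4) are skipped, MAPQ 0 is
#' treated as non-unique, and CIGARs are retained so gapped alignments
#' (indels) flow into the pileup. Malformed records are rejected with
#' their line number. `write_sam()` round-trips the table back to SAM
#' with `@SQ` headers taken from `contigs`.
#'
#' This reader covers the subset of SAM this pipeline produces and
#' consumes (single-end records, CIGAR ops M/=/X/I/D/S); it is not a
#' general-purpose SAM implementation.
#'
#' @param path SAM file path.
#' @param contigs optional named contig sequences; when given, mismatch
#'   counts are computed against them.
#' @return data.frame of class `read_alignments` (see [map_reads()]).
#' @export
read_sam <- function(path, contigs = NULL) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  rows <- vector("list", length(body))
  for (k in seq_along(body)) {
    ln <- body[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop_("malformed SAM record (fewer than 11 fields) at line ", ln)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(flag) || is.na(pos) || is.na(mapq))
      stop_("malformed SAM record (non-numeric FLAG/POS/MAPQ) at line ", ln)
    if (bitwAnd(flag, 4L) != 0L) next
    if (!grepl("^([0-9]+[MIDNSHP=X])+$", f[6]))
      stop_("malformed CIGAR '", f[6], "' at line ", ln)
    rows[[k]] <- data.frame(
      read_id = f[1], contig = f[3], start = pos,
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      mismatches = NA_integer_, unique = mapq > 0L, mapq = mapq,
      cigar = f[6], seq = f[10], qual = f[11], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(read_id = character(), contig = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), unique = logical(),
                      mapq = integer(), cigar = character(),
                      seq = character(), qual = character())
  if (!is.null(contigs) && nrow(res) > 0) {
    for (i in seq_len(nrow(res))) {
      walked <- walk_cigar(res$cigar[i], res$start[i], res$seq[i],
                           res$qual[i])
      m <- walked[walked$op %in% c("M", "X", "="), ]
      refb <- substring(contigs[[res$contig[i]]], m$rpos, m$rpos)
      res$mismatches[i] <- sum(refb != m$base)
    }
  }
  rownames(res) <- NULL
  class(res) <- c("read_alignments", "data.frame")
  res
}

#' @rdname read_sam
#' @param alignments a `read_alignments` table.
#' @export
write_sam <- function(alignments, contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(contigs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(contigs[[nm]])), con)
  if (nrow(alignments) > 0) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       alignments$read_id, flag, alignments$contig,
                       alignments$start, alignments$mapq, alignments$cigar,
                       alignments$seq, alignments$qual), con)
  }
  invisible(path)
}

# expand a CIGAR into per-base records: reference position (rpos, 1-based;
# NA for insertions), op, read base, numeric quality. Insertions are
# attached to the last consumed reference position as op "I".
walk_cigar <- function(cigar, start, seq, qual) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  rpos <- start; qpos <- 1L
  recs <- list()
  qv <- utf8ToInt(qual) - 33L
  sv <- chars(seq)
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X")) {
      idx <- seq_len(n[k])
      recs[[length(recs) + 1]] <- data.frame(
        rpos = rpos + idx - 1L, op = op[k], base = sv[qpos + idx - 1L],
        qual = qv[qpos + idx - 1L], stringsAsFactors = FALSE)
      rpos <- rpos + n[k]; qpos <- qpos + n[k]
    } else if (op[k] == "I") {
      recs[[length(recs) + 1]] <- data.frame(
        rpos = rpos - 1L, op = "I",
        base = collapse(sv[qpos:(qpos + n[k] - 1L)]),
        qual = qv[qpos], stringsAsFactors = FALSE)
      qpos <- qpos + n[k]
    } else if (op[k] == "D") {
      recs[[length(recs) + 1]] <- data.frame(
        rpos = rpos + seq_len(n[k]) - 1L, op = "D", base = "-",
        qual = NA_integer_, stringsAsFactors = FALSE)
      rpos <- rpos + n[k]
    } else if (op[k] %in% c("S", "H", "P")) {
      if (op[k] == "S") qpos <- qpos + n[k]
    } else if (op[k] == "N") {
      rpos <- rpos + n[k]
    }
  }
  do.call(rbind, recs)
}
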