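#' All-against-all alignment hit table
#'
#' Aligns every query against every subject with [smith_waterman()] and
#' tabulates the hits in BLAST tabular (outfmt-6 compatible) layout, with
#' E-values computed against the whole subject set
#' (`n` = sum of subject lengths, `m` = query length). Self-hits (same id
#' on both sides) are skipped.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param scheme a calibrated [scoring_scheme()].
#' @return data.frame with columns `qid, sid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, score`, plus
#'   `coverage_longer` and `log10_evalue`.
#' @export
alignment_table <- function(queries, subjects, scheme) {
  if (length(queries) == 0 || length(subjects) == 0)
    stop_("queries and subjects must be non-empty")
  if (is.null(names(queries)) || is.null(names(subjects)))
    stop_("queries and subjects must be named")
  n_db <- sum(nchar(subjects))
  rows <- vector("list", length(queries) * length(subjects))
  k <- 0L
  for (qi in seq_along(queries)) {
    for (si in seq_along(subjects)) {
      qid <- names(queries)[qi]; sid <- names(subjects)[si]
      if (identical(qid, sid)) next
      h <- smith_waterman(queries[[qi]], subjects[[si]], scheme)
      k <- k + 1L
      rows[[k]] <- data.frame(
        qid = qid, sid = sid,
        pident = if (h$length > 0) 100 * h$identities / h$length else 0,
        length = h$length,
        mismatch = h$length - h$gaps - h$identities,
        gapopen = count_gap_opens(h$aligned),
        qstart = h$qstart, qend = h$qend,
        sstart = h$sstart, send = h$send,
        evalue = evalue(h$score, nchar(queries[[qi]]), n_db, scheme),
        score = h$score,
        coverage_longer = h$coverage_longer,
        log10_evalue = log10_evalue(h$score, nchar(queries[[qi]]), n_db, scheme),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

count_gap_opens <- function(aligned) {
  n_opens <- function(s) {
    r <- rle(chars(s) == "-")
    sum(r$values)
  }
  n_opens(aligned[1]) + n_opens(aligned[2])
}

# best hit per query: highest score, ties broken by lowest subject id
best_hit_per_query <- function(hits) {
  hits <- hits[order(hits$qid, -hits$score, hits$sid), ]
  hits[!duplicated(hits$qid), ]
}

#' Family membership search
#'
#' A query is accepted into the family iff its best-scoring reference hit
#' has E-value below `threshold` and the reciprocal best-hit relation
#' holds: the reference member that is the query's best hit must itself
#' have that query as its best hit among all queries. Ties are broken by
#' score then lexicographic subject id.
#'
#' @param queries named character vector of candidate sequences.
#' @param family_reference named character vector of known family members.
#' @param threshold E-value acceptance cutoff.
#' @param scheme a calibrated [scoring_scheme()]; defaults to
#'   [blosum62_scheme()].
#' @return data.frame of accepted queries (`qid`, matched `sid`, `evalue`,
#'   `score`), with the full hit table as attribute `"hits"`.
#' @export
search_family <- function(queries, family_reference, threshold = 1e-15,
                          scheme = blosum62_scheme()) {
  if (length(family_reference) == 0) stop_("family reference must be non-empty")
  fwd <- alignment_table(queries, family_reference, scheme)
  rev <- alignment_table(family_reference, queries, scheme)
  bf <- best_hit_per_query(fwd)
  br <- best_hit_per_query(rev)
  rev_best <- setNames(br$sid, br$qid)
  keep <- bf$evalue < threshold & rev_best[bf$sid] == bf$qid
  keep[is.na(keep)] <- FALSE
  out <- bf[keep, c("qid", "sid", "evalue", "score")]
  rownames(out) <- NULL
  attr(out, "hits") <- fwd
  out
}

#' Remove exact-duplicate sequences
#'
#' Collapses records whose residue strings are identical, keeping the
#' first id for each distinct string; input order is preserved
#' (idempotent).
#'
#' @param sequences named character vector.
#' @return named character vector of distinct sequences.
#' @export
dedupe <- function(sequences) {
  sequences[!duplicated(unname(sequences))]
}

#' Write a hit table as tab-separated BLAST tabular output
#'
#' @param hits data.frame from [alignment_table()].
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  cols <- c("qid", "sid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "score")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
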