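#' Reciprocal-best-hit ortholog pairing
#'
#' Pairs (a, b) such that b is a's best-scoring hit in set B, a is b's
#' best-scoring hit in set A, both directional E-values are below
#' `evalue_max`, and the alignment covers strictly more than
#' `min_coverage` of the longer protein (alignment length, gaps included,
#' divided by the longer sequence's length). Ties for best hit are broken
#' by score then lexicographic subject id; self-hits are excluded when the
#' two sets share ids. The result is one-to-one by construction.
#'
#' @param set_A,set_B named character vectors of protein sequences
#'   (variety A = domesticated, variety B = wild by convention).
#' @param evalue_max E-value cutoff (both directions).
#' @param min_coverage coverage-of-longer cutoff (strict `>`).
#' @param scheme a calibrated [scoring_scheme()]; defaults to
#'   [blosum62_scheme()].
#' @return data.frame of class `ortholog_pairs` with columns `id_A`,
#'   `id_B`, `score`, `evalue`, `length`, `identities`, `pident`,
#'   `coverage_longer`.
#' @export
reciprocal_best_hits <- function(set_A, set_B, evalue_max = 1e-20,
                                 min_coverage = 0.80,
                                 scheme = blosum62_scheme()) {
  if (length(set_A) == 0 || length(set_B) == 0)
    stop_("both sequence sets must be non-empty")
  if (is.null(names(set_A)) || is.null(names(set_B)))
    stop_("sequence sets must be named")
  nA <- length(set_A); nB <- length(set_B)
  n_db_B <- sum(nchar(set_B)); n_db_A <- sum(nchar(set_A))

  enc_A <- lapply(set_A, encode_seq, alphabet = scheme$alphabet)
  enc_B <- lapply(set_B, encode_seq, alphabet = scheme$alphabet)
  score <- cpp_sw_score_matrix(enc_A, enc_B, scheme$matrix,
                               scheme$gap_open, scheme$gap_extend)
  dimnames(score) <- list(names(set_A), names(set_B))
  shared <- intersect(names(set_A), names(set_B))
  for (nm in shared) score[nm, nm] <- -Inf   # exclude self-hits
  best_j <- apply(score, 1, function(s) {
    top <- which(s == max(s))
    top[order(colnames(score)[top])][1]
  })
  best_i <- apply(score, 2, function(s) {
    top <- which(s == max(s))
    top[order(rownames(score)[top])][1]
  })
  rows <- list()
  for (i in seq_len(nA)) {
    j <- best_j[i]
    if (best_i[j] != i) next
    e_ab <- evalue(score[i, j], nchar(set_A[[i]]), n_db_B, scheme)
    e_ba <- evalue(score[i, j], nchar(set_B[[j]]), n_db_A, scheme)
    if (!(e_ab < evalue_max && e_ba < evalue_max)) next
    # full alignment (traceback) only for mutual best hits
    h <- smith_waterman(set_A[[i]], set_B[[j]], scheme)
    if (!(h$coverage_longer > min_coverage)) next
    rows[[length(rows) + 1]] <- data.frame(
      id_A = names(set_A)[i], id_B = names(set_B)[j],
      score = score[i, j],
      evalue = max(e_ab, e_ba),
      length = h$length, identities = h$identities,
      pident = 100 * h$identities / h$length,
      coverage_longer = h$coverage_longer, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_A = character(), id_B = character(), score = numeric(),
               evalue = numeric(), length = numeric(),
               identities = numeric(), pident = numeric(),
               coverage_longer = numeric())
  rownames(out) <- NULL
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}

#' Redundant (unpaired) copies after ortholog pairing
#'
#' A family member with no reciprocal-best-hit partner in the other
#' variety is a redundant copy -- the signature of a variety-specific
#' duplication. `|pairs| + |redundant_A| = |A|` always holds (and
#' likewise for B).
#'
#' @param pairs an `ortholog_pairs` table from [reciprocal_best_hits()].
#' @param set_A,set_B the same named sets the pairs were computed from.
#' @return list with character vectors `redundant_A`, `redundant_B`.
#' @export
classify_redundant <- function(pairs, set_A, set_B) {
  list(redundant_A = setdiff(names(set_A), pairs$id_A),
       redundant_B = setdiff(names(set_B), pairs$id_B))
}
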