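#' @title Pairwise alignment
#' @name pairwise-alignment
#' @description
#' `smith_waterman()` computes the optimal local alignment under affine
#' gaps (Gotoh's algorithm); `needleman_wunsch()` the optimal global
#' alignment. Both return an `alignment_hit` carrying the raw score,
#' alignment length (columns, gaps included), identities and
#' coverage-of-longer -- the alignment length divided by the longer
#' sequence's length, the quantity thresholded at 80% in the orthology
#' stage.
#'
#' @param a,b sequences (single character strings over the scheme's
#'   alphabet).
#' @param scheme a [scoring_scheme()].
#' @param ids optional length-2 character vector of query/subject ids.
#' @return an `alignment_hit`: list with `score`, `length`, `identities`,
#'   `gaps`, `coverage_longer`, 1-based coordinates
#'   (`qstart`,`qend`,`sstart`,`send`), and the gapped `aligned` strings.
NULL

encode_seq <- function(s, alphabet) {
  v <- chars(toupper(s))
  idx <- match(v, alphabet)
  if (anyNA(idx)) {
    bad <- unique(v[is.na(idx)])
    stop_("symbol(s) outside scheme alphabet: ", paste(bad, collapse = ", "))
  }
  idx
}

hit_from_path <- function(res, a, b, local) {
  path <- res$path
  if (length(path) == 0) {
    return(structure(list(score = res$score, length = 0L, identities = 0L,
                          gaps = 0L, coverage_longer = 0,
                          qstart = NA_integer_, qend = NA_integer_,
                          sstart = NA_integer_, send = NA_integer_,
                          aligned = c("", "")), class = "alignment_hit"))
  }
  av <- chars(a); bv <- chars(b)
  ai <- res$astart; bi <- res$bstart
  outa <- character(length(path)); outb <- character(length(path))
  for (k in seq_along(path)) {
    op <- path[k]
    if (op == 1L) { outa[k] <- av[ai]; outb[k] <- bv[bi]; ai <- ai + 1L; bi <- bi + 1L }
    else if (op == 2L) { outa[k] <- av[ai]; outb[k] <- "-"; ai <- ai + 1L }
    else { outa[k] <- "-"; outb[k] <- bv[bi]; bi <- bi + 1L }
  }
  ident <- sum(path == 1L & outa == outb)
  structure(list(
    score = res$score,
    length = length(path),
    identities = as.integer(ident),
    gaps = as.integer(sum(path != 1L)),
    coverage_longer = length(path) / max(nchar(a), nchar(b)),
    qstart = res$astart, qend = res$aend,
    sstart = res$bstart, send = res$bend,
    aligned = c(collapse(outa), collapse(outb))),
    class = "alignment_hit")
}

#' @rdname pairwise-alignment
#' @export
smith_waterman <- function(a, b, scheme, ids = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop_("sequences must be non-empty")
  ea <- encode_seq(a, scheme$alphabet)
  eb <- encode_seq(b, scheme$alphabet)
  res <- cpp_pairwise_align(ea, eb, scheme$matrix, scheme$gap_open,
                            scheme$gap_extend, TRUE)
  hit <- hit_from_path(res, a, b, TRUE)
  hit$ids <- ids
  hit
}

#' @rdname pairwise-alignment
#' @export
needleman_wunsch <- function(a, b, scheme, ids = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop_("sequences must be non-empty")
  ea <- encode_seq(a, scheme$alphabet)
  eb <- encode_seq(b, scheme$alphabet)
  res <- cpp_pairwise_align(ea, eb, scheme$matrix, scheme$gap_open,
                            scheme$gap_extend, FALSE)
  hit <- hit_from_path(res, a, b, FALSE)
  hit$ids <- ids
  hit
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf("<alignment_hit> score=%g length=%d identities=%d (%.1f%%) coverage_longer=%.3f\n",
              x$score, x$length, x$identities,
              if (x$length > 0) 100 * x$identities / x$length else 0,
              x$coverage_longer))
  invisible(x)
}
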