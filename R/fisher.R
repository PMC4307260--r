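#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities of
#' all tables with the observed margins whose probability does not
#' exceed the observed table's (with the customary relative slack of
#' 1e-7 for floating-point ties, as in `stats::fisher.test`). A table
#' with a zero margin carries no information; its p is 1 by convention
#' and the result is flagged with attribute `degenerate = TRUE`.
#'
#' @param tab 2x2 matrix (or length-4 vector, column-major) of
#'   non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.vector(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_("counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_   # column 1 margin
  n <- b + d    # column 2 margin
  k <- a + b    # row 1 margin
  if (m == 0 || n == 0 || k == 0 || c_ + d == 0)
    return(structure(1, degenerate = TRUE))
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Chi-square contingency test (optional alternative)
#'
#' Pearson chi-square without continuity correction on the 2x2 table;
#' provided as a faster large-count alternative to
#' [fisher_exact_2x2()]. Degenerate margins return p = 1, flagged.
#'
#' @inheritParams fisher_exact_2x2
#' @export
chisq_2x2 <- function(tab) {
  tab <- matrix(as.vector(tab), 2, 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(structure(1, degenerate = TRUE))
  unname(suppressWarnings(chisq.test(tab, correct = FALSE)$p.value))
}
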