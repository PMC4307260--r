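#' Scoring schemes for pairwise alignment
#'
#' A scoring scheme bundles an integer substitution matrix, affine gap
#' penalties and residue background frequencies, plus the Karlin-Altschul
#' parameters (`lambda`, `K`) that put raw alignment scores on an E-value
#' scale. A gap of length L scores `gap_open + L * gap_extend` (both
#' non-positive), so the first gap character already pays the opening charge.
#'
#' @param matrix square integer substitution matrix with identical row and
#'   column names (the alphabet).
#' @param gap_open,gap_extend gap penalties (scores, `<= 0`).
#' @param background named numeric vector of residue background frequencies
#'   over the alphabet; defaults to uniform. Normalised to sum to 1.
#' @param calibrate compute `lambda` and `K` (requires a negative expected
#'   score and a positive maximum score).
#' @return an object of class `scoring_scheme`.
#' @seealso [blosum62_scheme()], [simple_scheme()], [calibrate_karlin_altschul()]
#' @export
scoring_scheme <- function(matrix, gap_open = -11, gap_extend = -1,
                           background = NULL, calibrate = TRUE) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop_("substitution matrix must be square")
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
    stop_("substitution matrix must have identical row/column names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop_("substitution matrix must be symmetric")
  if (gap_open > 0 || gap_extend > 0)
    stop_("gap penalties are scores and must be <= 0")
  ab <- rownames(matrix)
  if (is.null(background)) {
    background <- setNames(rep(1 / length(ab), length(ab)), ab)
  } else {
    if (!all(ab %in% names(background)))
      stop_("background frequencies must cover the full alphabet")
    background <- background[ab]
    if (any(background <= 0)) stop_("background frequencies must be positive")
    background <- background / sum(background)
  }
  scheme <- structure(
    list(matrix = matrix, alphabet = ab, gap_open = gap_open,
         gap_extend = gap_extend, background = background,
         lambda = NULL, K = NULL, H = NULL),
    class = "scoring_scheme")
  if (calibrate) {
    ka <- calibrate_karlin_altschul(matrix, background)
    scheme$lambda <- ka$lambda
    scheme$K <- ka$K
    scheme$H <- ka$H
  }
  scheme
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %d-letter alphabet, gap %g/%g",
              length(x$alphabet), x$gap_open, x$gap_extend))
  if (!is.null(x$lambda))
    cat(sprintf(", lambda=%.4f, K=%.4f", x$lambda, x$K))
  cat("\n")
  invisible(x)
}

# Robinson & Robinson (1991) amino-acid background frequencies, the
# standard protein background for ungapped Karlin-Altschul statistics.
robinson_frequencies <- function() {
  c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
    Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
    L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
    S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
}

#' BLOSUM62 protein scheme with BLAST-style default gaps
#'
#' BLOSUM62 over the 20 standard amino acids (matrix from
#' \pkg{Biostrings}), gap open -11 / extend -1, Robinson-Robinson
#' background frequencies. Karlin-Altschul parameters are the ungapped
#' ones, used for gapped scores as in classical BLAST; E-values are
#' therefore approximate but conservative on near-identical family
#' members, which is how they are used here (hard threshold cutoffs).
#'
#' @param gap_open,gap_extend gap penalties (scores).
#' @return a `scoring_scheme`.
#' @export
blosum62_scheme <- function(gap_open = -11, gap_extend = -1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  aa <- names(robinson_frequencies())
  m <- env$BLOSUM62[aa, aa]
  scoring_scheme(m, gap_open = gap_open, gap_extend = gap_extend,
                 background = robinson_frequencies())
}

#' Simple match/mismatch scheme
#'
#' @param match,mismatch integer scores.
#' @param alphabet character vector of symbols.
#' @param gap_open,gap_extend gap penalties; the defaults give a linear
#'   per-character gap cost of `gap_extend`.
#' @param calibrate compute Karlin-Altschul parameters.
#' @return a `scoring_scheme`.
#' @export
simple_scheme <- function(match = 1, mismatch = -1,
                          alphabet = c("A", "C", "G", "T"),
                          gap_open = 0, gap_extend = -1, calibrate = TRUE) {
  k <- length(alphabet)
  m <- matrix(mismatch, k, k, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  scoring_scheme(m, gap_open = gap_open, gap_extend = gap_extend,
                 calibrate = calibrate)
}

# probability distribution of the pairwise score of two background residues,
# as a named numeric vector over the integer score support
score_distribution <- function(matrix, background) {
  p <- outer(background, background)
  s <- as.vector(matrix)
  if (max(abs(s - round(s))) > 1e-9)
    stop_("substitution scores must be integers for calibration")
  s <- as.integer(round(s))
  tapply(as.vector(p), s, sum)
}

#' Karlin-Altschul calibration of an ungapped scoring system
#'
#' Computes `lambda` as the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`, the relative entropy `H`, and
#' the prefactor `K` by the standard series for lattice score
#' distributions: with span `d` (the gcd of score differences),
#' `K = d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))` where
#' `sigma = sum_k (1/k) * (E[exp(lambda * S_k); S_k < 0] + P(S_k >= 0))`
#' over k-step sums `S_k` of i.i.d. pairwise scores, truncated when terms
#' fall below `tol`.
#'
#' @param matrix integer substitution matrix (square, symmetric, named).
#' @param background named residue background frequencies (normalised
#'   internally).
#' @param tol truncation tolerance for the `K` series.
#' @param max_terms cap on the number of series terms.
#' @return list with `lambda` (nats per score unit), `K`, and `H` (nats per
#'   aligned pair).
#' @export
calibrate_karlin_altschul <- function(matrix, background = NULL,
                                      tol = 1e-10, max_terms = 1000) {
  if (is.null(background))
    background <- setNames(rep(1 / nrow(matrix), nrow(matrix)), rownames(matrix))
  background <- background[rownames(matrix)]
  background <- background / sum(background)
  pr <- score_distribution(matrix, background)
  s <- as.integer(names(pr))
  mean_score <- sum(pr * s)
  if (mean_score >= 0)
    stop_("expected pairwise score must be negative (no positive root for lambda)")
  if (max(s) <= 0)
    stop_("maximum score must be positive")

  f <- function(lam) sum(pr * exp(lam * s)) - 1
  hi <- 0.5
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  H <- lambda * sum(pr * s * exp(lambda * s))

  # lattice span: the subgroup of the integers generated by the score
  # support (the values the walk maximum can take), i.e. the gcd of the
  # attainable scores
  d <- 0L
  for (v in s[pr > 0]) d <- gcd_int(d, abs(v))
  if (d == 0L) d <- 1L

  # sigma series over convolution powers of the score distribution
  lo <- min(s); hi_s <- max(s)
  base <- numeric(hi_s - lo + 1)
  base[s - lo + 1] <- pr
  cur <- base
  cur_lo <- lo
  sigma <- 0
  for (k in seq_len(max_terms)) {
    if (k > 1) {
      cur <- conv_full(cur, base)
      cur_lo <- cur_lo + lo
    }
    vals <- seq.int(cur_lo, length.out = length(cur))
    neg <- vals < 0
    term <- (sum(cur[neg] * exp(lambda * vals[neg])) + sum(cur[!neg])) / k
    sigma <- sigma + term
    if (term < tol) break
  }
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# full linear convolution of two probability vectors
conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(b)) {
    idx <- seq_along(a) + i - 1L
    out[idx] <- out[idx] + a * b[i]
  }
  out
}

#' E-value of an alignment score
#'
#' `E = K * m * n * exp(-lambda * score)` for query length `m` against a
#' database of total length `n`. Scores large enough to underflow return 0,
#' which compares correctly against any positive threshold; `log10_evalue()`
#' is provided where the magnitude itself is of interest.
#'
#' @param score raw alignment score.
#' @param m query length (residues).
#' @param n database length (sum of subject lengths).
#' @param scheme calibrated `scoring_scheme`.
#' @return E-value (vectorised over `score`).
#' @export
evalue <- function(score, m, n, scheme) {
  if (is.null(scheme$lambda) || is.null(scheme$K))
    stop_("scheme is not calibrated (lambda/K missing); build it with calibrate = TRUE")
  if (m <= 0 || n <= 0) stop_("m and n must be positive")
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' @rdname evalue
#' @export
log10_evalue <- function(score, m, n, scheme) {
  if (is.null(scheme$lambda) || is.null(scheme$K))
    stop_("scheme is not calibrated (lambda/K missing); build it with calibrate = TRUE")
  (log(scheme$K) + log(m) + log(n) - scheme$lambda * score) / log(10)
}
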