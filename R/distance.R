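#' Pairwise distances from a multiple alignment
#'
#' p-distance (proportion of differing sites) or Poisson-corrected
#' distance `-ln(1 - p)` between every pair of aligned rows, with
#' pairwise deletion of gap columns: for each pair only columns where
#' both rows are ungapped are compared.
#'
#' @param msa an `msa` (or named character vector of equal-length rows).
#' @param model `"poisson"` (default, the usual protein correction) or
#'   `"p"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- if (inherits(msa, "msa")) as.matrix(msa) else
    do.call(rbind, strsplit(msa, "", fixed = TRUE))
  if (is.null(rownames(m))) rownames(m) <- names(msa)
  n <- nrow(m)
  gap <- m == "-"
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop_("no comparable (ungapped) columns between ", rownames(m)[i],
            " and ", rownames(m)[j])
    p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    if (model == "poisson" && p >= 1)
      stop_("Poisson correction undefined for saturated pair (p = 1): ",
            rownames(m)[i], " vs ", rownames(m)[j])
    d <- if (model == "p") p else -log(1 - p)
    D[i, j] <- D[j, i] <- d
  }
  D
}
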