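#' Neighbor-joining tree reconstruction
#'
#' Standard Saitou-Nei agglomeration: repeatedly joins the pair (i, j)
#' minimising `Q_ij = (n - 2) d_ij - r_i - r_j` (ties broken by lowest
#' index pair, for deterministic reruns), with the usual branch-length
#' formulas. A negative branch length is clamped to 0 and the deficit
#' moved to the sister edge, preserving the path length through the new
#' node. On additive input distances the tree's path lengths reproduce
#' the matrix exactly.
#'
#' @param D symmetric distance matrix with at least 3 labelled taxa.
#' @param tol asymmetry tolerance.
#' @return an unrooted `phylo` (\pkg{ape}) tree with branch lengths.
#' @export
neighbor_joining <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop_("D must be a square matrix")
  if (nrow(D) < 3) stop_("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > tol) stop_("distance matrix is asymmetric")
  labels <- rownames(D) %||% paste0("t", seq_len(nrow(D)))

  # active nodes carry Newick fragments; joining glues fragments together
  frag <- newick_escape(labels)
  Dm <- D
  while (nrow(Dm) > 3) {
    n <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (Q[i, j] < best[1]) best <- c(Q[i, j], i, j)
    i <- best[2]; j <- best[3]
    bi <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- Dm[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newd <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    newd <- newd[-c(i, j)]
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], bi, frag[j], bj)
    frag <- c(frag[-c(i, j)], newfrag)
    Dm <- rbind(cbind(Dm[-c(i, j), -c(i, j), drop = FALSE], newd),
                c(newd, 0))
  }
  # final three-taxon star, closed form
  b1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  b2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  b3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  bs <- c(b1, b2, b3)
  for (k in 1:3) if (bs[k] < 0) {
    others <- setdiff(1:3, k)
    bs[others] <- bs[others] + bs[k] / 2
    bs[k] <- 0
  }
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], bs[1], frag[2], bs[2], frag[3], bs[3])
  ape::read.tree(text = nwk)
}

newick_escape <- function(x) {
  if (any(grepl("[(),:;]", x)))
    stop_("taxon labels may not contain Newick metacharacters")
  x
}

#' Path-length (patristic) distances of a tree
#' @param tree a `phylo`.
#' @return symmetric matrix of leaf-to-leaf path lengths.
#' @export
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
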