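#' Bootstrap splits, consensus and support mapping
#'
#' `bootstrap_consensus()` resamples alignment columns with replacement,
#' rebuilds a neighbor-joining tree per replicate (replicate `r` uses seed
#' `seed + r`, so replicates are reproducible independently), and returns
#' the majority-rule consensus: the tree of all splits occurring in a
#' fraction of replicates strictly greater than `threshold`, labelled
#' with their frequencies in percent. With `method = "map"` it instead
#' returns the full-data NJ tree with each internal edge labelled by the
#' percentage of replicates containing its split (the usual
#' "NJ tree with bootstrap values").
#'
#' @param msa an `msa`.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param threshold retention threshold as a fraction, in `[0.5, 1)`.
#' @param seed master seed.
#' @param model distance model, see [distance_matrix()].
#' @param method `"consensus"` (majority rule) or `"map"` (supports on the
#'   full-data NJ tree).
#' @return a `phylo` whose internal `node.label`s are supports in percent.
#' @export
bootstrap_consensus <- function(msa, replicates = 1000, threshold = 0.5,
                                seed = 1, model = "poisson",
                                method = c("consensus", "map")) {
  method <- match.arg(method)
  if (replicates < 1) stop_("replicates must be >= 1")
  if (threshold < 0.5 || threshold >= 1)
    stop_("threshold must be in [0.5, 1)")
  m <- as.matrix(msa)
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- with_seed(seed + r, sample.int(ncol(m), ncol(m), replace = TRUE))
    rows <- apply(m[, cols, drop = FALSE], 1, collapse)
    trees[[r]] <- neighbor_joining(distance_matrix(rows, model))
  }
  if (method == "consensus") {
    consensus_from_trees(trees, threshold)
  } else {
    ref <- neighbor_joining(distance_matrix(apply(m, 1, collapse), model))
    map_supports(ref, trees)
  }
}

# canonical split of each internal edge: the tip set on the far side of
# the edge, complemented if it contains the reference taxon (the
# alphabetically first label), encoded as a sorted comma-joined string
tree_splits <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  n <- length(tips)
  internal <- tree$edge[, 2] > n
  out <- character(0)
  for (node in tree$edge[internal, 2]) {
    cl <- tips[clade_tips(tree, node)]
    if (ref %in% cl) cl <- setdiff(tips, cl)
    if (length(cl) >= 2 && length(cl) <= n - 2)
      out <- c(out, paste(sort(cl), collapse = ","))
  }
  unique(out)
}

# tip indices descending from an internal node
clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- integer(0)
  while (length(kids)) {
    out <- c(out, kids[kids <= n])
    kids <- tree$edge[tree$edge[, 1] %in% kids[kids > n], 2]
  }
  out
}

#' Majority-rule consensus of a set of trees
#'
#' Retains every non-trivial split whose frequency across `trees` is
#' strictly greater than `threshold` (> 0.5 guarantees pairwise
#' compatibility) and assembles them into a tree; internal nodes are
#' labelled with the split frequency in percent. Branch lengths are not
#' defined for a consensus and are omitted.
#'
#' @param trees list of `phylo` objects on the same taxa.
#' @param threshold fraction in `[0.5, 1)`.
#' @return a `phylo` with `node.label` supports in percent.
#' @export
consensus_from_trees <- function(trees, threshold = 0.5) {
  if (threshold < 0.5 || threshold >= 1)
    stop_("threshold must be in [0.5, 1)")
  tips <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), tips))
      stop_("all trees must share the same taxa")
  counts <- table(unlist(lapply(trees, tree_splits)))
  freq <- as.numeric(counts) / length(trees)
  keep <- freq > threshold
  splits <- lapply(strsplit(names(counts)[keep], ",", fixed = TRUE), sort)
  supp <- round(100 * freq[keep], 6)

  # laminar family (none contains the reference taxon): nest by size
  ord <- order(-vapply(splits, length, integer(1)))
  splits <- splits[ord]; supp <- supp[ord]
  build <- function(members, active) {
    # newick fragments for the children partitioning `members`;
    # `active` holds indices of splits contained in `members`, size-desc
    frags <- character(0)
    placed <- character(0)
    while (length(active)) {
      i <- active[1]
      rest <- active[-1]
      inner <- rest[vapply(rest, function(j)
        all(splits[[j]] %in% splits[[i]]), logical(1))]
      frags <- c(frags, paste0(
        "(", paste(build(splits[[i]], inner), collapse = ","), ")",
        format(supp[i], trim = TRUE)))
      placed <- c(placed, splits[[i]])
      active <- setdiff(active, c(i, inner))
    }
    c(frags, newick_escape(setdiff(members, placed)))
  }
  nwk <- paste0("(", paste(build(tips, seq_along(splits)), collapse = ","),
                ");")
  ape::read.tree(text = nwk)
}

#' @rdname bootstrap_consensus
#' @param tree reference `phylo` to annotate.
#' @param trees list of replicate trees.
#' @export
map_supports <- function(tree, trees) {
  counts <- table(unlist(lapply(trees, tree_splits)))
  n <- length(tree$tip.label)
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  labs <- character(tree$Nnode)
  for (node in (n + 1):(n + tree$Nnode)) {
    cl <- tips[clade_tips(tree, node)]
    if (ref %in% cl) cl <- setdiff(tips, cl)
    key <- paste(sort(cl), collapse = ",")
    if (length(cl) >= 2 && length(cl) <= n - 2 && key %in% names(counts))
      labs[node - n] <- format(round(100 * counts[[key]] / length(trees), 6),
                               trim = TRUE)
    else if (length(cl) < 2 || length(cl) > n - 2)
      labs[node - n] <- ""   # trivial split (root or cherry-adjacent)
    else labs[node - n] <- "0"
  }
  tree$node.label <- labs
  tree
}
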