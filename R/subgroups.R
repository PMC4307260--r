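#' Cluster and subgroup classification from a supported tree
#'
#' Partitions the leaves of an unrooted tree with branch lengths and
#' per-edge supports into `n_clusters` clusters and, within them,
#' `n_subgroups` subgroups, by removing the longest well-supported
#' internal edges: the `n_subgroups - 1` longest internal edges with
#' support >= `min_support` are cut and the connected leaf components
#' are the subgroups; the coarser partition induced by the
#' `n_clusters - 1` longest of those same edges gives the clusters, so
#' subgroups always nest inside clusters. Deep family splits correspond
#' to the longest supported edges, which is what makes this cut rule
#' recover a planted cluster/subgroup hierarchy.
#'
#' Clusters are labelled with Roman numerals (I, II, ...) in decreasing
#' size order; subgroups are numbered within their cluster in decreasing
#' size order (`I-1`, `I-2`, ...). Singleton subgroups are allowed.
#'
#' @param tree a `phylo` with branch lengths and `node.label` supports in
#'   percent (e.g. from [bootstrap_consensus()] with `method = "map"`).
#' @param n_clusters number of clusters to extract.
#' @param min_support minimum edge support (percent) for an edge to be a
#'   candidate cut.
#' @param n_subgroups total number of subgroups across all clusters;
#'   defaults to `n_clusters` (one subgroup per cluster).
#' @return data.frame with columns `id`, `cluster`, `subgroup`; every
#'   leaf appears exactly once.
#' @export
extract_subgroups <- function(tree, n_clusters, min_support = 50,
                              n_subgroups = NULL) {
  n_subgroups <- n_subgroups %||% n_clusters
  if (n_subgroups < n_clusters)
    stop_("n_subgroups must be at least n_clusters")
  n <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stop_("tree must have branch lengths")
  internal <- which(tree$edge[, 2] > n)
  supp <- edge_supports(tree)
  qual <- internal[!is.na(supp[internal]) & supp[internal] >= min_support]
  need <- max(n_clusters, n_subgroups) - 1L
  if (length(qual) < need)
    stop_("only ", length(qual), " internal edges with support >= ",
          min_support, " but ", need, " cuts requested")
  qual <- qual[order(-tree$edge.length[qual], qual)]

  # greedy: walk the supported edges longest-first and cut an edge only if
  # it actually increases the number of leaf components (adjacent cuts can
  # isolate an internal node and waste a cut)
  cuts <- integer(0)
  n_comp <- 1L
  effective <- integer(0)
  for (e in qual) {
    if (length(effective) >= n_subgroups - 1L) break
    trial <- c(cuts, e)
    k <- length(unique(leaf_components(tree, trial)))
    if (k > n_comp) {
      cuts <- trial; n_comp <- k
      effective <- c(effective, e)
    }
  }
  if (length(effective) < n_subgroups - 1L)
    stop_("only ", length(effective), " effective supported cuts (support >= ",
          min_support, ") but ", n_subgroups - 1L, " needed")
  cut_sub <- effective
  cut_clu <- effective[seq_len(n_clusters - 1L)]

  comp_sub <- leaf_components(tree, cut_sub)
  comp_clu <- leaf_components(tree, cut_clu)

  lab_clu <- label_by_size(comp_clu, as.roman)
  out <- data.frame(id = tree$tip.label,
                    cluster = lab_clu[as.character(comp_clu)],
                    stringsAsFactors = FALSE)
  out$subgroup <- NA_character_
  for (cl in unique(out$cluster)) {
    idx <- out$cluster == cl
    sub <- comp_sub[idx]
    lab <- label_by_size(sub, function(i) i)
    out$subgroup[idx] <- paste0(cl, "-", lab[as.character(sub)])
  }
  rownames(out) <- NULL
  out
}

# support of each edge = node label of its (internal) child, as numeric;
# NA for tip edges and unlabelled nodes
edge_supports <- function(tree) {
  n <- length(tree$tip.label)
  supp <- rep(NA_real_, nrow(tree$edge))
  if (!is.null(tree$node.label)) {
    child <- tree$edge[, 2]
    int <- child > n
    lab <- tree$node.label[child[int] - n]
    supp[int] <- suppressWarnings(as.numeric(lab))
  } else {
    supp[tree$edge[, 2] > n] <- 100  # unlabelled: treat as fully supported
  }
  supp
}

# connected components of the leaves after deleting `cut` edges (indices
# into tree$edge); returns an integer component id per leaf
leaf_components <- function(tree, cut) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  parent <- seq_len(nn)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  keep <- setdiff(seq_len(nrow(tree$edge)), cut)
  for (e in keep) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

# map component ids to labels ordered by decreasing size (ties: by the
# alphabetically first member leaf, for determinism)
label_by_size <- function(comp, labeller) {
  sz <- table(comp)
  firsts <- tapply(names(comp) %||% as.character(seq_along(comp)), comp, min)
  ord <- order(-as.vector(sz), as.vector(firsts))
  ids <- names(sz)[ord]
  setNames(as.character(labeller(seq_along(ids))), ids)
}
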