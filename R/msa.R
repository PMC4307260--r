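#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by average-linkage clustering of pairwise global
#' alignment distances (1 - identity), then merges groups bottom-up by
#' profile-profile global alignment with affine gaps. Profiles are
#' per-column residue frequency vectors (over the rows in the group, gaps
#' contributing nothing); the column-column score is the
#' frequency-weighted expected substitution score.
#'
#' Ungapping any output row reproduces its input sequence exactly.
#'
#' @param sequences named character vector (>= 2 sequences).
#' @param scheme a [scoring_scheme()]; defaults to [blosum62_scheme()].
#' @return an object of class `msa`: named character vector of equal-length
#'   aligned rows (input order), with attribute `width`.
#' @export
progressive_msa <- function(sequences, scheme = blosum62_scheme()) {
  n <- length(sequences)
  if (n < 2) stop_("progressive alignment needs at least 2 sequences")
  if (is.null(names(sequences))) names(sequences) <- paste0("s", seq_len(n))
  enc <- lapply(sequences, encode_seq, alphabet = scheme$alphabet)

  if (n == 2) {
    hit <- needleman_wunsch(sequences[[1]], sequences[[2]], scheme)
    return(new_msa(setNames(hit$aligned, names(sequences))))
  }

  # guide distances: 1 - identity of the pairwise global alignment
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- needleman_wunsch(sequences[[i]], sequences[[j]], scheme)
    D[i, j] <- D[j, i] <- 1 - h$identities / h$length
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  # groups of aligned rows, merged along the hclust merge order
  groups <- lapply(seq_len(n), function(i) sequences[i])
  merged <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    pick <- function(v) if (v < 0) groups[[-v]] else merged[[v]]
    ga <- pick(hc$merge[k, 1]); gb <- pick(hc$merge[k, 2])
    merged[[k]] <- merge_profiles(ga, gb, scheme)
  }
  rows <- merged[[n - 1]]
  new_msa(rows[names(sequences)])
}

new_msa <- function(rows) {
  w <- unique(nchar(rows))
  stopifnot(length(w) == 1)
  structure(rows, width = w, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x), attr(x, "width")))
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unclass(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

#' Remove gaps from aligned rows
#' @param msa an `msa` (or character vector of aligned rows).
#' @return named character vector of ungapped sequences.
#' @export
ungap <- function(msa) {
  vapply(unclass(msa), function(s) gsub("-", "", s, fixed = TRUE),
         character(1))
}

profile_of <- function(rows, alphabet) {
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  prof <- matrix(0, length(alphabet), ncol(m))
  for (a in seq_along(alphabet))
    prof[a, ] <- colSums(m == alphabet[a])
  prof / length(rows)   # gap mass simply missing from the column
}

merge_profiles <- function(rows_a, rows_b, scheme) {
  pa <- profile_of(rows_a, scheme$alphabet)
  pb <- profile_of(rows_b, scheme$alphabet)
  S <- crossprod(pa, scheme$matrix %*% pb)
  path <- cpp_matrix_align(S, scheme$gap_open, scheme$gap_extend)
  ins_gaps <- function(rows, consume_op) {
    take <- path == 1L | path == consume_op
    vapply(rows, function(s) {
      v <- character(length(path))
      v[take] <- chars(s)
      v[!take] <- "-"
      collapse(v)
    }, character(1))
  }
  c(ins_gaps(rows_a, 2L), ins_gaps(rows_b, 3L))
}
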