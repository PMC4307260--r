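#' Species-by-subgroup copy-number tables
#'
#' A `copy_table` is an integer matrix of gene-copy counts with species
#' as rows and subgroup columns named `<cluster>.<subgroup>` (cluster
#' III, which has no subgroups, is the single column `III`). Totals are
#' always derived from the cells.
#'
#' @param counts integer matrix (species x subgroups).
#' @return an object of class `copy_table`.
#' @export
copy_table <- function(counts) {
  if (!is.matrix(counts)) stop_("counts must be a matrix")
  if (any(counts < 0)) stop_("counts must be non-negative")
  structure(counts, class = c("copy_table", class(counts)))
}

#' @export
print.copy_table <- function(x, ...) {
  cat(sprintf("<copy_table> %d species x %d subgroups, grand total %d\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' @rdname copy_table
#' @param x a `copy_table`.
#' @export
grand_total <- function(x) sum(x)

#' @rdname copy_table
#' @param cluster cluster label, e.g. `"I"`.
#' @export
cluster_total <- function(x, cluster) {
  sum(x[, cluster_of(colnames(x)) == cluster, drop = FALSE])
}

cluster_of <- function(cols) sub("[.].*$", "", cols)

#' Build a copy table from per-sequence subgroup assignments
#'
#' @param assignments data.frame with columns `id`, `species`, `subgroup`
#'   (subgroup in `<cluster>-<n>` or `<cluster>.<n>` form).
#' @return a `copy_table` (species x subgroup counts).
#' @export
copy_number_matrix <- function(assignments) {
  a <- as.data.frame(assignments)
  if (nrow(a) == 0)
    return(copy_table(matrix(0L, 0, 0)))
  missing <- is.na(a$species) | !nzchar(a$species)
  if (any(missing))
    stop_("sequence(s) without species metadata: ",
          paste(a$id[missing], collapse = ", "))
  sub <- gsub("-", ".", a$subgroup, fixed = TRUE)
  tab <- table(a$species, sub)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  # order columns by cluster (roman) then subgroup number
  cl <- cluster_of(colnames(m))
  num <- suppressWarnings(as.integer(sub("^[^.]*[.]", "", colnames(m))))
  num[is.na(num)] <- 0L
  m <- m[, order(as.integer(utils::as.roman(cl)), num), drop = FALSE]
  copy_table(m)
}

#' Read a copy-number table from TSV
#'
#' Expects leading annotation columns (e.g. kingdom/group) before the
#' species column, then one integer column per subgroup.
#'
#' @param path TSV path.
#' @param species_col name of the species column.
#' @return a `copy_table`.
#' @export
read_copy_table <- function(path, species_col = "species") {
  x <- read.delim(path, check.names = FALSE)
  first_count <- which(vapply(x, is.numeric, logical(1)))[1]
  m <- as.matrix(x[, first_count:ncol(x)])
  rownames(m) <- x[[species_col]]
  storage.mode(m) <- "integer"
  copy_table(m)
}

#' The packaged SAMe superfamily copy-number table
#'
#' The published 19-species copy-number matrix of the SAMe
#' methyltransferase superfamily (subgroups I-1..I-14, II-1..II-11 and
#' cluster III), transcribed cell-for-cell, together with the table's
#' own printed per-subgroup totals row. The two layers are kept separate
#' because the publication's per-species cells and its printed totals
#' row disagree slightly (columns I-4, I-10 and III); family-wide
#' summaries should use the printed totals, per-species comparisons the
#' cells.
#'
#' @return list with `counts` (a [copy_table()]) and `printed_totals`
#'   (named integer vector over the same columns).
#' @export
sames_copy_table <- function() {
  counts <- read_copy_table(
    system.file("extdata", "sames_copy_number_table.tsv",
                package = "samefam", mustWork = TRUE))
  tot <- read.delim(
    system.file("extdata", "sames_copy_number_totals.tsv",
                package = "samefam", mustWork = TRUE))
  list(counts = counts,
       printed_totals = setNames(as.integer(tot$count), tot$subgroup))
}

#' Subgroups where one variety exceeds another
#'
#' Lists the subgroups in which the copy number of `variety_A` is
#' strictly greater than that of `variety_B`, with the per-subgroup
#' difference.
#'
#' @param x a `copy_table`.
#' @param variety_A,variety_B row names.
#' @return data.frame with columns `subgroup` (in `<cluster>-<n>` form),
#'   `copies_A`, `copies_B`, `difference`.
#' @export
compare_copy_numbers <- function(x, variety_A, variety_B) {
  for (v in c(variety_A, variety_B))
    if (!v %in% rownames(x)) stop_("row not found in copy table: ", v)
  a <- x[variety_A, ]; b <- x[variety_B, ]
  idx <- which(a > b)
  out <- data.frame(
    subgroup = gsub(".", "-", colnames(x)[idx], fixed = TRUE),
    copies_A = as.integer(a[idx]), copies_B = as.integer(b[idx]),
    difference = as.integer(a[idx] - b[idx]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' The packaged subgroup expression and variation table
#'
#' Published per-gene RPKM values (domesticated bud, domesticated flower,
#' wild bud) and the amino-acid variation annotation for the ortholog
#' pairs of the copy-expanded subgroups.
#'
#' @return data.frame with columns `subgroup`, `pfam`, `gene_A`,
#'   `gene_B`, `rpkm_A_bud`, `rpkm_A_flower`, `rpkm_B_bud`,
#'   `aa_variation`.
#' @export
sames_expression_table <- function() {
  read.delim(system.file("extdata", "sames_expression_table.tsv",
                         package = "samefam", mustWork = TRUE))
}
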