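#' Translate a coding sequence
#'
#' Standard genetic code, reading frame 1; translation stops at the
#' first stop codon (not included), trailing bases short of a codon are
#' ignored, and any codon containing a non-ACGT symbol translates to
#' `X`.
#'
#' @param cds nucleotide string (length >= 3).
#' @return protein string.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) < 3) stop_("CDS must be at least one codon long")
  code <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3
  starts <- (seq_len(n) - 1L) * 3L + 1L
  codons <- substring(toupper(cds), starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  collapse(aa)
}

#' Amino-acid differences between an ortholog pair
#'
#' Globally aligns the two proteins and reports every aligned column
#' with differing residues as a change positioned on the variety-A
#' protein (1-based), in the field's `<pos><refA>/<altB>` notation
#' (e.g. `365A/E`). Alignment gap columns are reported separately as
#' indel annotations (attribute `"indels"`), not as residue changes.
#'
#' @param protein_A,protein_B protein strings (variety A listed first,
#'   positions indexed on A).
#' @param scheme protein [scoring_scheme()]; defaults to
#'   [blosum62_scheme()].
#' @return data.frame of class `aa_changes` with columns `pos`, `ref`,
#'   `alt`, `label`, positions strictly increasing; attribute `"indels"`
#'   is a data.frame (`pos_A`, `type`, `length`).
#' @export
aa_changes <- function(protein_A, protein_B, scheme = blosum62_scheme()) {
  if (!nzchar(protein_A) || !nzchar(protein_B))
    stop_("proteins must be non-empty")
  h <- needleman_wunsch(protein_A, protein_B, scheme)
  av <- chars(h$aligned[1]); bv <- chars(h$aligned[2])
  apos <- cumsum(av != "-")
  diffs <- which(av != bv & av != "-" & bv != "-")
  changes <- data.frame(pos = apos[diffs], ref = av[diffs], alt = bv[diffs],
                        stringsAsFactors = FALSE)
  changes$label <- sprintf("%d%s/%s", changes$pos, changes$ref, changes$alt)
  gapcols <- which(av == "-" | bv == "-")
  indels <- data.frame(pos_A = integer(), type = character(),
                       length = integer())
  if (length(gapcols)) {
    runs <- split(gapcols, cumsum(c(1, diff(gapcols) != 1)))
    indels <- do.call(rbind, lapply(runs, function(r) {
      data.frame(pos_A = max(apos[r[1]], 1L),
                 type = if (av[r[1]] == "-") "insertion" else "deletion",
                 length = length(r), stringsAsFactors = FALSE)
    }))
    rownames(indels) <- NULL
  }
  attr(changes, "indels") <- indels
  class(changes) <- c("aa_changes", "data.frame")
  changes
}

#' Render amino-acid changes as in published variation tables
#'
#' Joins the labels with `", "`; an identical pair renders as `"none"`.
#'
#' @param changes an `aa_changes` table.
#' @export
format_aa_changes <- function(changes) {
  if (nrow(changes) == 0) "none" else paste(changes$label, collapse = ", ")
}
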