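#' Pileup of aligned reads over contigs
#'
#' Expands each alignment's CIGAR into per-base records and stacks them
#' per reference position. Deletions contribute a `-` allele at each
#' deleted position; insertions contribute a `+SEQ` allele attached to
#' the preceding reference position. With `unique_only`, alignments
#' flagged non-unique are excluded entirely.
#'
#' @param alignments a `read_alignments` table ([map_reads()] or
#'   [read_sam()]).
#' @param contigs named contig sequences (alignments overrunning a contig
#'   are rejected).
#' @param unique_only drop non-unique alignments.
#' @return data.frame of class `pileup`: `contig`, `pos` (1-based),
#'   `allele`, `qual`, `unique`, one row per read base.
#' @export
pileup <- function(alignments, contigs, unique_only = FALSE) {
  if (unique_only) alignments <- alignments[alignments$unique, , drop = FALSE]
  rows <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    w <- walk_cigar(alignments$cigar[i], alignments$start[i],
                    alignments$seq[i], alignments$qual[i])
    if (!alignments$contig[i] %in% names(contigs))
      stop_("alignment to unknown contig: ", alignments$contig[i])
    cl <- nchar(contigs[[alignments$contig[i]]])
    if (max(w$rpos, na.rm = TRUE) > cl)
      stop_("alignment of ", alignments$read_id[i], " overruns contig ",
            alignments$contig[i])
    allele <- ifelse(w$op == "I", paste0("+", w$base), w$base)
    rows[[i]] <- data.frame(contig = alignments$contig[i], pos = w$rpos,
                            allele = allele, qual = w$qual,
                            unique = alignments$unique[i],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(contig = character(), pos = integer(),
                      allele = character(), qual = integer(),
                      unique = logical())
  rownames(res) <- NULL
  class(res) <- c("pileup", "data.frame")
  res
}

# per-site slice of a pileup
site_slice <- function(pile, contig, pos) {
  pile[pile$contig == contig & pile$pos == pos, , drop = FALSE]
}

# allele counts at a site, sorted decreasing
site_counts <- function(pile, contig, pos) {
  s <- site_slice(pile, contig, pos)
  sort(table(s$allele), decreasing = TRUE)
}

#' Candidate variant calls from a pileup
#'
#' Every position carrying at least one non-reference allele becomes a
#' candidate. The alternate allele is the most frequent non-reference
#' allele (ties broken lexicographically); `-` and `+SEQ` alleles yield
#' indel candidates, bases yield SNPs. Coverage counts base-consuming
#' reads at the position (insertion records are alleles, not coverage).
#'
#' @param pile a `pileup`.
#' @param ref_contigs named reference contig sequences.
#' @return data.frame of class `variant_calls`: `contig`, `pos`, `ref`,
#'   `alt`, `type`, `alt_count`, `coverage`, `mean_qual`, `status`
#'   (unset, `NA`).
#' @export
call_candidates <- function(pile, ref_contigs) {
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      type = character(), alt_count = integer(),
                      coverage = integer(), mean_qual = numeric(),
                      status = character())
  if (nrow(pile) == 0) {
    class(empty) <- c("variant_calls", "data.frame")
    return(empty)
  }
  key <- paste(pile$contig, pile$pos)
  rows <- list()
  for (k in unique(key)) {
    s <- pile[key == k, , drop = FALSE]
    contig <- s$contig[1]; pos <- s$pos[1]
    ref <- substr(ref_contigs[[contig]], pos, pos)
    nonref <- s$allele[s$allele != ref & s$allele != "+"]
    if (length(nonref) == 0) next
    tab <- sort(table(nonref), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    alt <- sort(top)[1]
    base_rows <- s$allele != "-" & !startsWith(s$allele, "+")
    rows[[length(rows) + 1]] <- data.frame(
      contig = contig, pos = pos, ref = ref, alt = alt,
      type = if (alt == "-" || startsWith(alt, "+")) "indel" else "SNP",
      alt_count = as.integer(tab[[alt]]),
      coverage = as.integer(sum(base_rows) + sum(s$allele == "-")),
      mean_qual = mean(s$qual[base_rows]),
      status = NA_character_, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty
  res <- res[order(res$contig, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("variant_calls", "data.frame")
  res
}
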