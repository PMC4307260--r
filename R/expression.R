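#' RPKM: reads per kilobase of transcript per million mapped reads
#'
#' `1e9 * count / (length * total_mapped)`. Vectorised over `count` and
#' `length`.
#'
#' @param count mapped read count(s).
#' @param length transcript length(s) in bp (> 0).
#' @param total_mapped library size: total mapped reads (> 0).
#' @return RPKM value(s); 0 iff `count` is 0.
#' @export
rpkm <- function(count, length, total_mapped) {
  if (any(length <= 0)) stop_("transcript length must be positive")
  if (any(total_mapped <= 0)) stop_("total mapped reads must be positive")
  if (any(count < 0)) stop_("read counts must be non-negative")
  1e9 * count / (length * total_mapped)
}

#' Invert RPKM back to a read count
#' @inheritParams rpkm
#' @param value RPKM value(s).
#' @export
rpkm_to_count <- function(value, length, total_mapped) {
  value * length * total_mapped / 1e9
}

#' Variety- and tissue-differential expression calls
#'
#' For each gene with RPKM measured in variety-A bud, variety-A flower
#' and variety-B bud, computes the fold change between varieties (bud
#' vs bud) and between tissues (within variety A) as max/min after
#' flooring values at `floor` RPKM, and flags a contrast as differential
#' when the fold reaches `fold_threshold`. Additionally, a contrast with
#' one side at literal 0 and the other at `zero_vs` RPKM or more is
#' always flagged, whatever the floored fold. Genes that are
#' variety-differential but not tissue-differential are the candidates
#' related to the varietal difference rather than to flower development.
#'
#' @param records data.frame with columns `gene`, `rpkm_A_bud`,
#'   `rpkm_A_flower`, `rpkm_B_bud` (no missing values).
#' @param fold_threshold fold-change cutoff (`>=`), default 2.
#' @param floor value at which zeros (and near-zeros) are floored before
#'   forming the ratio, in RPKM units.
#' @param zero_vs RPKM level that makes a 0-vs-positive contrast an
#'   automatic flag.
#' @return data.frame of class `contrast_calls`: `gene`, `fold_variety`,
#'   `fold_tissue` (both >= 1), `variety_differential`,
#'   `tissue_differential`, `candidate`.
#' @export
contrast <- function(records, fold_threshold = 2, floor = 1, zero_vs = 5) {
  need <- c("gene", "rpkm_A_bud", "rpkm_A_flower", "rpkm_B_bud")
  if (!all(need %in% names(records)))
    stop_("records needs columns: ", paste(need, collapse = ", "))
  for (col in need[-1]) {
    bad <- is.na(records[[col]])
    if (any(bad))
      stop_("missing ", col, " for gene(s): ",
            paste(records$gene[bad], collapse = ", "))
  }
  fold <- function(x, y) {
    fx <- pmax(x, floor); fy <- pmax(y, floor)
    pmax(fx, fy) / pmin(fx, fy)
  }
  zero_rule <- function(x, y)
    (x == 0 & y >= zero_vs) | (y == 0 & x >= zero_vs)
  fv <- fold(records$rpkm_A_bud, records$rpkm_B_bud)
  ft <- fold(records$rpkm_A_bud, records$rpkm_A_flower)
  vd <- fv >= fold_threshold |
    zero_rule(records$rpkm_A_bud, records$rpkm_B_bud)
  td <- ft >= fold_threshold |
    zero_rule(records$rpkm_A_bud, records$rpkm_A_flower)
  out <- data.frame(gene = records$gene, fold_variety = fv,
                    fold_tissue = ft, variety_differential = vd,
                    tissue_differential = td, candidate = vd & !td,
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_calls", "data.frame")
  out
}

#' Fold change of summed subgroup expression between varieties
#'
#' Ratio of the summed RPKM of the subgroup's members in variety A to the
#' summed RPKM of its members in variety B. A zero denominator with a
#' positive numerator is reported as infinite and flagged.
#'
#' @param rpkm_A,rpkm_B named RPKM vectors for the two varieties.
#' @param members_A,members_B the subgroup's member ids in each variety.
#' @return list with `fold`, `sum_A`, `sum_B`, `infinite`.
#' @export
subgroup_fold <- function(rpkm_A, rpkm_B, members_A, members_B) {
  if (length(members_A) == 0 || length(members_B) == 0)
    stop_("member lists must be non-empty")
  miss <- c(setdiff(members_A, names(rpkm_A)),
            setdiff(members_B, names(rpkm_B)))
  if (length(miss)) stop_("members without RPKM: ", paste(miss, collapse = ", "))
  sa <- sum(rpkm_A[members_A]); sb <- sum(rpkm_B[members_B])
  inf <- sb == 0 && sa > 0
  list(fold = if (inf) Inf else sa / sb, sum_A = sa, sum_B = sb,
       infinite = inf)
}

#' Comparative-Ct relative quantification (2^-ddCt)
#'
#' `dCt = Ct_target - Ct_reference` per sample, `ddCt = dCt_sample -
#' dCt_calibrator`, relative abundance `2^-ddCt`; the calibrator sample
#' is 1 by construction.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct`.
#' @param target target gene id.
#' @param reference endogenous control gene id (must be measured in every
#'   sample).
#' @param calibrator calibrator sample id.
#' @return named numeric vector of relative abundances per sample.
#' @export
ddct <- function(ct, target, reference, calibrator) {
  get_ct <- function(g, s) {
    v <- ct$ct[ct$gene == g & ct$sample == s]
    if (length(v) != 1) NA_real_ else v
  }
  samples <- unique(ct$sample[ct$gene == target])
  ref <- vapply(samples, function(s) get_ct(reference, s), numeric(1))
  if (anyNA(ref))
    stop_("reference gene ", reference, " missing in sample(s): ",
          paste(samples[is.na(ref)], collapse = ", "))
  if (!calibrator %in% samples) stop_("calibrator sample not measured: ",
                                      calibrator)
  tar <- vapply(samples, function(s) get_ct(target, s), numeric(1))
  dct <- tar - ref
  ddct <- dct - dct[samples == calibrator]
  setNames(2^(-ddct), samples)
}

#' Format RPKM for reporting (two decimals, as in published tables)
#' @param x numeric RPKM.
#' @export
format_rpkm <- function(x) sprintf("%.2f", x)
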