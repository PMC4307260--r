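#' Filter thresholds for the variant cascade
#'
#' Defaults follow the pipeline's published filter settings: minimum
#' site coverage 8 reads, minimum mean base quality 20, a third allele
#' supported by more than 2 reads disqualifies the site, candidate sites
#' closer than 60 bp are mutually removed, at least 21 uniquely aligned
#' reads (i.e. strictly more than 20) across the two varieties, and a
#' two-sided contingency p-value below 0.01.
#'
#' @param min_coverage minimum reads covering the site in the calling
#'   pileup.
#' @param min_mean_quality minimum mean Phred quality of covering bases.
#' @param max_third_allele_reads maximum reads supporting any allele
#'   other than ref and alt.
#' @param cluster_window candidates on the same contig closer than this
#'   many bp are removed (both of them). Set `NA` to disable.
#' @param min_unique_reads minimum uniquely aligned reads at the site.
#' @param unique_scope `"pooled"` (across both varieties, the default)
#'   or `"per_variety"`.
#' @param max_p contingency-test p-value must be strictly below this.
#' @param third_allele_filter,cluster_filter enable flags for the two
#'   interpretation-dependent sub-filters.
#' @return list of class `variant_thresholds`.
#' @export
variant_thresholds <- function(min_coverage = 8, min_mean_quality = 20,
                               max_third_allele_reads = 2,
                               cluster_window = 60, min_unique_reads = 21,
                               unique_scope = c("pooled", "per_variety"),
                               max_p = 0.01, third_allele_filter = TRUE,
                               cluster_filter = TRUE) {
  unique_scope <- match.arg(unique_scope)
  th <- list(min_coverage = min_coverage,
             min_mean_quality = min_mean_quality,
             max_third_allele_reads = max_third_allele_reads,
             cluster_window = cluster_window,
             min_unique_reads = min_unique_reads,
             unique_scope = unique_scope, max_p = max_p,
             third_allele_filter = third_allele_filter,
             cluster_filter = cluster_filter)
  num <- unlist(th[c("min_coverage", "min_mean_quality",
                     "max_third_allele_reads", "min_unique_reads",
                     "max_p")])
  if (any(num < 0)) stop_("thresholds must be non-negative")
  class(th) <- "variant_thresholds"
  th
}

#' Ordered filter cascade over candidate variants
#'
#' Applies the site-level disqualification rules in a fixed order and
#' records the first failing stage in `status`
#' (`pass` or `fail:<filter>`):
#' 1. `coverage` -- reads covering the site in the calling (cross-variety)
#'    pileup below `min_coverage`;
#' 2. `quality` -- mean base quality of those reads below
#'    `min_mean_quality`;
#' 3. `third_allele` -- an allele other than ref/alt supported by more
#'    than `max_third_allele_reads` reads across both pileups (a paralog
#'    collapse signature);
#' 4. `cluster` -- another candidate within `cluster_window` bp on the
#'    same contig (both candidates fail; computed over the full candidate
#'    list, so relaxing another threshold can never flip a pass to fail);
#' 5. `unique_reads` -- fewer than `min_unique_reads` uniquely aligned
#'    reads at the site (pooled across varieties by default);
#' 6. `contingency` -- two-sided test on the 2x2 variety-by-allele count
#'    table not below `max_p`.
#'
#' `pileup_other` is the cross-variety pileup the candidates were called
#' from (reads of the other variety on these contigs); `pileup_self` the
#' same-variety pileup used for the contingency contrast.
#'
#' @param candidates a `variant_calls` table from [call_candidates()].
#' @param pileup_other,pileup_self `pileup` objects.
#' @param thresholds a [variant_thresholds()].
#' @param test `"fisher"` (exact, default) or `"chisq"`.
#' @return the candidates with added columns `ref_self`, `alt_self`,
#'   `ref_other`, `alt_other`, `unique_reads`, `p_value` and `status`.
#' @export
filter_cascade <- function(candidates, pileup_other, pileup_self,
                           thresholds = variant_thresholds(),
                           test = c("fisher", "chisq")) {
  test <- match.arg(test)
  th <- thresholds
  n <- nrow(candidates)
  out <- candidates
  out$ref_self <- out$alt_self <- out$ref_other <- out$alt_other <-
    out$unique_reads <- NA_integer_
  out$p_value <- NA_real_
  out$status <- NA_character_
  if (n == 0) return(out)

  # stage 4 precomputed over the full candidate list
  clustered <- rep(FALSE, n)
  if (isTRUE(th$cluster_filter) && !is.na(th$cluster_window)) {
    for (i in seq_len(n)) {
      same <- which(out$contig == out$contig[i])
      near <- abs(out$pos[same] - out$pos[i]) < th$cluster_window
      clustered[i] <- sum(near) > 1
    }
  }

  for (i in seq_len(n)) {
    ct <- out$contig[i]; p <- out$pos[i]
    s_other <- site_slice(pileup_other, ct, p)
    if (nrow(s_other) == 0)
      stop_("candidate at ", ct, ":", p, " has no matching pileup")
    s_self <- site_slice(pileup_self, ct, p)
    base_other <- s_other[s_other$allele != "-" &
                          !startsWith(s_other$allele, "+"), ]
    coverage <- nrow(base_other) + sum(s_other$allele == "-")
    mean_q <- mean(base_other$qual)

    counts_all <- table(c(s_other$allele, s_self$allele))
    third <- counts_all[!names(counts_all) %in% c(out$ref[i], out$alt[i])]
    uniq <- c(other = sum(s_other$unique), self = sum(s_self$unique))

    ro <- sum(s_other$allele == out$ref[i]); ao <- sum(s_other$allele == out$alt[i])
    rs <- sum(s_self$allele == out$ref[i]); as_ <- sum(s_self$allele == out$alt[i])
    out$ref_other[i] <- ro; out$alt_other[i] <- ao
    out$ref_self[i] <- rs; out$alt_self[i] <- as_
    out$unique_reads[i] <- sum(uniq)
    tab <- matrix(c(rs, ro, as_, ao), 2, 2)   # rows: self/other; cols: ref/alt
    pv <- if (test == "fisher") fisher_exact_2x2(tab) else chisq_2x2(tab)
    out$p_value[i] <- as.numeric(pv)

    status <- "pass"
    if (coverage < th$min_coverage) status <- "fail:coverage"
    else if (is.nan(mean_q) || mean_q < th$min_mean_quality)
      status <- "fail:quality"
    else if (isTRUE(th$third_allele_filter) && length(third) > 0 &&
             max(third) > th$max_third_allele_reads)
      status <- "fail:third_allele"
    else if (clustered[i]) status <- "fail:cluster"
    else if ((th$unique_scope == "pooled" && sum(uniq) < th$min_unique_reads) ||
             (th$unique_scope == "per_variety" &&
              any(uniq < th$min_unique_reads)))
      status <- "fail:unique_reads"
    else if (!(out$p_value[i] < th$max_p)) status <- "fail:contingency"
    out$status[i] <- status
  }
  out
}

#' Reciprocal confirmation of calls between variety contig sets
#'
#' A cross-variety variant called on an A contig (from B reads) is
#' confirmed when the homologous position of the partner B contig --
#' under the coordinate map of a global alignment of the contig pair --
#' carries the mirror-image call (ref and alt exchanged, since each
#' contig presents its own variety's allele as reference). Calls on
#' contigs without a best-hit partner are flagged `unmapped`, as are
#' calls whose position falls in an alignment gap.
#'
#' @param calls_on_A calls made on A contigs from B reads
#'   (`variant_calls`, typically after [filter_cascade()]).
#' @param calls_on_B calls made on B contigs from A reads.
#' @param contig_pairs data.frame with columns `id_A`, `id_B`: best-hit
#'   contig partners.
#' @param contigs_A,contigs_B named nucleotide contig sequences.
#' @param scheme nucleotide scoring scheme for the coordinate-mapping
#'   alignment.
#' @return `calls_on_A` with added columns `partner_contig`,
#'   `partner_pos` and `confirmation`
#'   (`confirmed` / `unconfirmed` / `unmapped`).
#' @export
reciprocal_confirm <- function(calls_on_A, calls_on_B, contig_pairs,
                               contigs_A, contigs_B,
                               scheme = simple_scheme(match = 2,
                                                      mismatch = -3,
                                                      gap_open = -5,
                                                      gap_extend = -2,
                                                      calibrate = FALSE)) {
  out <- calls_on_A
  out$partner_contig <- NA_character_
  out$partner_pos <- NA_integer_
  out$confirmation <- "unmapped"
  if (nrow(out) == 0) return(out)
  partner <- setNames(contig_pairs$id_B, contig_pairs$id_A)
  maps <- list()
  for (i in seq_len(nrow(out))) {
    ca <- out$contig[i]
    if (!ca %in% names(partner)) next
    cb <- partner[[ca]]
    if (is.null(maps[[ca]])) {
      h <- needleman_wunsch(contigs_A[[ca]], contigs_B[[cb]], scheme)
      maps[[ca]] <- coord_map(h)
    }
    pb <- maps[[ca]][out$pos[i]]
    out$partner_contig[i] <- cb
    if (is.na(pb)) next          # deleted in partner: stays unmapped
    out$partner_pos[i] <- pb
    hit <- calls_on_B$contig == cb & calls_on_B$pos == pb
    mirrored <- any(hit & calls_on_B$ref == out$alt[i] &
                    calls_on_B$alt == out$ref[i])
    out$confirmation[i] <- if (mirrored) "confirmed" else "unconfirmed"
  }
  out
}

# position map a -> b from a global alignment hit (NA where b is gapped)
coord_map <- function(hit) {
  av <- chars(hit$aligned[1]); bv <- chars(hit$aligned[2])
  ai <- cumsum(av != "-"); bi <- cumsum(bv != "-")
  keep <- av != "-"
  map <- ifelse(bv[keep] == "-", NA_integer_, bi[keep])
  map
}

#' Write variant calls as a VCF-like TSV
#'
#' Columns: CHROM, POS, REF, ALT, counts per variety, mean quality,
#' p-value, status (1-based positions).
#'
#' @param calls a filtered `variant_calls` table.
#' @param path output path.
#' @export
write_variants <- function(calls, path) {
  d <- data.frame(CHROM = calls$contig, POS = calls$pos, REF = calls$ref,
                  ALT = calls$alt, TYPE = calls$type,
                  REF_SELF = calls$ref_self, ALT_SELF = calls$alt_self,
                  REF_OTHER = calls$ref_other, ALT_OTHER = calls$alt_other,
                  MEAN_QUAL = round(calls$mean_qual, 2),
                  P = signif(calls$p_value, 4), STATUS = calls$status)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
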