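STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Specification of a two-variety gene-family panel
#'
#' Describes the simulated superfamily: one row of `subgroup_layout` per
#' subgroup with the copy number in each variety and, optionally, the
#' number of cross-variety ortholog pairs to plant (`pairs`; defaults to
#' `min(copies_A, copies_B)`). Sequences are simulated as coding DNA and
#' translated, so nucleotide and protein fixtures stay consistent.
#'
#' The divergence hierarchy is: a single family root CDS; each cluster
#' ancestor diverges from it by `cluster_divergence_pct`; each subgroup
#' founder diverges from its cluster ancestor by
#' `subgroup_divergence_pct`; each copy lineage diverges from its subgroup
#' founder by `duplication_divergence_pct`; and for planted ortholog pairs
#' the two variety alleles each diverge from their shared lineage by
#' `divergence_pct / 2`, giving the nominal cross-variety divergence
#' between orthologs. Copies without a partner ("redundant" copies, the
#' signature of variety-specific duplication) are recent within-variety
#' duplicates: each diverges from one of the subgroup's paired copies
#' (round robin) by `duplication_divergence_pct`, so it is never the
#' reciprocal best hit of anything in the other variety; in a subgroup
#' with no pairs at all they are free-standing lineages of the founder.
#'
#' @param subgroup_layout data.frame with columns `cluster`, `subgroup`,
#'   `copies_A`, `copies_B`, optionally `pairs` and `family_label`.
#' @param base_length gene length in codons (residues).
#' @param divergence_pct percent nucleotide divergence between planted
#'   ortholog alleles (0 <= x < 50).
#' @param duplication_divergence_pct percent divergence between copy
#'   lineages within a subgroup; must exceed `divergence_pct` for
#'   reciprocal-best-hit recovery of the planted pairs to be well posed.
#' @param subgroup_divergence_pct percent divergence of subgroup founders
#'   from their cluster ancestor.
#' @param cluster_divergence_pct percent divergence of cluster ancestors
#'   from the single family root (all clusters are homologous, as in a
#'   real superfamily).
#' @param seed integer master seed; output is byte-identical per seed.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(subgroup_layout, base_length = 500,
                        divergence_pct = 2, duplication_divergence_pct = 10,
                        subgroup_divergence_pct = 20,
                        cluster_divergence_pct = 40, seed = 1) {
  need <- c("cluster", "subgroup", "copies_A", "copies_B")
  if (!all(need %in% names(subgroup_layout)))
    stop_("subgroup_layout needs columns: ", paste(need, collapse = ", "))
  lay <- as.data.frame(subgroup_layout)
  if (is.null(lay$pairs)) lay$pairs <- NA_integer_
  if (is.null(lay$family_label)) lay$family_label <- NA_character_
  if (any(lay$copies_A < 0) || any(lay$copies_B < 0))
    stop_("copy counts must be non-negative")
  if (any(lay$copies_A != round(lay$copies_A)) ||
      any(lay$copies_B != round(lay$copies_B)))
    stop_("copy counts must be integers")
  lay$pairs <- ifelse(is.na(lay$pairs), pmin(lay$copies_A, lay$copies_B),
                      lay$pairs)
  if (any(lay$pairs > pmin(lay$copies_A, lay$copies_B)))
    stop_("pairs cannot exceed min(copies_A, copies_B)")
  for (pct in c(divergence_pct, duplication_divergence_pct,
                subgroup_divergence_pct, cluster_divergence_pct))
    if (pct < 0 || pct >= 50) stop_("divergence percentages must be in [0, 50)")
  structure(list(subgroup_layout = lay, base_length = base_length,
                 divergence_pct = divergence_pct,
                 duplication_divergence_pct = duplication_divergence_pct,
                 subgroup_divergence_pct = subgroup_divergence_pct,
                 cluster_divergence_pct = cluster_divergence_pct,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# random CDS of n_codons codons drawn uniformly from the 61 sense codons
random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, STOP_CODONS)
  collapse(sample(codons, n_codons, replace = TRUE))
}

# substitute round(pct/100 * L) nucleotide positions, uniform positions,
# all three alternative bases equiprobable, never creating an in-frame stop
mutate_cds <- function(cds, pct) {
  L <- nchar(cds)
  n_sub <- round(pct / 100 * L)
  if (n_sub == 0) return(cds)
  v <- chars(cds)
  pos <- sample.int(L, n_sub)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alts <- sample(setdiff(bases, v[p]))
    ci <- (p - 1) %/% 3          # codon index, 0-based
    cpos <- ci * 3 + 1
    for (alt in alts) {
      codon <- v[cpos:(cpos + 2)]
      codon[p - cpos + 1] <- alt
      if (!collapse(codon) %in% STOP_CODONS) { v[p] <- alt; break }
    }
  }
  collapse(v)
}

#' Generate a two-variety gene-family panel with known orthology
#'
#' Simulates coding sequences for the two varieties according to a
#' [family_spec()], translates them, and records the planted orthology as
#' ground truth. Deterministic for a fixed spec (including its seed).
#'
#' @param spec a [family_spec()].
#' @param prefix_A,prefix_B id prefixes for the domesticated (A) and wild
#'   (B) variety.
#' @return an object of class `family_panel`: list with `cds_A`, `cds_B`,
#'   `protein_A`, `protein_B` (named character vectors), `meta`
#'   (data.frame: id, variety, cluster, subgroup, family_label, role), and
#'   `orthology` (data.frame: id_A, id_B, subgroup).
#' @export
generate_panel <- function(spec, prefix_A = "FLJ", prefix_B = "rFLJ") {
  stopifnot(inherits(spec, "family_spec"))
  lay <- spec$subgroup_layout
  with_seed(spec$seed, {
    cds_A <- character(); cds_B <- character()
    meta <- list(); ortho <- list()
    root <- random_cds(spec$base_length)
    for (cl in unique(lay$cluster)) {
      ancestor <- mutate_cds(root, spec$cluster_divergence_pct)
      rows <- which(lay$cluster == cl)
      for (r in rows) {
        sg <- lay$subgroup[r]
        sg_full <- paste0(cl, "-", sg)
        founder <- mutate_cds(ancestor, spec$subgroup_divergence_pct)
        nA <- lay$copies_A[r]; nB <- lay$copies_B[r]; np <- lay$pairs[r]
        add <- function(id, variety, role)
          meta[[length(meta) + 1L]] <<- data.frame(
            id = id, variety = variety, cluster = cl, subgroup = sg_full,
            family_label = lay$family_label[r], role = role)

        # paired lineages: one ancestral copy per ortholog pair, each
        # variety allele diverging by half the nominal ortholog divergence
        paired_A <- character(np); paired_B <- character(np)
        for (l in seq_len(np)) {
          lineage <- mutate_cds(founder, spec$duplication_divergence_pct)
          id_a <- sprintf("%s_%s_g%02d", prefix_A, sg_full, l)
          id_b <- sprintf("%s_%s_g%02d", prefix_B, sg_full, l)
          paired_A[l] <- id_a; paired_B[l] <- id_b
          cds_A[[id_a]] <- mutate_cds(lineage, spec$divergence_pct / 2)
          cds_B[[id_b]] <- mutate_cds(lineage, spec$divergence_pct / 2)
          add(id_a, "A", "ortholog"); add(id_b, "B", "ortholog")
          ortho[[length(ortho) + 1L]] <- data.frame(
            id_A = id_a, id_B = id_b, subgroup = sg_full)
        }
        # surplus copies: recent within-variety duplicates of a paired
        # copy (round robin), or free-standing lineages when the subgroup
        # has no pairs at all
        surplus <- function(n_extra, paired_ids, pool, prefix) {
          for (k in seq_len(n_extra)) {
            id <- sprintf("%s_%s_g%02d", prefix, sg_full, np + k)
            parent <- if (np > 0) pool[[paired_ids[(k - 1L) %% np + 1L]]]
                      else mutate_cds(founder, spec$duplication_divergence_pct)
            pool[[id]] <- mutate_cds(parent, spec$duplication_divergence_pct)
            add(id, if (prefix == prefix_A) "A" else "B", "redundant")
          }
          pool
        }
        cds_A <- surplus(nA - np, paired_A, cds_A, prefix_A)
        cds_B <- surplus(nB - np, paired_B, cds_B, prefix_B)
      }
    }
    meta <- if (length(meta)) do.call(rbind, meta) else
      data.frame(id = character(), variety = character(),
                 cluster = character(), subgroup = character(),
                 family_label = character(), role = character())
    ortho <- if (length(ortho)) do.call(rbind, ortho) else
      data.frame(id_A = character(), id_B = character(),
                 subgroup = character())
    structure(list(
      cds_A = cds_A, cds_B = cds_B,
      protein_A = vapply(cds_A, translate_cds, character(1)),
      protein_B = vapply(cds_B, translate_cds, character(1)),
      meta = meta, orthology = ortho, spec = spec),
      class = "family_panel")
  })
}

#' @export
print.family_panel <- function(x, ...) {
  cat(sprintf("<family_panel> %d A + %d B sequences, %d subgroups, %d planted ortholog pairs\n",
              length(x$cds_A), length(x$cds_B),
              length(unique(x$meta$subgroup)), nrow(x$orthology)))
  invisible(x)
}

#' Simulate reads from transcripts, with planted variants
#'
#' Draws `expression[gene]` reads per transcript, start positions uniform
#' along the transcript, and plants each variant of `variant_spec` into
#' exactly `alt_count` of the reads covering its site. Reads are clean
#' (no sequencing error) unless `error_rate > 0`, and carry constant
#' Phred quality `quality` unless a `quality_model` function is given.
#'
#' @param transcripts named character vector of transcript (contig)
#'   sequences the reads are drawn from.
#' @param expression named integer vector: reads requested per gene (genes
#'   absent or 0 produce no reads).
#' @param variant_spec optional data.frame with columns `contig`, `pos`
#'   (1-based), `ref`, `alt`, `alt_count`; `ref` must match the transcript
#'   base and the position must fall inside the transcript.
#' @param read_length read length in bp; transcripts shorter than this are
#'   rejected.
#' @param quality constant per-base Phred quality.
#' @param quality_model optional `function(n)` returning `n` integer
#'   qualities, overriding `quality`.
#' @param error_rate per-base substitution error rate (default 0: clean
#'   reads, so planted allele counts are exact).
#' @param seed integer seed.
#' @return an object of class `read_set`: data.frame with `read_id`,
#'   `gene`, `start` (1-based on the transcript), `seq`, `qual`
#'   (Phred+33), plus the realised truth tables as attributes
#'   `"truth_expression"` and `"truth_variants"`.
#' @export
generate_reads <- function(transcripts, expression, variant_spec = NULL,
                           read_length = 75, quality = 30,
                           quality_model = NULL, error_rate = 0, seed = 1) {
  if (any(expression < 0)) stop_("expression counts must be non-negative")
  genes <- names(expression)[expression > 0]
  if (!all(genes %in% names(transcripts)))
    stop_("expression names missing from transcripts: ",
          paste(setdiff(genes, names(transcripts)), collapse = ", "))
  if (!is.null(variant_spec) && nrow(variant_spec) > 0) {
    for (i in seq_len(nrow(variant_spec))) {
      vs <- variant_spec[i, ]
      if (!vs$contig %in% names(transcripts))
        stop_("variant contig not in transcripts: ", vs$contig)
      L <- nchar(transcripts[[vs$contig]])
      if (vs$pos < 1 || vs$pos > L)
        stop_("variant position outside transcript: ", vs$contig, ":", vs$pos)
      if (substr(transcripts[[vs$contig]], vs$pos, vs$pos) != vs$ref)
        stop_("variant ref base does not match transcript at ",
              vs$contig, ":", vs$pos)
    }
  }
  with_seed(seed, {
    rows <- list()
    for (g in genes) {
      tx <- transcripts[[g]]
      L <- nchar(tx)
      if (L < read_length)
        stop_("transcript ", g, " shorter than read length")
      n <- expression[[g]]
      starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
      seqs <- substring(tx, starts, starts + read_length - 1L)
      if (error_rate > 0) {
        for (j in seq_along(seqs)) {
          err <- which(runif(read_length) < error_rate)
          if (length(err)) {
            v <- chars(seqs[j])
            for (p in err) v[p] <- sample(setdiff(c("A","C","G","T"), v[p]), 1)
            seqs[j] <- collapse(v)
          }
        }
      }
      rows[[g]] <- data.frame(
        read_id = sprintf("%s_r%04d", g, seq_len(n)),
        gene = g, start = starts, seq = seqs, stringsAsFactors = FALSE)
    }
    reads <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read_id = character(), gene = character(),
                 start = integer(), seq = character())
    rownames(reads) <- NULL
    if (!is.null(variant_spec) && nrow(variant_spec) > 0) {
      for (i in seq_len(nrow(variant_spec))) {
        vs <- variant_spec[i, ]
        covering <- which(reads$gene == vs$contig &
                          reads$start <= vs$pos &
                          reads$start + read_length - 1L >= vs$pos)
        if (length(covering) < vs$alt_count)
          stop_("planted variant at ", vs$contig, ":", vs$pos,
                " requires alt_count ", vs$alt_count,
                " but only ", length(covering), " reads cover the site")
        pick <- sample(covering, vs$alt_count)
        off <- vs$pos - reads$start[pick] + 1L
        substr(reads$seq[pick], off, off) <- vs$alt
      }
    }
    quals <- if (is.null(quality_model)) {
      function(n) rep.int(as.integer(quality), n)
    } else quality_model
    reads$qual <- vapply(seq_len(nrow(reads)), function(i)
      collapse(intToUtf8(quals(read_length) + 33L, multiple = TRUE)),
      character(1))
    attr(reads, "truth_expression") <- expression[genes]
    attr(reads, "truth_variants") <- variant_spec
    class(reads) <- c("read_set", "data.frame")
    reads
  })
}

#' Apply a variant table to contig sequences
#'
#' Produces the partner variety's contigs by substituting each variant's
#' `alt` base at its position -- the generator of fixed cross-variety
#' differences used by the variant-calling fixtures.
#'
#' @param contigs named character vector.
#' @param variant_spec data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param rename optional function mapping old contig names to new ones.
#' @return named character vector with variants applied.
#' @export
apply_variants <- function(contigs, variant_spec, rename = identity) {
  out <- contigs
  for (i in seq_len(nrow(variant_spec))) {
    vs <- variant_spec[i, ]
    if (!vs$contig %in% names(out))
      stop_("variant contig not in contigs: ", vs$contig)
    if (substr(out[[vs$contig]], vs$pos, vs$pos) != vs$ref)
      stop_("ref mismatch at ", vs$contig, ":", vs$pos)
    substr(out[[vs$contig]], vs$pos, vs$pos) <- vs$alt
  }
  names(out) <- rename(names(out))
  out
}
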