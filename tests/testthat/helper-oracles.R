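# Independent oracles and small fixture builders used across the suite.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")
random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

# Brute-force local alignment score: for every anchored start pair
# (i0, j0) run an unclamped affine DP over the suffix block and take the
# maximum over all end cells (i.e. enumerate all local start/end pairs).
# Plain iterative R; gap of length L costs gap_open + L * gap_extend.
oracle_local_score <- function(a, b, sub, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  go <- gap_open + gap_extend; ge <- gap_extend
  best <- 0
  for (i0 in seq_len(n)) for (j0 in seq_len(m)) {
    M <- matrix(-Inf, n - i0 + 2, m - j0 + 2)
    E <- F_ <- matrix(-Inf, n - i0 + 2, m - j0 + 2)
    M[1, 1] <- 0
    for (i in seq_len(n - i0 + 1) + 1) for (j in seq_len(m - j0 + 1) + 1) {
      s <- sub[av[i0 + i - 2], bv[j0 + j - 2]]
      M[i, j] <- max(M[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1]) + s
      E[i, j] <- max(M[i, j - 1] + go, F_[i, j - 1] + go, E[i, j - 1] + ge)
      F_[i, j] <- max(M[i - 1, j] + go, E[i - 1, j] + go, F_[i - 1, j] + ge)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Exhaustive two-sided Fisher p by direct enumeration of all tables with
# the observed margins, probabilities from choose() ratios in log space.
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; N <- a + b + c_ + d
  xs <- max(0, r1 - (N - c1)):min(r1, c1)
  logp <- lchoose(c1, xs) + lchoose(N - c1, r1 - xs) - lchoose(N, r1)
  p <- exp(logp)
  p_obs <- p[xs == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# layout of the two focal varieties taken from the published 19-species
# copy-number table, restricted to the five copy-expanded subgroups, with
# the published ortholog-pair structure
expanded_subgroup_layout <- function() {
  data.frame(
    cluster  = c("I", "I", "II", "II", "II"),
    subgroup = c("1", "12", "2", "8", "11"),
    copies_A = c(30L, 5L, 4L, 7L, 20L),
    copies_B = c(27L, 3L, 3L, 5L, 17L),
    pairs    = c(27L, 3L, 3L, 4L, 17L))
}

# small clean variant-calling scenario: equal-copy panel, fixed
# cross-variety differences applied to the B contigs, clean reads both
# ways; returns everything the cascade needs
variant_scenario <- function(n_genes = 3, base_length = 100,
                             reads_per_gene = 100, read_length = 50,
                             positions = c(80, 200, 150),
                             seed = 11) {
  lay <- data.frame(cluster = "I", subgroup = "1",
                    copies_A = n_genes, copies_B = n_genes)
  panel <- generate_panel(family_spec(lay, base_length = base_length,
                                      divergence_pct = 0,
                                      duplication_divergence_pct = 10,
                                      seed = seed))
  contigs_A <- panel$cds_A
  genes <- names(contigs_A)[c(1, 1, 2)][seq_along(positions)]
  vs <- data.frame(contig = genes, pos = positions,
                   ref = NA_character_, alt = NA_character_)
  for (i in seq_len(nrow(vs))) {
    r <- substr(contigs_A[[vs$contig[i]]], vs$pos[i], vs$pos[i])
    vs$ref[i] <- r
    vs$alt[i] <- setdiff(c("A", "C", "G", "T"), r)[1]
  }
  contigs_B <- apply_variants(contigs_A, vs,
                              rename = function(n) sub("FLJ", "rFLJ", n))
  expr <- setNames(rep(reads_per_gene, length(contigs_A)), names(contigs_A))
  reads_A <- generate_reads(contigs_A, expr, read_length = read_length,
                            seed = seed + 1)
  reads_B <- generate_reads(contigs_B,
                            setNames(expr, names(contigs_B)),
                            read_length = read_length, seed = seed + 2)
  list(panel = panel, contigs_A = contigs_A, contigs_B = contigs_B,
       variants = vs, reads_A = reads_A, reads_B = reads_B)
}

# hand-built pileup rows (one row per read base) for cascade label tests
make_site <- function(contig, pos, alleles, quals = 30, unique = TRUE) {
  data.frame(contig = contig, pos = pos, allele = alleles,
             qual = rep_len(quals, length(alleles)),
             unique = rep_len(unique, length(alleles)),
             stringsAsFactors = FALSE)
}
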