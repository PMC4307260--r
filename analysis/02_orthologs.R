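#!/usr/bin/env Rscript
# Reciprocal-best-hit orthology in the five copy-expanded subgroups.
#
# Simulates each subgroup with the two varieties' published copy numbers
# and pairing structure (2% ortholog divergence), mines ortholog pairs by
# RBH under the pipeline thresholds (E < 1e-20, coverage-of-longer > 80%)
# and tabulates pairs and redundant copies per subgroup.
#
# Finds: 27 / 3 / 3 / 4 / 17 pairs in I-1, I-12, II-2, II-8, II-11, with
# 3 / 2 / 1 / 3+1 / 3 redundant copies, matching the planted truth
# exactly in every subgroup.

library(samefam)
dir.create("results", showWarnings = FALSE)

layout <- data.frame(
  cluster  = c("I", "I", "II", "II", "II"),
  subgroup = c("1", "12", "2", "8", "11"),
  copies_A = c(30L, 5L, 4L, 7L, 20L),
  copies_B = c(27L, 3L, 3L, 5L, 17L),
  pairs    = c(27L, 3L, 3L, 4L, 17L))

all_pairs <- list(); summary <- list()
for (r in seq_len(nrow(layout))) {
  spec <- family_spec(layout[r, ], base_length = 500, divergence_pct = 2,
                      seed = 42 + r - 1)
  panel <- generate_panel(spec)
  pairs <- reciprocal_best_hits(panel$protein_A, panel$protein_B,
                                evalue_max = 1e-20, min_coverage = 0.80)
  red <- classify_redundant(pairs, panel$protein_A, panel$protein_B)
  sg <- paste0(layout$cluster[r], "-", layout$subgroup[r])
  exact <- setequal(paste(pairs$id_A, pairs$id_B),
                    paste(panel$orthology$id_A, panel$orthology$id_B))
  summary[[r]] <- data.frame(
    subgroup = sg, copies_A = layout$copies_A[r],
    copies_B = layout$copies_B[r], pairs = nrow(pairs),
    redundant_A = length(red$redundant_A),
    redundant_B = length(red$redundant_B),
    truth_recovered = exact)
  all_pairs[[r]] <- cbind(subgroup = sg,
                          pairs[, c("id_A", "id_B", "pident",
                                    "coverage_longer")])
  cat(sprintf("%-6s %2d pairs, %d + %d redundant, truth recovered: %s\n",
              sg, nrow(pairs), length(red$redundant_A),
              length(red$redundant_B), exact))
}
write.table(do.call(rbind, summary), "results/ortholog_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, all_pairs), "results/ortholog_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
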