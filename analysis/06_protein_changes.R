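#!/usr/bin/env Rscript
# Amino-acid variation between ortholog pairs, in position/residue
# notation (e.g. 365A/E, positions indexed on the domesticated protein).
#
# Simulates a subgroup at 2% nucleotide divergence, pairs orthologs by
# RBH, translates both members of each pair and annotates every aligned
# residue difference; gaps would be reported on a separate indel channel.
#
# Finds: each ortholog pair differs at a handful of residues (2%
# nucleotide divergence -> mostly silent or single-residue changes), and
# the zero-divergence control annotates every pair as "none".

library(samefam)
dir.create("results", showWarnings = FALSE)

lay <- data.frame(cluster = "II", subgroup = "8", copies_A = 7,
                  copies_B = 5, pairs = 4)
panel <- generate_panel(family_spec(lay, base_length = 500,
                                    divergence_pct = 2, seed = 42))
pairs <- reciprocal_best_hits(panel$protein_A, panel$protein_B)
sch <- blosum62_scheme()
rows <- lapply(seq_len(nrow(pairs)), function(k) {
  ch <- aa_changes(panel$protein_A[[pairs$id_A[k]]],
                   panel$protein_B[[pairs$id_B[k]]], sch)
  data.frame(id_A = pairs$id_A[k], id_B = pairs$id_B[k],
             n_changes = nrow(ch),
             changes = format_aa_changes(ch))
})
out <- do.call(rbind, rows)
write.table(out, "results/aa_changes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(out)
cat(sprintf("\ntotal residue changes across %d pairs: %d\n",
            nrow(out), sum(out$n_changes)))

# zero-divergence control
lay0 <- data.frame(cluster = "I", subgroup = "1", copies_A = 2, copies_B = 2)
p0 <- generate_panel(family_spec(lay0, base_length = 200,
                                 divergence_pct = 0, seed = 7))
ch0 <- vapply(seq_len(nrow(p0$orthology)), function(k)
  format_aa_changes(aa_changes(p0$protein_A[[p0$orthology$id_A[k]]],
                               p0$protein_B[[p0$orthology$id_B[k]]], sch)),
  character(1))
cat("zero-divergence control annotations:", paste(unique(ch0)), "\n")
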