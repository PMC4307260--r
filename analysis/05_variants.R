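#!/usr/bin/env Rscript
# Cross-variety SNP detection with the filter cascade and reciprocal
# confirmation.
#
# Simulates a clean two-variety panel with fixed nucleotide differences
# planted between the variety contigs, maps each variety's reads onto
# the other variety's contigs, calls candidates from the pileups, runs
# the ordered filter cascade (coverage >= 8, mean quality >= 20, third
# allele <= 2 reads, 60 bp cluster window, > 20 unique reads pooled,
# Fisher p < 0.01) and confirms calls at the homologous position of the
# partner contig.
#
# Finds: every planted difference is called, passes the cascade and is
# reciprocally confirmed; no false positives appear anywhere else.

library(samefam)
dir.create("results", showWarnings = FALSE)

lay <- data.frame(cluster = "I", subgroup = "1", copies_A = 4, copies_B = 4)
panel <- generate_panel(family_spec(lay, base_length = 150,
                                    divergence_pct = 0,
                                    duplication_divergence_pct = 10,
                                    seed = 42))
contigs_A <- panel$cds_A

# plant 6 fixed differences, well separated and away from contig ends
plant <- data.frame(
  contig = names(contigs_A)[c(1, 1, 2, 3, 3, 4)],
  pos = c(90, 260, 150, 120, 300, 222))
plant$ref <- substring(contigs_A[plant$contig], plant$pos, plant$pos)
plant$alt <- vapply(plant$ref,
                    function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
contigs_B <- apply_variants(contigs_A, plant,
                            rename = function(n) sub("FLJ", "rFLJ", n))

expr <- setNames(rep(150L, 4), names(contigs_A))
reads_A <- generate_reads(contigs_A, expr, read_length = 60, seed = 43)
reads_B <- generate_reads(contigs_B, setNames(expr, names(contigs_B)),
                          read_length = 60, seed = 44)

p_BA <- pileup(map_reads(reads_B, contigs_A), contigs_A)
p_AA <- pileup(map_reads(reads_A, contigs_A), contigs_A)
calls <- filter_cascade(call_candidates(p_BA, contigs_A), p_BA, p_AA)

p_AB <- pileup(map_reads(reads_A, contigs_B), contigs_B)
cand_B <- call_candidates(p_AB, contigs_B)
pairs <- data.frame(id_A = names(contigs_A), id_B = names(contigs_B))
conf <- reciprocal_confirm(calls, cand_B, pairs, contigs_A, contigs_B)

write_variants(conf, "results/variant_calls.tsv")
print(conf[, c("contig", "pos", "ref", "alt", "p_value", "status",
               "confirmation")])
called <- paste(conf$contig[conf$status == "pass"],
                conf$pos[conf$status == "pass"])
truth <- paste(plant$contig, plant$pos)
cat(sprintf("\nplanted %d, called %d, pass %d, confirmed %d; exact truth recovery: %s\n",
            nrow(plant), nrow(conf), sum(conf$status == "pass"),
            sum(conf$confirmation == "confirmed"),
            setequal(called, truth)))
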