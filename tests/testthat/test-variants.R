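test_that("the mapper places exact substrings and flags ties", {
  set.seed(19)
  ctg <- c(c1 = random_dna(200), c2 = random_dna(200))
  reads <- data.frame(read_id = "r1", seq = substr(ctg[["c1"]], 41, 90))
  aln <- map_reads(reads, ctg, seed_k = 20)
  expect_equal(aln$contig, "c1")
  expect_equal(aln$start, 41L)
  expect_equal(aln$mismatches, 0L)
  expect_true(aln$unique)

  # identical region in two contigs: tie -> non-unique
  ctg2 <- ctg
  substr(ctg2[["c2"]], 41, 90) <- substr(ctg2[["c1"]], 41, 90)
  aln2 <- map_reads(reads, ctg2, seed_k = 20)
  expect_false(aln2$unique)
  expect_equal(aln2$mapq, 0L)

  # too many mismatches: dropped
  r <- reads
  v <- strsplit(r$seq, "")[[1]]
  at <- c(5, 15, 25, 35)
  v[at] <- vapply(v[at], function(x) setdiff(c("A","C","G","T"), x)[1], "")
  r$seq <- paste(v, collapse = "")
  expect_equal(nrow(map_reads(r, ctg, seed_k = 10, max_mismatches = 3)), 0L)
  expect_error(map_reads(reads, character(0)), "empty")
})

test_that("reverse-strand reads are mapped in reference orientation", {
  set.seed(29)
  ctg <- c(c1 = random_dna(150))
  fwd <- substr(ctg[["c1"]], 30, 79)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  aln <- map_reads(data.frame(read_id = "r", seq = rc), ctg, seed_k = 15)
  expect_equal(aln$strand, "-")
  expect_equal(aln$start, 30L)
  expect_equal(aln$seq, fwd)   # stored in reference orientation
})

test_that("SAM ingest skips unmapped, rejects malformed, round-trips", {
  set.seed(39)
  ctg <- c(c1 = random_dna(120))
  reads <- data.frame(read_id = c("r1", "r2"),
                      seq = c(substr(ctg[["c1"]], 1, 50),
                              substr(ctg[["c1"]], 51, 100)))
  aln <- map_reads(reads, ctg, seed_k = 20)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, ctg, sam)
  back <- read_sam(sam, ctg)
  expect_equal(back$read_id, aln$read_id)
  expect_equal(back$start, aln$start)
  expect_equal(back$seq, aln$seq)
  expect_equal(back$mismatches, c(0L, 0L))

  lines <- readLines(sam)
  writeLines(c(lines, "bad\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII"), sam)
  expect_equal(nrow(read_sam(sam)), 2L)   # 0x4 skipped
  writeLines(c(lines, "broken\trecord"), sam)
  expect_error(read_sam(sam), as.character(length(lines) + 1))
})

test_that("pileup stacks bases, honours unique_only, rejects overruns", {
  ctg <- c(c1 = strrep("ACGT", 25))
  aln <- data.frame(read_id = c("r1", "r2", "r3"), contig = "c1",
                    start = c(1L, 1L, 5L), strand = "+",
                    mismatches = 0L, unique = c(TRUE, FALSE, TRUE),
                    mapq = c(60L, 0L, 60L), cigar = "10M",
                    seq = substr(ctg[["c1"]], 1, 10),
                    qual = strrep("?", 10))   # Phred 30
  aln$seq[3] <- substr(ctg[["c1"]], 5, 14)
  p <- pileup(aln, ctg)
  expect_equal(sum(p$pos == 5), 3L)
  expect_equal(sum(p$pos == 1), 2L)
  pu <- pileup(aln, ctg, unique_only = TRUE)
  expect_equal(sum(pu$pos == 1), 1L)
  expect_equal(nrow(pileup(aln[0, ], ctg)), 0L)
  bad <- aln[3, ]; bad$start <- 95L
  expect_error(pileup(bad, ctg), "overruns")
})

test_that("candidates appear only at non-reference alleles", {
  ctg <- c(c1 = strrep("ACGT", 25))
  ref10 <- substr(ctg[["c1"]], 10, 10)
  ref50 <- substr(ctg[["c1"]], 50, 50)
  clean <- make_site("c1", 10, rep(ref10, 12))
  expect_equal(nrow(call_candidates(clean, ctg)), 0L)
  planted <- rbind(make_site("c1", 10, c(rep(ref10, 20), rep("G", 10))),
                   make_site("c1", 50, rep(ref50, 8)))
  cand <- call_candidates(planted, ctg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pos, 10L)
  expect_equal(cand$alt, "G")
  expect_equal(cand$alt_count, 10L)
  expect_equal(cand$coverage, 30L)
  expect_equal(cand$type, "SNP")
})

test_that("gapped SAM alignments yield indel candidates", {
  ctg <- c(c1 = strrep("ACGT", 10))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:c1\tLN:40",
    # 5M2D5M starting at 1: deletion of ref 6..7
    paste("rd", 0, "c1", 1, 60, "5M2D5M", "*", 0, 0,
          paste0(substr(ctg[["c1"]], 1, 5), substr(ctg[["c1"]], 8, 12)),
          strrep("I", 10), sep = "\t")), sam)
  aln <- read_sam(sam)
  p <- pileup(aln, ctg)
  cand <- call_candidates(p, ctg)
  expect_true(all(cand$type == "indel"))
  expect_setequal(cand$pos, c(6L, 7L))
  expect_true(all(cand$alt == "-"))
})

test_that("Fisher p equals the enumeration oracle on all small tables", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2)), 2 / 252,
               tolerance = 1e-12)
  # symmetry under row and column swaps
  tabs <- list(c(3, 1, 2, 7), c(8, 2, 1, 9), c(4, 4, 4, 4))
  for (v in tabs) {
    t0 <- matrix(v, 2, 2)
    expect_equal(fisher_exact_2x2(t0), fisher_exact_2x2(t0[2:1, ]))
    expect_equal(fisher_exact_2x2(t0), fisher_exact_2x2(t0[, 2:1]))
  }
  # exhaustive agreement for N <= 16 (the acceptance run extends to 30)
  for (N in 2:16) {
    for (a in 0:N) for (b in 0:(N - a)) for (c_ in 0:(N - a - b)) {
      d <- N - a - b - c_
      if ((a + b) * (c_ + d) * (a + c_) * (b + d) == 0) next
      expect_equal(fisher_exact_2x2(matrix(c(a, c_, b, d), 2, 2)),
                   oracle_fisher_p(a, b, c_, d), tolerance = 1e-12)
    }
  }
  # degenerate margin: p = 1, flagged
  pz <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2))
  expect_equal(as.numeric(pz), 1)
  expect_true(attr(pz, "degenerate"))
})

test_that("each cascade stage fails with its own label", {
  ctg <- c(c1 = strrep("ACGT", 100), c2 = strrep("ACGT", 100))
  th <- variant_thresholds()
  # helper: self pileup with ref allele, other pileup as given
  ref_at <- function(contig, pos, n = 30) {
    r <- substr(ctg[[contig]], pos, pos)
    make_site(contig, pos, rep(r, n))
  }
  alt_of <- function(contig, pos) setdiff(c("A", "C", "G", "T"),
                                          substr(ctg[[contig]], pos, pos))[1]

  site <- function(contig, pos, n_alt, n_ref = 0, qual = 30, unique = TRUE,
                   third = 0) {
    a <- alt_of(contig, pos)
    r <- substr(ctg[[contig]], pos, pos)
    third_allele <- setdiff(c("A", "C", "G", "T"), c(a, r))[1]
    make_site(contig, pos,
              c(rep(a, n_alt), rep(r, n_ref), rep(third_allele, third)),
              quals = qual, unique = unique)
  }

  run1 <- function(other, self) {
    cand <- call_candidates(other, ctg)
    filter_cascade(cand, other, self, th)
  }

  # coverage 7 < 8
  out <- run1(site("c1", 101, 7), ref_at("c1", 101))
  expect_equal(out$status, "fail:coverage")
  # mean quality 19.5 < 20
  out <- run1(site("c1", 101, 30, qual = c(19, 20)), ref_at("c1", 101))
  expect_equal(out$status, "fail:quality")
  # third allele on 3 reads > 2
  out <- run1(site("c1", 101, 27, third = 3), ref_at("c1", 101))
  expect_equal(out$status, "fail:third_allele")
  # two candidates 40 bp apart: both fail
  other <- rbind(site("c1", 101, 30), site("c1", 141, 30))
  self <- rbind(ref_at("c1", 101), ref_at("c1", 141))
  out <- filter_cascade(call_candidates(other, ctg), other, self, th)
  expect_equal(out$status, c("fail:cluster", "fail:cluster"))
  # 61 bp apart: both pass
  other <- rbind(site("c1", 101, 30), site("c1", 162, 30))
  self <- rbind(ref_at("c1", 101), ref_at("c1", 162))
  out <- filter_cascade(call_candidates(other, ctg), other, self, th)
  expect_equal(out$status, c("pass", "pass"))
  # pooled unique reads 20 (10 + 10), needs > 20
  out <- run1(site("c1", 101, 10), ref_at("c1", 101, 10))
  expect_equal(out$status, "fail:unique_reads")
  # balanced alleles in both varieties: contingency test not significant
  other <- site("c1", 101, 15, n_ref = 15)
  out <- run1(other, site("c1", 101, 15, n_ref = 15))
  expect_equal(out$status, "fail:contingency")
  expect_gte(out$p_value, 0.01)
  # a clean fixed difference passes
  out <- run1(site("c1", 101, 30), ref_at("c1", 101))
  expect_equal(out$status, "pass")
  expect_lt(out$p_value, 0.01)
})

test_that("relaxing any threshold never converts a pass into a fail", {
  sc <- variant_scenario(seed = 51)
  aln_BA <- map_reads(sc$reads_B, sc$contigs_A)
  aln_AA <- map_reads(sc$reads_A, sc$contigs_A)
  p_BA <- pileup(aln_BA, sc$contigs_A)
  p_AA <- pileup(aln_AA, sc$contigs_A)
  cand <- call_candidates(p_BA, sc$contigs_A)
  strict <- filter_cascade(cand, p_BA, p_AA, variant_thresholds())
  relaxed <- filter_cascade(cand, p_BA, p_AA, variant_thresholds(
    min_coverage = 2, min_mean_quality = 5, max_third_allele_reads = 10,
    cluster_window = 10, min_unique_reads = 5, max_p = 0.2))
  was_pass <- strict$status == "pass"
  expect_true(all(relaxed$status[was_pass] == "pass"))
})

test_that("the clean pipeline recovers exactly the planted variants", {
  sc <- variant_scenario(seed = 61)
  aln_BA <- map_reads(sc$reads_B, sc$contigs_A)
  p_BA <- pileup(aln_BA, sc$contigs_A)
  p_AA <- pileup(map_reads(sc$reads_A, sc$contigs_A), sc$contigs_A)
  cand <- call_candidates(p_BA, sc$contigs_A)
  expect_setequal(paste(cand$contig, cand$pos),
                  paste(sc$variants$contig, sc$variants$pos))
  calls <- filter_cascade(cand, p_BA, p_AA)
  expect_true(all(calls$status == "pass"))
  # zero-divergence panel: no candidates at all
  clean <- call_candidates(p_AA, sc$contigs_A)
  expect_equal(nrow(clean), 0L)
})

test_that("reciprocal confirmation mirrors calls and flags gaps", {
  sc <- variant_scenario(seed = 71)
  p_BA <- pileup(map_reads(sc$reads_B, sc$contigs_A), sc$contigs_A)
  p_AA <- pileup(map_reads(sc$reads_A, sc$contigs_A), sc$contigs_A)
  calls_A <- filter_cascade(call_candidates(p_BA, sc$contigs_A),
                            p_BA, p_AA)
  p_AB <- pileup(map_reads(sc$reads_A, sc$contigs_B), sc$contigs_B)
  cand_B <- call_candidates(p_AB, sc$contigs_B)
  pairs <- data.frame(id_A = names(sc$contigs_A), id_B = names(sc$contigs_B))
  conf <- reciprocal_confirm(calls_A, cand_B, pairs,
                             sc$contigs_A, sc$contigs_B)
  expect_true(all(conf$confirmation == "confirmed"))
  # a call on a contig with no partner is unmapped
  conf2 <- reciprocal_confirm(calls_A, cand_B, pairs[0, ],
                              sc$contigs_A, sc$contigs_B)
  expect_true(all(conf2$confirmation == "unmapped"))
  # a call at a position deleted in the partner is unmapped
  ctg_del <- sc$contigs_B
  v1 <- sc$variants[1, ]
  ctg_del[[paste0("r", v1$contig)]] <- paste0(
    substr(ctg_del[[paste0("r", v1$contig)]], 1, v1$pos - 3),
    substr(ctg_del[[paste0("r", v1$contig)]], v1$pos + 3, 1e6))
  conf3 <- reciprocal_confirm(calls_A, cand_B, pairs,
                              sc$contigs_A, ctg_del)
  hit <- conf3$contig == v1$contig & conf3$pos == v1$pos
  expect_true(all(conf3$confirmation[hit] == "unmapped"))
})
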