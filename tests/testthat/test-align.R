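dna_scheme <- simple_scheme(gap_open = 0, gap_extend = -1, calibrate = FALSE)

test_that("local alignment handles identity, near-identity and symmetry", {
  h <- smith_waterman("ACGT", "ACGT", dna_scheme)
  expect_equal(h$score, 4)
  expect_equal(h$identities, 4L)
  expect_equal(h$length, 4L)

  h2 <- smith_waterman("ACGT", "AGT", dna_scheme)
  expect_equal(h2$score, 2)

  # symmetric matrix: score invariant under operand swap
  set.seed(4)
  for (i in 1:5) {
    a <- random_dna(9); b <- random_dna(7)
    expect_equal(smith_waterman(a, b, dna_scheme)$score,
                 smith_waterman(b, a, dna_scheme)$score)
  }
})

test_that("symbols outside the alphabet are rejected by name", {
  expect_error(smith_waterman("ACGU", "ACGT", dna_scheme), "U")
  expect_error(needleman_wunsch("AC", "", dna_scheme), "non-empty")
})

test_that("local score equals the exhaustive start/end-pair oracle", {
  set.seed(11)
  schemes <- list(dna_scheme,
                  simple_scheme(match = 2, mismatch = -3,
                                gap_open = -4, gap_extend = -1,
                                calibrate = FALSE))
  for (sch in schemes) {
    for (i in 1:12) {
      a <- random_dna(sample(3:12, 1))
      b <- random_dna(sample(3:12, 1))
      expect_equal(smith_waterman(a, b, sch)$score,
                   oracle_local_score(a, b, sch$matrix, sch$gap_open,
                                      sch$gap_extend),
                   info = paste(a, b))
    }
  }
})

test_that("alignment scores agree with the reference implementation", {
  # independent cross-check against Biostrings::pairwiseAlignment with
  # the same BLOSUM62 matrix and 11/1 affine gaps
  sch <- blosum62_scheme()
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  set.seed(21)
  for (i in 1:6) {
    a <- random_protein(45); b <- random_protein(38)
    expect_equal(
      smith_waterman(a, b, sch)$score,
      Biostrings::score(Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = env$BLOSUM62,
        gapOpening = 11, gapExtension = 1, type = "local")))
    expect_equal(
      needleman_wunsch(a, b, sch)$score,
      Biostrings::score(Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = env$BLOSUM62,
        gapOpening = 11, gapExtension = 1, type = "global")))
  }
})

test_that("the batch score matrix agrees with single alignments", {
  sch <- blosum62_scheme()
  set.seed(31)
  A <- setNames(replicate(4, random_protein(30)), paste0("a", 1:4))
  B <- setNames(replicate(3, random_protein(25)), paste0("b", 1:3))
  tab <- alignment_table(A, B, sch)
  for (r in sample(nrow(tab), 6))
    expect_equal(tab$score[r],
                 smith_waterman(A[[tab$qid[r]]], B[[tab$sid[r]]], sch)$score)
})

test_that("family search accepts members and excludes decoys", {
  set.seed(41)
  fam_root <- random_protein(200)
  member <- fam_root
  substr(member, 5, 5) <- "W"
  decoy <- random_protein(30)
  res <- search_family(c(q_member = member, q_decoy = decoy),
                       c(ref1 = fam_root), threshold = 1e-15)
  expect_identical(res$qid, "q_member")
  expect_error(search_family(c(q = member), character(0)), "non-empty")
})

test_that("dedupe collapses exact duplicates, keeps first ids, idempotent", {
  s <- c(x = "MKT", y = "MKT", z = "MW")
  d <- dedupe(s)
  expect_identical(names(d), c("x", "z"))
  expect_identical(dedupe(d), d)
  # never removes the last copy of a distinct string
  set.seed(5)
  u <- setNames(replicate(20, random_protein(8)), paste0("s", 1:20))
  expect_equal(length(dedupe(u)), length(unique(unname(u))))
})
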