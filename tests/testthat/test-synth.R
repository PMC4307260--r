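test_that("panel copy counts follow the layout (two-variety published rows)", {
  # the two focal varieties' full rows: 133 and 122 sequences in total
  tab <- sames_copy_table()$counts
  lay <- data.frame(
    cluster = sub("[.].*", "", colnames(tab)),
    subgroup = sub("^[^.]*[.]?", "", colnames(tab)),
    copies_A = as.integer(tab["Lonicera japonica", ]),
    copies_B = as.integer(tab["Lonicera japonica var. chinensis", ]))
  lay$subgroup[lay$cluster == "III"] <- "1"
  spec <- family_spec(lay, base_length = 40, seed = 2)
  panel <- generate_panel(spec)
  expect_equal(length(panel$cds_A), 133L)
  expect_equal(length(panel$cds_B), 122L)
  # per-variety counts equal the layout column sums per subgroup
  counts_A <- table(panel$meta$subgroup[panel$meta$variety == "A"])
  keys <- paste0(lay$cluster, "-", lay$subgroup)[lay$copies_A > 0]
  expect_equal(as.integer(counts_A[keys]), lay$copies_A[lay$copies_A > 0])
})

test_that("zero divergence with equal copies gives identical sets up to ids", {
  lay <- data.frame(cluster = "I", subgroup = "1", copies_A = 4, copies_B = 4)
  spec <- family_spec(lay, base_length = 50, divergence_pct = 0, seed = 9)
  panel <- generate_panel(spec)
  expect_identical(unname(panel$cds_A), unname(panel$cds_B))
  expect_identical(unname(panel$protein_A), unname(panel$protein_B))
})

test_that("generation is byte-identical for a fixed seed", {
  lay <- data.frame(cluster = "I", subgroup = "1", copies_A = 3, copies_B = 2)
  spec <- family_spec(lay, base_length = 60, seed = 33)
  p1 <- generate_panel(spec); p2 <- generate_panel(spec)
  expect_identical(p1, p2)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(p1, dir = d1); write_fixture(p2, dir = d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
})

test_that("invalid layouts are rejected", {
  lay <- data.frame(cluster = "I", subgroup = "1", copies_A = -1, copies_B = 2)
  expect_error(family_spec(lay), "non-negative")
  lay2 <- data.frame(cluster = "I", subgroup = "1", copies_A = 2,
                     copies_B = 2, pairs = 3)
  expect_error(family_spec(lay2), "pairs")
  lay3 <- data.frame(cluster = "I", subgroup = "1", copies_A = 2, copies_B = 2)
  expect_error(family_spec(lay3, divergence_pct = 50), "\\[0, 50\\)")
})

test_that("proteins are consistent translations of the CDS", {
  lay <- data.frame(cluster = "I", subgroup = "1", copies_A = 3, copies_B = 3)
  panel <- generate_panel(family_spec(lay, base_length = 80, seed = 14))
  expect_identical(panel$protein_A,
                   vapply(panel$cds_A, translate_cds, character(1)))
  # no premature stops: full-length proteins
  expect_true(all(nchar(panel$protein_A) == 80))
})

test_that("reads honour requested counts and planted allele counts exactly", {
  lay <- data.frame(cluster = "I", subgroup = "1", copies_A = 2, copies_B = 0)
  panel <- generate_panel(family_spec(lay, base_length = 100,
                                      divergence_pct = 0, seed = 6))
  ctg <- panel$cds_A
  g1 <- names(ctg)[1]; g2 <- names(ctg)[2]
  expr <- setNames(c(40L, 0L), c(g1, g2))
  ref <- substr(ctg[[g1]], 150, 150)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  vs <- data.frame(contig = g1, pos = 150, ref = ref, alt = alt,
                   alt_count = 10)
  reads <- generate_reads(ctg, expr, vs, read_length = 60, seed = 8)
  expect_true(all(reads$gene == g1))          # zero-count gene absent
  expect_equal(nrow(reads), 40L)
  # independent string-matching recovery: a clean read is a substring of
  # either the reference or the variant-applied contig; alt reads are
  # those matching only the variant form
  alt_ctg <- apply_variants(ctg, vs)[[g1]]
  is_sub <- function(s, big) grepl(s, big, fixed = TRUE)
  in_ref <- vapply(reads$seq, is_sub, logical(1), big = ctg[[g1]])
  in_alt <- vapply(reads$seq, is_sub, logical(1), big = alt_ctg)
  expect_true(all(in_ref | in_alt))
  expect_equal(sum(!in_ref), 10L)
  # constant-quality model: all bases at Phred 30
  expect_true(all(unlist(lapply(reads$qual, utf8ToInt)) - 33L == 30L))
})

test_that("out-of-bounds or mismatched variant specs are rejected", {
  lay <- data.frame(cluster = "I", subgroup = "1", copies_A = 1, copies_B = 0)
  panel <- generate_panel(family_spec(lay, base_length = 50, seed = 3))
  ctg <- panel$cds_A
  expr <- setNames(10L, names(ctg))
  vs <- data.frame(contig = names(ctg), pos = 1000, ref = "A", alt = "C",
                   alt_count = 1)
  expect_error(generate_reads(ctg, expr, vs, read_length = 40),
               "outside")
  expect_error(generate_reads(ctg, setNames(-1L, names(ctg))),
               "non-negative")
})

test_that("fixtures round-trip through write and read", {
  lay <- data.frame(cluster = c("I", "II"), subgroup = c("1", "2"),
                    copies_A = c(3, 2), copies_B = c(2, 2))
  panel <- generate_panel(family_spec(lay, base_length = 60, seed = 12))
  expr <- setNames(rep(15L, length(panel$cds_A)), names(panel$cds_A))
  reads <- generate_reads(panel$cds_A, expr, read_length = 50, seed = 13)
  d <- tempfile()
  write_fixture(panel, reads, d)
  back <- read_fixture(d)
  expect_identical(back$protein_A, panel$protein_A)
  expect_identical(back$cds_B, panel$cds_B)
  expect_identical(back$reads$seq, reads$seq)
  expect_identical(back$reads$qual, reads$qual)
  # truth orthology row count equals the number of planted pairs
  expect_equal(nrow(back$orthology), nrow(panel$orthology))
  expect_equal(nrow(back$orthology), 2 + 2)
})

test_that("an empty panel writes valid empty files", {
  lay <- data.frame(cluster = "I", subgroup = "1", copies_A = 0, copies_B = 0)
  panel <- generate_panel(family_spec(lay, base_length = 30, seed = 1))
  d <- tempfile()
  write_fixture(panel, dir = d)
  back <- read_fixture(d)
  expect_length(back$protein_A, 0)
  expect_equal(nrow(back$orthology), 0)
})
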