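test_that("identical sequences align without gaps", {
  s <- setNames(rep("MKTAYIAK", 3), c("a", "b", "c"))
  msa <- progressive_msa(s)
  expect_equal(attr(msa, "width"), 8L)
  expect_false(any(grepl("-", unclass(msa), fixed = TRUE)))
  expect_error(progressive_msa(s[1]), "at least 2")
})

test_that("a single-indel trio yields one gap column and round-trips", {
  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  del <- paste0(substr(base, 1, 14), substr(base, 16, nchar(base)))
  s <- c(full1 = base, full2 = base, short = del)
  msa <- progressive_msa(s)
  expect_equal(attr(msa, "width"), nchar(base))  # one gap column
  expect_equal(sum(as.matrix(msa) == "-"), 1L)
  expect_identical(ungap(msa), s)
})

test_that("ungapping any progressive alignment reproduces its inputs", {
  set.seed(17)
  lay <- data.frame(cluster = c("I", "II"), subgroup = c("1", "1"),
                    copies_A = c(4, 3), copies_B = 0)
  panel <- generate_panel(family_spec(lay, base_length = 60, seed = 18))
  msa <- progressive_msa(panel$protein_A)
  expect_identical(ungap(msa), panel$protein_A)
  expect_gte(attr(msa, "width"), max(nchar(panel$protein_A)))
})

test_that("distances follow p and Poisson definitions with pairwise deletion", {
  rows <- c(a = "ACGT", b = "ACGA")
  D <- distance_matrix(rows, model = "p")
  expect_equal(D["a", "b"], 0.25)
  expect_equal(diag(D), c(a = 0, b = 0))
  Dp <- distance_matrix(rows, model = "poisson")
  expect_gte(Dp["a", "b"], D["a", "b"])   # -ln(1-p) >= p
  # pairwise deletion: gap columns dropped per pair
  rows2 <- c(a = "AC-T", b = "ACGT", c = "TTTT")
  D2 <- distance_matrix(rows2, model = "p")
  expect_equal(D2["a", "b"], 0)
  # a pair with no comparable columns is rejected by name
  rows3 <- c(a = "A--", b = "-CC", c = "ACC")
  expect_error(distance_matrix(rows3), "a and b")
})

test_that("neighbor joining resolves three taxa in closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  pd <- tree_distances(tr)
  expect_equal(pd[rownames(D), colnames(D)], D, tolerance = 1e-12)
})

test_that("neighbor joining recovers additive matrices exactly", {
  # four-point condition: dAB + dCD = 10 < dAC + dBD = dAD + dBC = 12,
  # so the split must be AB|CD
  lab <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(lab, lab))
  tr <- neighbor_joining(D)
  pd <- tree_distances(tr)
  expect_equal(pd[lab, lab], D, tolerance = 1e-9)
  expect_identical(samefam:::tree_splits(tr), "C,D")  # the AB|CD bipartition

  # random additive matrices from random trees round-trip to 1e-9
  set.seed(23)
  for (i in 1:5) {
    rt <- ape::rtree(8)
    rt$edge.length <- rt$edge.length + 0.05
    Dr <- ape::cophenetic.phylo(rt)
    tr2 <- neighbor_joining(Dr)
    expect_equal(tree_distances(tr2)[rownames(Dr), colnames(Dr)], Dr,
                 tolerance = 1e-9)
    # independent reference: ape's own NJ yields the same path lengths
    tr3 <- ape::nj(Dr)
    expect_equal(ape::cophenetic.phylo(tr3)[rownames(Dr), colnames(Dr)], Dr,
                 tolerance = 1e-9)
  }
})

test_that("degenerate distance input is rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(D), "3 taxa")
  D3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D3), "asymmetric")
})
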