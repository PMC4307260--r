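trees_fixture <- function() {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  list(t1 = t1, t2 = t2)
}

test_that("unanimous replicates give their topology with full support", {
  tf <- trees_fixture()
  cons <- consensus_from_trees(rep(list(tf$t1), 10), 0.5)
  expect_identical(sort(samefam:::tree_splits(cons)),
                   sort(samefam:::tree_splits(tf$t1)))
  expect_true(all(as.numeric(cons$node.label[nzchar(cons$node.label)]) == 100))
})

test_that("a split in 6 of 10 trees is retained with support 60", {
  tf <- trees_fixture()
  cons <- consensus_from_trees(c(rep(list(tf$t1), 6), rep(list(tf$t2), 4)),
                               0.5)
  expect_true("c,d" %in% samefam:::tree_splits(cons))
  sup <- as.numeric(cons$node.label[nzchar(cons$node.label)])
  expect_true(all(sup == 60))
  # minority splits from the other topology are absent
  expect_false("b,d" %in% samefam:::tree_splits(cons))
})

test_that("consensus retains only splits above threshold and compatible", {
  tf <- trees_fixture()
  trees <- c(rep(list(tf$t1), 6), rep(list(tf$t2), 4))
  cons <- consensus_from_trees(trees, 0.7)   # 60% split now dropped
  expect_length(samefam:::tree_splits(cons), 0)
  expect_error(consensus_from_trees(trees, 0.4), "threshold")
  expect_error(consensus_from_trees(trees, 1), "threshold")
})

msa_fixture <- function(seed = 7) {
  lay <- data.frame(cluster = c("I", "I", "II"), subgroup = c("1", "2", "1"),
                    copies_A = c(4, 3, 3), copies_B = 0)
  panel <- generate_panel(family_spec(lay, base_length = 120,
                                      divergence_pct = 0,
                                      duplication_divergence_pct = 8,
                                      subgroup_divergence_pct = 20,
                                      cluster_divergence_pct = 35,
                                      seed = seed))
  list(panel = panel, msa = progressive_msa(panel$protein_A))
}

test_that("bootstrap consensus is deterministic per seed and validates input", {
  fx <- msa_fixture()
  c1 <- bootstrap_consensus(fx$msa, replicates = 15, seed = 5)
  c2 <- bootstrap_consensus(fx$msa, replicates = 15, seed = 5)
  expect_identical(ape::write.tree(c1), ape::write.tree(c2))
  expect_error(bootstrap_consensus(fx$msa, replicates = 0), "replicates")
  expect_error(bootstrap_consensus(fx$msa, threshold = 0.3), "threshold")
})

test_that("mapped supports annotate the reference topology", {
  fx <- msa_fixture()
  tr <- bootstrap_consensus(fx$msa, replicates = 25, seed = 9,
                            method = "map")
  expect_identical(sort(tr$tip.label), sort(names(fx$panel$protein_A)))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("planted clusters and subgroups are recovered from the tree", {
  fx <- msa_fixture()
  tr <- bootstrap_consensus(fx$msa, replicates = 50, seed = 3,
                            method = "map")
  asg <- extract_subgroups(tr, n_clusters = 2, min_support = 50,
                           n_subgroups = 3)
  truth <- fx$panel$meta[match(asg$id, fx$panel$meta$id), ]
  part <- function(f, ids) unname(lapply(split(ids, f), sort))
  expect_true(setequal(part(asg$cluster, asg$id),
                       part(truth$cluster, truth$id)))
  expect_true(setequal(part(asg$subgroup, asg$id),
                       part(truth$subgroup, truth$id)))
  # labels: clusters by decreasing size, subgroups numbered within
  expect_equal(sum(asg$cluster == "I"), 7)
  expect_true(all(grepl("^(I|II)-[0-9]+$", asg$subgroup)))
  # every leaf assigned exactly once
  expect_identical(sort(asg$id), sort(tr$tip.label))
})

test_that("single-cluster extraction and unsatisfiable cuts behave", {
  fx <- msa_fixture()
  tr <- bootstrap_consensus(fx$msa, replicates = 10, seed = 2,
                            method = "map")
  one <- extract_subgroups(tr, n_clusters = 1)
  expect_true(all(one$cluster == "I"))
  expect_equal(nrow(one), length(tr$tip.label))
  expect_error(extract_subgroups(tr, n_clusters = 3, min_support = 101),
               "support")
})
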