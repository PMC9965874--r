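# Newick I/O, midpoint rooting, monophyly, clade metrics

random_bl_tree <- function(n) {
  t <- ape::rtree(n)
  t$edge.length <- runif(nrow(t$edge), 0.01, 1)
  t
}

patristic <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

root_tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

test_that("Newick parsing validates structure and round-trips to 1e-9", {
  t <- read_newick(text = "((A:1,B:3):1,C:2);")
  expect_identical(sort(t$tip.label), c("A", "B", "C"))
  expect_error(read_newick(text = "((A:1,A:2):1,B:1);"), "duplicate")
  expect_error(read_newick(text = "((A:1,B:2;"), "parse error")
  expect_error(read_newick(text = "((A,B),C);"), "branch lengths")
  set.seed(71)
  for (k in 1:40) {
    t0 <- random_bl_tree(sample(4:30, 1))
    t1 <- read_newick(text = write_newick(t0))
    expect_identical(sort(t1$tip.label), sort(t0$tip.label))
    expect_lt(max(abs(patristic(t1) - patristic(t0))), 1e-9)
  }
})

test_that("midpoint rooting equalizes the two deepest tips on hand examples", {
  # two leaves: midpoint of the 4-long path
  r2 <- midpoint_root(read_newick(text = "(A:1,B:3);"))
  expect_equal(unname(root_tip_depths(r2)[c("A", "B")]), c(2, 2))
  # midpoint landing exactly on an internal node: no zero-length edge
  r3 <- midpoint_root(read_newick(text = "((A:1,B:3):1,C:2);"))
  d3 <- root_tip_depths(r3)
  expect_equal(unname(d3[c("A", "B", "C")]), c(1, 3, 3))
  expect_false(any(r3$edge.length < 1e-12))
  # midpoint strictly inside an edge
  r4 <- midpoint_root(read_newick(text = "((A:1,B:1):1,C:8);"))
  d4 <- root_tip_depths(r4)
  expect_equal(max(d4), 5)          # half the 10-long diameter
  expect_equal(unname(d4["C"]), 5)
  expect_error(midpoint_root(read_newick(text = "(A:1);")), "2 leaves")
})

test_that("midpoint rooting preserves patristic distances and halves the diameter", {
  set.seed(72)
  for (k in 1:20) {
    t0 <- random_bl_tree(20)
    r <- midpoint_root(t0)
    expect_lt(max(abs(patristic(r) - patristic(t0))), 1e-9)
    depths <- root_tip_depths(r)
    expect_equal(max(depths), max(patristic(t0)) / 2, tolerance = 1e-9)
    # independent cross-check: same maximal depth as phangorn's midpoint
    pm <- phangorn::midpoint(t0)
    expect_equal(max(depths), max(root_tip_depths(pm)), tolerance = 1e-9)
  }
})

test_that("monophyly is decided by the MRCA's descendant set", {
  t <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(t, "A")$monophyletic)
  expect_true(is_monophyletic(t, c("A", "B"))$monophyletic)
  ac <- is_monophyletic(t, c("A", "C"))
  expect_false(ac$monophyletic)
  expect_setequal(ac$intruders, c("B", "D"))
  expect_error(is_monophyletic(t, c("A", "Q")), "unknown leaf")
})

test_that("clade metrics recover stems and depths on hand examples", {
  t <- read_newick(text = "((A:0.1,B:0.1):0.05,C:0.5);")
  m <- clade_metrics(t, c("A", "B"))
  expect_equal(m$stem_length, 0.05)
  expect_equal(m$mean_mrca_to_tip, 0.1)
  expect_equal(m$mean_root_to_tip, 0.15)
  expect_identical(m$n_leaves, 2L)
  # whole leaf set: stem reported as 0, depth is the tree-wide mean
  all_m <- clade_metrics(t, c("A", "B", "C"))
  expect_equal(all_m$stem_length, 0)
  expect_equal(all_m$mean_root_to_tip, mean(c(0.15, 0.15, 0.5)))
  # single leaf: zero depth below its own MRCA
  expect_equal(clade_metrics(t, "C")$mean_mrca_to_tip, 0)
  expect_error(clade_metrics(t, c("A", "C")), "intruding leaves: B")
})

test_that("fixture trees carry their planted clade structure exactly", {
  ft <- generate_fixture_tree(seed = 73)
  for (nm in names(ft$clades)) {
    expect_true(is_monophyletic(ft$tree, ft$clades[[nm]])$monophyletic)
  }
  m_shallow <- clade_metrics(ft$tree, ft$clades$shallow)
  m_deep <- clade_metrics(ft$tree, ft$clades$deep)
  expect_equal(m_shallow$mean_mrca_to_tip, 0.1, tolerance = 1e-9)
  expect_equal(m_deep$mean_mrca_to_tip, 0.5, tolerance = 1e-9)
  # a planted clade plus the outgroup is never monophyletic
  expect_false(
    is_monophyletic(ft$tree,
                    c(ft$clades$shallow, "outgroup"))$monophyletic)
  # single-clade spec degenerates to a cherry
  cherry <- generate_fixture_tree(
    clade_spec = list(list(name = "pair", n_leaves = 2L, depth = 0.3)),
    seed = 74)
  expect_identical(ape::Ntip(cherry$tree), 3L)
  expect_equal(clade_metrics(cherry$tree, cherry$clades$pair)$mean_mrca_to_tip,
               0.3, tolerance = 1e-9)
})
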