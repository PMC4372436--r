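test_that("parse_newick reads simple trees and preserves polytomies", {
  t2 <- parse_newick("(A:1,B:1):0;")
  expect_s3_class(t2, "phylo")
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(total_branch_length(t2), 2.0)

  t3 <- parse_newick("(A:1,B:1,C:1):0;")
  expect_equal(length(t3$tip.label), 3L)
  expect_equal(t3$Nnode, 1L)  # single root, polytomy kept

  expect_error(parse_newick("(A:1,A:1);"), "duplicate leaf labels")
  expect_error(parse_newick("(A:1,B:1"), "unclosed|missing terminal")
  expect_error(parse_newick("(A:1,B:1));"), "unmatched.*character")
  expect_error(parse_newick("(A,B);"), "no branch lengths")
  expect_equal(total_branch_length(parse_newick("(A,B);",
                                                missing_lengths = "zero")), 0)
})

test_that("write/parse round trip preserves topology, labels and lengths", {
  for (seed in 1:10) {
    tree <- random_test_tree(8, seed)
    back <- parse_newick(write_newick(tree))
    expect_setequal(back$tip.label, tree$tip.label)
    d1 <- patristic_distances(tree)
    d2 <- patristic_distances(back)[rownames(d1), colnames(d1)]
    expect_equal(d2, d1, tolerance = 1e-10)
  }
})

test_that("patristic distances match the root-path enumeration oracle", {
  for (seed in 1:25) {
    tree <- random_test_tree(6, seed)
    expect_equal(patristic_distances(tree), oracle_patristic(tree),
                 tolerance = 1e-12)
  }
})

test_that("patristic distances satisfy the four-point condition", {
  for (seed in 1:10) {
    tree <- random_test_tree(6, seed)
    d <- patristic_distances(tree)
    tips <- tree$tip.label
    combos <- combn(tips, 4, simplify = FALSE)
    for (q in combos) {
      s <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                  d[q[1], q[3]] + d[q[2], q[4]],
                  d[q[1], q[4]] + d[q[2], q[3]]))
      expect_lte(s[3] - s[2], 1e-9)
    }
  }
})

test_that("pruning preserves pairwise distances among retained taxa", {
  cat_tree <- parse_newick("((A:1,B:1):1,C:2);")
  pruned <- prune_to_taxa(cat_tree, c("A", "C"))
  expect_equal(patristic_distances(pruned)["A", "C"], 4.0)

  for (seed in 1:10) {
    tree <- random_test_tree(10, seed)
    keep <- sample(tree$tip.label, 5)
    sub <- prune_to_taxa(tree, keep)
    expect_setequal(sub$tip.label, keep)
    d_full <- patristic_distances(tree)[keep, keep]
    d_sub <- patristic_distances(sub)[keep, keep]
    expect_equal(d_sub, d_full, tolerance = 1e-10)
  }

  expect_equal(total_branch_length(prune_to_taxa(cat_tree, c("A", "B", "C"))),
               total_branch_length(cat_tree))
  expect_error(prune_to_taxa(cat_tree, c("A", "Z")), "unknown taxa: Z")
  expect_error(prune_to_taxa(cat_tree, character()), "empty")
})

test_that("pruning an ultrametric tree stays ultrametric", {
  tree <- simulate_bd_tree(30, 1, 0, seed = 5)
  sub <- prune_to_taxa(tree, sample(tree$tip.label, 12))
  expect_true(is_ultrametric(sub, tol = 1e-9))
})

test_that("mean-path-length dating hits its calibrations and ultrametricity", {
  # fixed point: already-ultrametric tree calibrated at its own height
  tree <- simulate_bd_tree(15, 1, 0.2, seed = 3)
  h <- tree_height(tree)
  out <- mpl_ultrametricize(tree, root_age = h)
  expect_equal(sort(out$edge.length), sort(tree$edge.length),
               tolerance = 1e-9)

  # cherry with unequal leaf branches: MPL root age equals the calibration,
  # so dating only equalizes the two leaf branches
  cherry <- parse_newick("(A:1,B:3);")
  u <- mpl_ultrametricize(cherry, root_age = 2)
  expect_equal(sort(u$edge.length), c(2, 2))

  # hand-computed three-leaf case: internal MPL age 1, root MPL age 3
  t3 <- parse_newick("((A:1,B:1):1,C:4);")
  u3 <- mpl_ultrametricize(t3, root_age = 3)
  expect_true(is_ultrametric(u3, tol = 1e-9))
  d <- patristic_distances(u3)
  expect_equal(tree_height(u3), 3)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 6)
  expect_lt(d["A", "B"], d["A", "C"])
})

test_that("mpl output is ultrametric on random phylograms", {
  for (seed in 1:10) {
    tree <- random_test_tree(12, seed)
    out <- mpl_ultrametricize(tree, root_age = 10)
    expect_true(is_ultrametric(out, tol = 1e-9))
    expect_equal(tree_height(out), 10, tolerance = 1e-9)
    expect_true(all(out$edge.length >= 0))
  }
})

test_that("mpl honours internal calibrations and rejects conflicts", {
  tree <- parse_newick("(((A:1,B:2):1,C:3):1,D:5);")
  cal <- calibration(c("A", "B"), 1.5)
  out <- mpl_ultrametricize(tree, calibrations = list(cal), root_age = 6)
  expect_true(is_ultrametric(out, tol = 1e-9))
  # the calibrated MRCA sits at exactly its assigned age
  d <- patristic_distances(out)
  expect_equal(d["A", "B"], 2 * 1.5)
  expect_equal(tree_height(out), 6)

  # descendant calibrated older than the root age is a conflict
  expect_error(
    mpl_ultrametricize(tree, calibrations = list(calibration(c("A", "B"), 9)),
                       root_age = 6),
    "conflicting calibrations")
  expect_error(mpl_ultrametricize(tree,
                                  list(calibration(c("A", "Z"), 2)),
                                  root_age = 6),
               "unknown taxa")
  expect_error(mpl_ultrametricize(tree), "root must be calibrated")
})
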