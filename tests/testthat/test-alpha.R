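test_that("faith_pd matches hand-worked and oracle values", {
  star <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(faith_pd(star, c("A", "B")), 2.0)
  expect_equal(faith_pd(star, c("A", "B", "C")), total_branch_length(star))

  # single taxon on an ultrametric tree: rooted PD equals the tree height
  tree <- simulate_bd_tree(10, 1, 0, seed = 2)
  expect_equal(faith_pd(tree, tree$tip.label[1]), tree_height(tree),
               tolerance = 1e-9)

  expect_error(faith_pd(star, c("A", "nope")), "unknown taxa")
  expect_error(faith_pd(star, character()), "empty")
})

test_that("faith_pd agrees with the edge-enumeration oracle, both rootings", {
  for (seed in 1:25) {
    tree <- random_test_tree(8, seed)
    set.seed(seed + 1000)
    taxa <- sample(tree$tip.label, sample(2:6, 1))
    expect_equal(faith_pd(tree, taxa), oracle_pd(tree, taxa, rooted = TRUE),
                 tolerance = 1e-12)
    expect_equal(faith_pd(tree, taxa, include_root = FALSE),
                 oracle_pd(tree, taxa, rooted = FALSE), tolerance = 1e-12)
  }
})

test_that("PD is monotone under taxon addition and maximal at the pool", {
  tree <- random_test_tree(12, 99)
  set.seed(1)
  taxa <- sample(tree$tip.label, 4)
  pd0 <- faith_pd(tree, taxa)
  for (extra in setdiff(tree$tip.label, taxa)) {
    expect_gte(faith_pd(tree, c(taxa, extra)), pd0 - 1e-12)
  }
  expect_equal(faith_pd(tree, tree$tip.label), total_branch_length(tree))
})

test_that("mpd and mntd match brute-force pair enumeration", {
  star <- parse_newick("(A:1,B:1,C:1);")
  d_star <- patristic_distances(star)
  expect_equal(mpd(d_star, c("A", "B")), 2.0)
  expect_equal(mpd(d_star, c("A", "B", "C")), 2.0)
  expect_equal(mntd(d_star, c("A", "B")), 2.0)

  # cherry pair plus a distant outgroup: MNTD < MPD
  t3 <- parse_newick("((A:1,B:1):4,C:5);")
  d3 <- patristic_distances(t3)
  expect_equal(mpd(d3, c("A", "B", "C")), (2 + 10 + 10) / 3)
  expect_equal(mntd(d3, c("A", "B", "C")), (2 + 2 + 10) / 3)
  expect_lt(mntd(d3, c("A", "B", "C")), mpd(d3, c("A", "B", "C")))

  for (seed in 1:25) {
    tree <- random_test_tree(10, seed)
    d <- patristic_distances(tree)
    set.seed(seed + 2000)
    taxa <- sample(tree$tip.label, 6)
    expect_equal(mpd(d, taxa), oracle_mpd(d, taxa), tolerance = 1e-12)
    expect_equal(mntd(d, taxa), oracle_mntd(d, taxa), tolerance = 1e-12)
  }

  expect_warning(res <- mpd(d3, "A"), "undefined")
  expect_true(is.na(res))
  # MPD of the pool equals the mean off-diagonal entry
  d <- patristic_distances(random_test_tree(9, 5))
  expect_equal(mpd(d, rownames(d)), mean(d[upper.tri(d)]))
})

test_that("ses_metric is reproducible and degenerates gracefully", {
  tree <- simulate_bd_tree(30, 1, 0.2, seed = 8)
  d <- patristic_distances(tree)
  pool <- tree$tip.label
  taxa <- pool[1:10]
  a <- ses_metric("mpd", d, taxa, pool, n_rand = 199, seed = 42L)
  b <- ses_metric("mpd", d, taxa, pool, n_rand = 199, seed = 42L)
  expect_identical(a, b)
  expect_equal(a$z, (a$observed - a$null_mean) / a$null_sd)
  expect_gte(a$p_rank, 1 / 200)
  expect_lte(a$p_rank, 1)

  # site = entire pool: every null draw is the pool; flagged, not NaN
  deg <- ses_metric("mpd", d, pool, pool, n_rand = 99, seed = 1L)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$z))
  expect_equal(deg$null_sd, 0)

  expect_error(ses_metric("mpd", d, c("t1", "zz"), pool), "contained in the pool")
  expect_error(ses_metric("mpd", d, "t1", pool), "richness must be >= 2")
})

test_that("overdispersed assemblies give positive z(MPD), clustered negative", {
  tree <- simulate_bd_tree(80, 1, 0.3, seed = 21)
  d <- patristic_distances(tree)
  pool <- tree$tip.label
  z_for <- function(scenario, seed) {
    cm <- assemble_communities(tree, 30, scenario_spec(scenario, 12,
                                                       strength = 5,
                                                       seed = seed))
    sapply(rownames(cm), function(s) {
      ses_metric("mpd", d, colnames(cm)[cm[s, ] > 0], pool, n_rand = 199,
                 seed = bioregdiv:::site_seed(1L, s))$z
    })
  }
  z_over <- z_for("overdispersed", 31)
  z_clus <- z_for("clustered", 32)
  expect_gt(mean(z_over > 0), 0.95)
  expect_gt(mean(z_clus < 0), 0.95)
})

test_that("alpha_table is internally consistent and carries a Total row", {
  tree <- simulate_bd_tree(25, 1, 0, seed = 4)
  cm <- assemble_communities(tree, 4, scenario_spec("random", 8, seed = 9))
  tax <- stats::setNames(paste0("F", rep(1:5, 5)), tree$tip.label)
  tab <- alpha_table(tree, cm, tax, n_rand = 99, seed = 7L)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$site[5], "Total")
  expect_equal(tab$sr[1:4], unname(richness(cm)))
  expect_equal(tab$fam[1:4], unname(family_rollup(cm, tax)$fam))
  expect_true(all(tab$pd <= total_branch_length(tree) + 1e-9))
  pool <- colnames(cm)[colSums(cm) > 0]
  expect_equal(tab$sr[5], length(pool))
  expect_equal(tab$pd[5], faith_pd(tree, pool))
  expect_true(is.na(tab$nri[5]) && is.na(tab$nti[5]))

  # single site covering every taxon: PD = total branch length
  cm_all <- matrix(1, 1, 25, dimnames = list("s1", tree$tip.label))
  tab_all <- suppressWarnings(alpha_table(tree, cm_all, n_rand = 99))
  expect_equal(tab_all$pd[1], total_branch_length(tree))
})

test_that("per-site null streams are stable when sites are added", {
  tree <- simulate_bd_tree(40, 1, 0, seed = 11)
  cm <- assemble_communities(tree, 3, scenario_spec("random", 10, seed = 2))
  tab3 <- alpha_table(tree, cm, n_rand = 99, seed = 5L,
                      pool = tree$tip.label)
  cm4 <- rbind(cm, s_extra = as.numeric(seq_len(ncol(cm)) %in% 1:10))
  rownames(cm4)[4] <- "s_extra"
  tab4 <- alpha_table(tree, cm4, n_rand = 99, seed = 5L,
                      pool = tree$tip.label)
  expect_equal(tab4$nri[1:3], tab3$nri[1:3])
  expect_equal(tab4$nti[1:3], tab3$nti[1:3])
})
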