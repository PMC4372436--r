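test_that("spearman handles worked examples and monotone invariance", {
  expect_equal(spearman(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman(1:6, -(1:6)^3)$rho, -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)

  set.seed(3)
  x <- rnorm(12)
  y <- rnorm(12)
  base <- spearman(x, y)
  trans <- spearman(exp(x), y^3 * 0 + y)  # monotone transform of x
  expect_equal(trans$rho, base$rho)

  # pairwise-complete dropping
  x2 <- c(x, NA)
  y2 <- c(y, 1)
  expect_equal(spearman(x2, y2)$n, 12)

  expect_warning(res <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman(1:3, 3:1), "at least 4")
})

test_that("exact spearman p agrees with cor.test on tie-free small samples", {
  set.seed(9)
  for (i in 1:5) {
    x <- sample(1:7)
    y <- sample(1:7)
    ours <- spearman(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE))
    expect_equal(ours$rho, unname(ref$estimate))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  expect_equal(bonferroni(0.2, m = 1), 0.2)
  expect_equal(bonferroni(c(0.01, 0.4)), c(0.02, 0.8))
})

test_that("mantel_relate: identity, monotone transform, and id alignment", {
  d <- planted_config_dist(8, 21)
  res <- mantel_relate(d, d, n_perm = 199, seed = 3L)
  expect_equal(res$rho, 1)
  expect_equal(res$p, 1 / 200)

  # monotone transform keeps rho = 1
  res2 <- mantel_relate(d, d^2, n_perm = 199, seed = 3L)
  expect_equal(res2$rho, 1)

  # d2 id order must not matter
  perm <- sample(rownames(d))
  res3 <- mantel_relate(d, d[perm, perm] * 2, n_perm = 199, seed = 3L)
  expect_equal(res3$rho, 1)

  d_bad <- d
  rownames(d_bad) <- colnames(d_bad) <- paste0("x", 1:8)
  expect_error(mantel_relate(d, d_bad), "same id set")
})

test_that("exact mantel p matches exhaustive permutation enumeration", {
  d1 <- planted_config_dist(5, 31)
  d2 <- planted_config_dist(5, 32)
  res <- mantel_relate(d1, d2, exact = TRUE)
  expect_equal(res$n_perm, 120L)

  # independent enumeration oracle
  ids <- rownames(d1)
  ut <- upper.tri(d1)
  perms <- bioregdiv:::permutations_of(5)
  rhos <- apply(perms, 1, function(p) {
    m2 <- d2[p, p]
    cor(d1[ut], m2[ut], method = "spearman")
  })
  obs <- cor(d1[ut], d2[ut], method = "spearman")
  expect_equal(res$rho, obs)
  expect_equal(res$p, mean(rhos >= obs - 1e-12))
})

test_that("mantel p is roughly uniform under independence", {
  set.seed(5)
  ps <- replicate(40, {
    d1 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
    d2 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
    ids <- paste0("s", 1:7)
    dimnames(d1) <- dimnames(d2) <- list(ids, ids)
    mantel_relate(d1, d2, n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("log-log PD~SR regression recovers exact power laws", {
  sr <- c(10, 25, 80, 200)
  pd <- 10^2.5 * sr^0.7
  fit <- suppressWarnings(loglog_pd_sr(sr, pd))
  expect_equal(fit$slope, 0.7, tolerance = 1e-12)
  expect_equal(fit$intercept, 2.5, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  two <- suppressWarnings(loglog_pd_sr(c(10, 100), c(50, 400)))
  expect_equal(two$r2, 1)
  expect_error(loglog_pd_sr(c(0, 10), c(1, 2)), "positive")
})

test_that("correlation suite recovers planted rank correlation", {
  tree <- simulate_bd_tree(120, 1, 0.2, seed = 51)
  cm <- assemble_communities(tree, 50, scenario_spec("random", 20, seed = 52))
  alpha <- data.frame(site = rownames(cm), sr = unname(richness(cm)),
                      fam = NA_integer_, pd = NA_real_, mpd = NA_real_,
                      mntd = NA_real_, stringsAsFactors = FALSE)
  # PD per site, no randomization needed for this check
  alpha$pd <- sapply(rownames(cm), function(s)
    faith_pd(tree, colnames(cm)[cm[s, ] > 0]))
  attrs <- generate_attributes(alpha, target_rho = 0.8, seed = 53L)
  suite <- correlation_suite(alpha, attrs)
  got <- suite$rho[suite$diversity == "pd" &
                   suite$attribute == "rem_rf_pct_sub"]
  expect_equal(got, 0.8, tolerance = 0.1)

  # a duplicated diversity column as an attribute gives rho exactly 1
  attrs2 <- attrs
  attrs2$re_count <- alpha$pd
  suite2 <- correlation_suite(alpha, attrs2)
  expect_equal(suite2$rho[suite2$diversity == "pd" &
                          suite2$attribute == "re_count"], 1)
})

test_that("correlation suite excludes sites and reports n for the subset", {
  tree <- simulate_bd_tree(40, 1, 0, seed = 61)
  cm <- assemble_communities(tree, 8, scenario_spec("random", 10, seed = 62))
  alpha <- data.frame(site = rownames(cm), sr = unname(richness(cm)),
                      pd = sapply(rownames(cm), function(s)
                        faith_pd(tree, colnames(cm)[cm[s, ] > 0])),
                      stringsAsFactors = FALSE)
  alpha$sr <- alpha$sr + stats::runif(8)  # break rank ties
  attrs <- generate_attributes(alpha, target_rho = 0.5, seed = 63L)
  suite <- correlation_suite(alpha, attrs, exclude = paste0("s", 1:4))
  sub <- suite[suite$subset == "excluded", ]
  expect_true(all(sub$n == 4))
  expect_true(all(suite$p_adj >= suite$p - 1e-12))
})
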