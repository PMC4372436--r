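# Brute-force oracles for the phylogenetic metrics. These walk the tree's
# edge table directly (naive root-path enumeration) and never call the
# package's own spanning-edge machinery, so they stay independent of the
# code paths they check.

# list over tips: indices (into tree$edge rows) of the edges on the
# root -> tip path
oracle_root_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_edge <- integer(n_tip + tree$Nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  lapply(seq_len(n_tip), function(tip) {
    path <- integer()
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1L]
    }
    path
  })
}

oracle_patristic <- function(tree) {
  paths <- oracle_root_paths(tree)
  n <- length(paths)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      shared <- intersect(paths[[i]], paths[[j]])
      edges <- c(setdiff(paths[[i]], shared), setdiff(paths[[j]], shared))
      d[i, j] <- d[j, i] <- sum(tree$edge.length[edges])
    }
  }
  d
}

oracle_pd <- function(tree, taxa, rooted = TRUE) {
  paths <- oracle_root_paths(tree)
  idx <- match(taxa, tree$tip.label)
  union_edges <- unique(unlist(paths[idx]))
  if (rooted) return(sum(tree$edge.length[union_edges]))
  common <- Reduce(intersect, paths[idx])
  sum(tree$edge.length[setdiff(union_edges, common)])
}

oracle_mpd <- function(d, taxa) {
  vals <- c()
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      if (j > i) vals <- c(vals, d[taxa[i], taxa[j]])
    }
  }
  mean(vals)
}

oracle_mntd <- function(d, taxa) {
  mean(sapply(taxa, function(i) min(sapply(setdiff(taxa, i),
                                           function(j) d[i, j]))))
}

oracle_dpw <- function(d, ta, tb) {
  vals <- c()
  for (i in ta) for (j in tb) vals <- c(vals, d[i, j])
  mean(vals)
}

oracle_dnn <- function(d, ta, tb) {
  a_to_b <- mean(sapply(ta, function(i) min(d[i, tb])))
  b_to_a <- mean(sapply(tb, function(j) min(d[ta, j])))
  (a_to_b + b_to_a) / 2
}

oracle_unifrac <- function(tree, ta, tb) {
  paths <- oracle_root_paths(tree)
  ea <- unique(unlist(paths[match(ta, tree$tip.label)]))
  eb <- unique(unlist(paths[match(tb, tree$tip.label)]))
  len <- tree$edge.length
  union_len <- sum(len[union(ea, eb)])
  uniq <- sum(len[setdiff(ea, eb)]) + sum(len[setdiff(eb, ea)])
  if (union_len > 0) uniq / union_len else 0
}

# random non-ultrametric test tree with unit-scale branch lengths
random_test_tree <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.1, 2)
  tree
}

random_community <- function(tree, n_sites, min_k = 2, seed = 1) {
  set.seed(seed)
  pool <- tree$tip.label
  m <- matrix(0, n_sites, length(pool),
              dimnames = list(paste0("s", seq_len(n_sites)), pool))
  for (i in seq_len(n_sites)) {
    k <- sample(min_k:length(pool), 1)
    m[i, sample(pool, k)] <- 1
  }
  m
}

planted_config_dist <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 2), n, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d
}

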