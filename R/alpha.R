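# Count, for every edge, how many of the focal taxa sit below it. The
# spanning-edge classification drives both Faith's PD and UniFrac.
edge_taxon_counts <- function(tree, taxa) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  below <- integer(n_all)
  below[match(taxa, tree$tip.label)] <- 1L
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(post))) {
    below[post[k, 1L]] <- below[post[k, 1L]] + below[post[k, 2L]]
  }
  below[tree$edge[, 2L]]
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree spanning a set of taxa.
#' By default the subtree is rooted: the path from the taxa back to the tree
#' root is included, so a single taxon on an ultrametric tree has PD equal
#' to the tree height and the full leaf set has PD equal to the total branch
#' length. Set \code{include_root = FALSE} for the unrooted convention
#' (branch lengths strictly between the taxa).
#'
#' @param tree A \code{phylo} object.
#' @param taxa Character vector of leaf labels (non-empty subset).
#' @param include_root Include the root path (default TRUE).
#' @return Non-negative numeric scalar.
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("empty taxon set", call. = FALSE)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "), call. = FALSE)
  cnt <- edge_taxon_counts(tree, taxa)
  keep <- if (include_root) cnt > 0L else cnt > 0L & cnt < length(taxa)
  sum(tree$edge.length[keep])
}

#' Mean pairwise phylogenetic distance within a community
#'
#' @param dist Patristic distance matrix over taxa (see
#'   \code{\link{patristic_distances}}).
#' @param taxa Character vector of taxon ids, at least 2 (with fewer the
#'   quantity is undefined and \code{NA} is returned with a warning).
#' @return Mean of d(i, j) over all unordered distinct pairs.
#' @export
mpd <- function(dist, taxa) {
  taxa <- unique(as.character(taxa))
  check_taxa_in_dist(dist, taxa)
  n <- length(taxa)
  if (n < 2L) {
    warning("MPD undefined for fewer than 2 taxa", call. = FALSE)
    return(NA_real_)
  }
  sub <- dist[taxa, taxa]
  sum(sub) / (n * (n - 1))
}

#' Mean nearest taxon distance within a community
#'
#' @inheritParams mpd
#' @return Mean over taxa of the distance to the nearest other community
#'   member.
#' @export
mntd <- function(dist, taxa) {
  taxa <- unique(as.character(taxa))
  check_taxa_in_dist(dist, taxa)
  n <- length(taxa)
  if (n < 2L) {
    warning("MNTD undefined for fewer than 2 taxa", call. = FALSE)
    return(NA_real_)
  }
  sub <- dist[taxa, taxa]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

check_taxa_in_dist <- function(dist, taxa) {
  missing <- setdiff(taxa, rownames(dist))
  if (length(missing))
    stop("taxa absent from distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Deterministic per-site RNG stream: a stable string hash folded into the
# master seed, so adding or reordering sites never perturbs another site's
# null draws.
site_seed <- function(master_seed, site_id) {
  h <- 0
  for (code in utf8ToInt(as.character(site_id)))
    h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(master_seed) + h) %% 2147483647)
}

#' Standardized effect size of MPD or MNTD under the sample-pool null
#'
#' Null communities are uniform random subsets of the taxon pool with the
#' same richness as the observed community, drawn without replacement and
#' independently for each randomization (the "sample.pool" null). The
#' standardized effect size is z = (observed - null mean) / null sd, and the
#' two-tailed p-value comes from the mid-rank of the observed value among
#' observed + null: p = 2 min(r, n+1-r)/(n+1), capped at 1. Positive z means
#' community members are more phylogenetically distant than chance
#' (evenness/overdispersion); negative z means clustering. NRI is reported
#' here as z of MPD and NTI as z of MNTD in that orientation; note that much
#' of the literature multiplies these indices by -1.
#'
#' When the observed community equals the whole pool every null draw is the
#' community itself; z is then reported as \code{NA} with
#' \code{degenerate = TRUE} rather than propagating 0/0.
#'
#' @param metric "mpd" or "mntd".
#' @param dist Patristic distance matrix over (at least) the pool.
#' @param taxa Observed community (character vector, richness >= 2).
#' @param pool Taxon pool to draw nulls from: all taxa occurring anywhere in
#'   the community matrix under study.
#' @param n_rand Number of randomizations (default 999).
#' @param seed Integer seed for this site's null stream.
#' @return List with fields \code{metric, observed, null_mean, null_sd, z,
#'   p_rank, n_rand, seed, degenerate}.
#' @export
ses_metric <- function(metric = c("mpd", "mntd"), dist, taxa, pool,
                       n_rand = 999, seed = 1L) {
  metric <- match.arg(metric)
  taxa <- unique(as.character(taxa))
  pool <- unique(as.character(pool))
  check_taxa_in_dist(dist, pool)
  if (!all(taxa %in% pool))
    stop("observed taxa must be contained in the pool", call. = FALSE)
  k <- length(taxa)
  if (k < 2L) stop("site richness must be >= 2", call. = FALSE)
  fn <- if (metric == "mpd") mpd else mntd
  observed <- fn(dist, taxa)
  pool_idx <- match(pool, rownames(dist))
  dsub <- dist[pool_idx, pool_idx]
  set.seed(seed)
  null <- vapply(seq_len(n_rand), function(i) {
    idx <- sample.int(length(pool_idx), k)
    s <- dsub[idx, idx]
    if (metric == "mpd") {
      sum(s) / (k * (k - 1))
    } else {
      diag(s) <- Inf
      mean(apply(s, 1L, min))
    }
  }, numeric(1))
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  degenerate <- k == length(pool) || null_sd == 0
  z <- if (degenerate) NA_real_ else (observed - null_mean) / null_sd
  r <- rank(c(observed, null), ties.method = "average")[1L]
  p <- min(1, 2 * min(r, n_rand + 1 - r) / (n_rand + 1))
  list(metric = metric, observed = observed, null_mean = null_mean,
       null_sd = null_sd, z = z, p_rank = p, n_rand = n_rand,
       seed = seed, degenerate = degenerate)
}

#' Per-site alpha diversity table (SR, Fam, PD, MPD, MNTD, NRI, NTI)
#'
#' Computes, for every site in a community matrix, species richness, family
#' richness, rooted Faith's PD, MPD, MNTD, and the standardized effect sizes
#' of MPD (NRI) and MNTD (NTI) against the sample-pool null, plus their
#' two-tailed rank p-values. A pooled "Total" row carries the full pool's
#' SR, Fam, PD, MPD and MNTD with the effect sizes left blank (the pool
#' cannot deviate from its own null). Sign orientation: positive NRI/NTI =
#' evenness, negative = clustering (see \code{\link{ses_metric}}).
#'
#' @param tree Chronogram containing every community taxon as a leaf.
#' @param cm Community matrix.
#' @param taxonomy Optional taxon -> family map; when absent the Fam column
#'   is \code{NA}.
#' @param n_rand Randomizations per site (default 999).
#' @param seed Master seed; per-site streams are derived from it.
#' @param pool Null pool (default: all taxa present in at least one site).
#' @return Data frame, one row per site plus a final "Total" row.
#' @export
alpha_table <- function(tree, cm, taxonomy = NULL, n_rand = 999, seed = 1L,
                        pool = NULL) {
  missing <- setdiff(colnames(cm), tree$tip.label)
  if (length(missing))
    stop("community taxa absent from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(pool)) pool <- colnames(cm)[colSums(cm > 0) > 0]
  dist <- patristic_distances(tree)
  sr <- richness(cm)
  fam <- if (!is.null(taxonomy)) family_rollup(cm, taxonomy)$fam
         else stats::setNames(rep(NA_integer_, nrow(cm)), rownames(cm))
  rows <- lapply(rownames(cm), function(site) {
    taxa <- colnames(cm)[cm[site, ] > 0]
    if (length(taxa) == 0L)
      return(data.frame(site = site, sr = 0L, fam = 0L, pd = NA_real_,
                        mpd = NA_real_, nri = NA_real_, p_nri = NA_real_,
                        mntd = NA_real_, nti = NA_real_, p_nti = NA_real_,
                        stringsAsFactors = FALSE))
    pd <- faith_pd(tree, taxa)
    if (length(taxa) >= 2L) {
      s_mpd <- ses_metric("mpd", dist, taxa, pool, n_rand,
                          site_seed(seed, site))
      s_mntd <- ses_metric("mntd", dist, taxa, pool, n_rand,
                           site_seed(seed, paste0(site, "#mntd")))
      mpd_v <- s_mpd$observed; mntd_v <- s_mntd$observed
      nri <- s_mpd$z; p_nri <- s_mpd$p_rank
      nti <- s_mntd$z; p_nti <- s_mntd$p_rank
    } else {
      mpd_v <- mntd_v <- nri <- nti <- p_nri <- p_nti <- NA_real_
    }
    data.frame(site = site, sr = sr[[site]], fam = fam[[site]], pd = pd,
               mpd = mpd_v, nri = nri, p_nri = p_nri, mntd = mntd_v,
               nti = nti, p_nti = p_nti, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  pool_fam <- if (!is.null(taxonomy))
    length(unique(taxonomy[intersect(pool, names(taxonomy))]))
  else NA_integer_
  total <- data.frame(site = "Total", sr = length(pool),
                      fam = as.integer(pool_fam),
                      pd = faith_pd(tree, pool),
                      mpd = mpd(dist, pool), nri = NA_real_,
                      p_nri = NA_real_, mntd = mntd(dist, pool),
                      nti = NA_real_, p_nti = NA_real_,
                      stringsAsFactors = FALSE)
  rbind(tab, total)
}
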