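#' Non-metric multidimensional scaling of a distance matrix
#'
#' Wraps \code{vegan::metaMDS} (global NMDS via \code{monoMDS}, Kruskal
#' stress-1, primary tie treatment) with a deterministic post-processing:
#' the best configuration over \code{n_starts} random starts is centred,
#' rotated to its principal axes, and reflected so the first coordinate of
#' the first site is non-negative. Stress is reported on the 0--1 scale.
#'
#' @param d Symmetric dissimilarity matrix with site ids as dimnames.
#' @param k Number of dimensions, 2 or 3.
#' @param n_starts Random starts (default 20).
#' @param max_iter Iteration cap per start (default 500).
#' @param seed Integer seed; fixed seed gives a reproducible configuration.
#' @return List with \code{points} (sites x k matrix), \code{stress},
#'   \code{k}, \code{n_starts}, \code{converged}, \code{seed}.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 500, seed = 1L) {
  stopifnot(k %in% c(2L, 3L))
  validate_distance_matrix(d)
  if (nrow(d) < k + 2)
    stop("need at least k + 2 sites for a k-dimensional ordination",
         call. = FALSE)
  off <- d[upper.tri(d)]
  degenerate <- max(off) - min(off) <= 1e-12
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(stats::as.dist(d), k = k, try = n_starts,
                   trymax = n_starts, maxit = max_iter, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  ))
  pts <- fit$points
  pts <- scale(pts, center = TRUE, scale = FALSE)
  # principal-axes rotation; reflection fixed per axis by the first site
  rot <- svd(pts)$v
  pts <- pts %*% rot
  for (j in seq_len(ncol(pts))) {
    anchor <- pts[which(abs(pts[, j]) > 1e-12)[1L], j]
    if (!is.na(anchor) && anchor < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("axis", seq_len(k))
  rownames(pts) <- rownames(d)
  if (degenerate)
    warning("all dissimilarities equal: configuration is arbitrary",
            call. = FALSE)
  list(points = pts, stress = fit$stress, k = as.integer(k),
       n_starts = as.integer(n_starts), converged = fit$converged > 0,
       seed = as.integer(seed), degenerate = degenerate)
}
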