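site_taxa_list <- function(cm) {
  lapply(seq_len(nrow(cm)), function(i) colnames(cm)[cm[i, ] > 0])
}

empty_site_matrix <- function(cm) {
  n <- nrow(cm)
  matrix(0, n, n, dimnames = list(rownames(cm), rownames(cm)))
}

#' Between-community mean pairwise phylogenetic distance (Dpw)
#'
#' Dpw(A, B) is the mean patristic distance over all cross pairs i in A,
#' j in B, including taxa shared between the two sites (which contribute
#' zero distances) -- the comdist convention. The matrix diagonal is stored
#' as 0; each site's within-community MPD (the natural diagonal quantity) is
#' attached as the \code{"within"} attribute.
#'
#' @param dist Patristic distance matrix over taxa.
#' @param cm Community matrix.
#' @return Symmetric site x site matrix with zero diagonal.
#' @export
dpw <- function(dist, cm) {
  check_taxa_in_dist(dist, colnames(cm))
  taxa <- site_taxa_list(cm)
  out <- empty_site_matrix(cm)
  n <- nrow(cm)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      if (length(taxa[[a]]) == 0L || length(taxa[[b]]) == 0L) {
        out[a, b] <- out[b, a] <- NA_real_
      } else {
        out[a, b] <- out[b, a] <- mean(dist[taxa[[a]], taxa[[b]]])
      }
    }
  }
  attr(out, "within") <- vapply(taxa, function(tx) {
    if (length(tx) >= 2L) mpd(dist, tx) else NA_real_
  }, numeric(1))
  out
}

#' Between-community mean nearest phylogenetic neighbour distance (Dnn)
#'
#' Dnn(A, B) symmetrizes by averaging the two directed means: for each
#' member of A the distance to its nearest neighbour in B, averaged over A,
#' and vice versa. Shared taxa contribute zero minima, so identical or
#' nested communities score 0 in the corresponding direction.
#'
#' @inheritParams dpw
#' @return Symmetric site x site matrix with zero diagonal.
#' @export
dnn <- function(dist, cm) {
  check_taxa_in_dist(dist, colnames(cm))
  taxa <- site_taxa_list(cm)
  out <- empty_site_matrix(cm)
  n <- nrow(cm)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      ta <- taxa[[a]]; tb <- taxa[[b]]
      if (length(ta) == 0L || length(tb) == 0L) {
        out[a, b] <- out[b, a] <- NA_real_
      } else {
        d_ab <- dist[ta, tb, drop = FALSE]
        to_b <- mean(apply(d_ab, 1L, min))
        to_a <- mean(apply(d_ab, 2L, min))
        out[a, b] <- out[b, a] <- (to_b + to_a) / 2
      }
    }
  }
  out
}

#' Unweighted UniFrac dissimilarity between communities
#'
#' For sites A and B the spanning edge set of each community is taken as in
#' rooted Faith's PD (edges on the paths from the community's taxa to the
#' tree root). UniFrac = (branch length unique to A + unique to B) / branch
#' length of the union's spanning set, so 0 means identical spanning sets
#' and 1 means no shared branches. Equivalently
#' (PD(A) + PD(B) - 2 PD_shared) / PD(A u B).
#'
#' @param tree Chronogram containing every community taxon.
#' @param cm Community matrix.
#' @return Symmetric site x site matrix in [0, 1]; sites with zero taxa get
#'   \code{NA} rows/columns.
#' @export
unifrac <- function(tree, cm) {
  missing <- setdiff(colnames(cm), tree$tip.label)
  if (length(missing))
    stop("community taxa absent from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  taxa <- site_taxa_list(cm)
  # edge incidence per site: does the edge lie on some root path?
  inc <- vapply(taxa, function(tx) {
    if (length(tx) == 0L) rep(NA, nrow(tree$edge))
    else edge_taxon_counts(tree, tx) > 0L
  }, logical(nrow(tree$edge)))
  len <- tree$edge.length
  out <- empty_site_matrix(cm)
  n <- nrow(cm)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      ia <- inc[, a]; ib <- inc[, b]
      if (anyNA(ia) || anyNA(ib)) {
        out[a, b] <- out[b, a] <- NA_real_
      } else {
        union_len <- sum(len[ia | ib])
        uniq <- sum(len[xor(ia, ib)])
        out[a, b] <- out[b, a] <- if (union_len > 0) uniq / union_len else 0
      }
    }
  }
  out
}

#' Bray-Curtis dissimilarity between site rows
#'
#' In binary mode values are reduced to presence/absence and the result is
#' the Sorensen complement 1 - 2|A n B| / (|A| + |B|); in count mode
#' (e.g. site x family abundances) it is sum|x - y| / sum(x + y). Computed
#' with \code{vegan::vegdist}.
#'
#' @param m Site x feature matrix (incidence or counts).
#' @param binary Reduce to presence/absence first (default TRUE).
#' @return Symmetric site x site matrix in [0, 1] (binary mode guarantees
#'   the bound; count mode does too since all values are non-negative).
#' @export
bray_curtis <- function(m, binary = TRUE) {
  if (any(m < 0)) stop("negative values in composition matrix", call. = FALSE)
  d <- vegan::vegdist(m, method = "bray", binary = binary)
  out <- as.matrix(d)
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' Validate a distance matrix
#'
#' @param d Square numeric matrix.
#' @param bounded Require entries in [0, 1].
#' @return \code{d}, invisibly, or an error.
#' @export
validate_distance_matrix <- function(d, bounded = FALSE) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12, na.rm = TRUE))
    stop("distance matrix diagonal is not zero", call. = FALSE)
  if (any(d < 0, na.rm = TRUE))
    stop("negative dissimilarities", call. = FALSE)
  if (bounded && any(d > 1 + 1e-12, na.rm = TRUE))
    stop("dissimilarities exceed 1", call. = FALSE)
  invisible(d)
}

#' Write a distance matrix as square CSV (ids in header row and column)
#'
#' @param d Distance matrix with dimnames.
#' @param file Output path.
#' @export
write_distance_matrix <- function(d, file) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
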