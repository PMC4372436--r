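#' Spearman rank correlation with tie-aware ranks
#'
#' rho is the Pearson correlation of average ranks computed on pairwise
#' complete observations. The two-tailed p-value uses exact permutation
#' enumeration for n <= 9 and the t approximation
#' t = rho sqrt((n-2)/(1-rho^2)) otherwise.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value in
#'   either are dropped.
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (n <= 9L) {
    perms <- permutations_of(n)
    # correlation of rx with every permutation of ry, via the cross sum
    cx <- rx - mean(rx); cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    cyP <- matrix(cy[perms], nrow(perms), n)
    rhos <- as.numeric(cyP %*% cx) / denom
    mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = min(1, p), n = n)
}

#' Enumerate all permutations of 1..n
#'
#' @param n Integer (kept small; n! rows are materialized).
#' @return Integer matrix of n! rows.
#' @keywords internal
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Bonferroni adjustment
#'
#' @param pvals Vector of p-values.
#' @param m Number of tests (default \code{length(pvals)}).
#' @return \code{pmin(1, m * pvals)}.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  pmin(1, m * pvals)
}

#' Mantel-type matrix correlation with Spearman rho (RELATE equivalent)
#'
#' The statistic is the Spearman correlation of the corresponding
#' upper-triangle entries of two distance matrices over the same ids. The
#' null distribution permutes the ids of the second matrix (rows and columns
#' jointly); the one-tailed p-value tests for positive association:
#' p = (count of null rho >= observed + 1) / (n_perm + 1). With
#' \code{exact = TRUE} all n! relabelings are enumerated instead and
#' p = count(rho_perm >= rho_obs) / n! (the identity permutation included).
#'
#' @param d1,d2 Distance matrices with identical id sets (order may differ;
#'   d2 is aligned to d1's ids).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed.
#' @param exact Enumerate all permutations (only sensible for small n).
#' @return List with \code{rho}, \code{p}, \code{n_perm}, \code{seed},
#'   \code{n}.
#' @export
mantel_relate <- function(d1, d2, n_perm = 999, seed = 1L, exact = FALSE) {
  ids <- rownames(d1)
  if (is.null(ids) || is.null(rownames(d2)) ||
      !setequal(ids, rownames(d2)) || length(ids) != nrow(d2))
    stop("distance matrices must share the same id set", call. = FALSE)
  n <- length(ids)
  if (n < 4L) stop("need at least 4 sites", call. = FALSE)
  d2 <- d2[ids, ids]
  ut <- upper.tri(d1)
  rho_of <- function(perm) {
    m2 <- d2[perm, perm]
    stats::cor(d1[ut], m2[ut], method = "spearman")
  }
  rho <- rho_of(seq_len(n))
  if (exact) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, rho_of)
    p <- mean(rhos >= rho - 1e-12)
    n_perm <- nrow(perms)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) rho_of(sample.int(n)),
                   numeric(1))
    p <- (sum(null >= rho - 1e-12) + 1) / (n_perm + 1)
  }
  list(rho = rho, p = p, n_perm = as.integer(n_perm),
       seed = as.integer(seed), n = n)
}

#' Log-log regression of phylogenetic diversity on species richness
#'
#' Ordinary least squares of log10(PD) on log10(SR); base 10 throughout, so
#' the intercept is in log10(PD) units while the slope is base-invariant.
#'
#' @param sr,pd Positive numeric vectors (species richness and Faith's PD
#'   per site), or a data frame with columns \code{sr} and \code{pd} passed
#'   as the first argument.
#' @return List with \code{slope}, \code{intercept}, \code{r2}, \code{n}.
#' @export
loglog_pd_sr <- function(sr, pd = NULL) {
  if (is.data.frame(sr)) {
    pd <- sr$pd
    sr <- sr$sr
  }
  ok <- stats::complete.cases(sr, pd)
  sr <- sr[ok]; pd <- pd[ok]
  if (any(sr <= 0) || any(pd <= 0))
    stop("SR and PD must be positive for the log-log fit", call. = FALSE)
  fit <- stats::lm(log10(pd) ~ log10(sr))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = summary(fit)$r.squared, n = length(sr))
}

#' Diversity-by-attribute Spearman correlation suite
#'
#' Correlates every diversity metric (SR, Fam, PD, MPD, MNTD) against every
#' subregion attribute, on the full site set and again with a configured
#' exclusion list removed (depauperate sites can dominate rank patterns).
#' Missing attribute values are dropped pairwise; Bonferroni adjustment is
#' applied within each subset across all pairs tested.
#'
#' @param alpha Alpha diversity table (\code{\link{alpha_table}} output;
#'   any "Total" row is ignored).
#' @param attrs Attribute data frame (\code{\link{load_attributes}}).
#' @param exclude Character vector of site ids for the second pass
#'   (default none: only the full set is reported).
#' @return Data frame with columns \code{subset, diversity, attribute, n,
#'   rho, p, p_adj}.
#' @export
correlation_suite <- function(alpha, attrs, exclude = character()) {
  alpha <- alpha[alpha$site != "Total", , drop = FALSE]
  merged <- merge(alpha, attrs, by = "site")
  div_cols <- intersect(c("sr", "fam", "pd", "mpd", "mntd"), names(merged))
  attr_cols <- setdiff(attr_fields, "site")
  subsets <- list(all = merged)
  if (length(exclude))
    subsets$excluded <- merged[!(merged$site %in% exclude), , drop = FALSE]
  out <- list()
  for (sub_name in names(subsets)) {
    dat <- subsets[[sub_name]]
    rows <- list()
    for (dv in div_cols) {
      for (at in attr_cols) {
        n_ok <- sum(stats::complete.cases(dat[[dv]], dat[[at]]))
        if (n_ok < 4L) next
        res <- tryCatch(spearman(dat[[dv]], dat[[at]]),
                        warning = function(w) list(rho = NA_real_,
                                                   p = NA_real_, n = n_ok))
        rows[[paste(dv, at)]] <- data.frame(
          subset = sub_name, diversity = dv, attribute = at, n = res$n,
          rho = res$rho, p = res$p, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, c(rows, make.row.names = FALSE))
    tab$p_adj <- bonferroni(tab$p, m = nrow(tab))
    out[[sub_name]] <- tab
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
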