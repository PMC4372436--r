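#' Load a site-by-taxon community matrix from CSV
#'
#' Sites are rows; the first column holds site ids, the header row taxon
#' ids. Cells must be non-negative numbers; any value greater than zero
#' counts as a presence. Zero-sum rows are allowed but reported via a
#' message so empty communities do not pass silently.
#'
#' @param file Path to a CSV file.
#' @return Numeric matrix with site ids as rownames and taxon ids as
#'   colnames.
#' @export
load_community <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("community table must have at least one site and one taxon",
         call. = FALSE)
  sites <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- sites
  validate_community(m)
}

validate_community <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community matrix needs site rownames and taxon colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate site ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(m) || any(!is.finite(m)))
    stop("non-numeric or missing cells in community matrix", call. = FALSE)
  if (any(m < 0)) stop("negative abundances are not allowed", call. = FALSE)
  zero <- rownames(m)[rowSums(m) == 0]
  if (length(zero))
    message("community matrix has zero-sum sites: ",
            paste(zero, collapse = ", "))
  m
}

#' Write a community matrix to CSV
#'
#' @param m Community matrix (sites x taxa).
#' @param file Output path.
#' @export
write_community <- function(m, file) {
  df <- data.frame(site = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Per-site species richness
#'
#' @param m Community matrix.
#' @return Named integer vector: number of taxa with incidence > 0 per site.
#' @export
richness <- function(m) {
  r <- rowSums(m > 0)
  storage.mode(r) <- "integer"
  r
}

#' Load a taxon-to-family taxonomy table
#'
#' @param file CSV with columns \code{taxon,family}.
#' @return Named character vector mapping taxon id to family.
#' @export
load_taxonomy <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "family") %in% names(df)))
    stop("taxonomy CSV must have columns taxon,family", call. = FALSE)
  if (anyDuplicated(df$taxon))
    stop("taxa mapped to more than one family: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "),
         call. = FALSE)
  stats::setNames(as.character(df$family), df$taxon)
}

#' Roll a community matrix up to family composition
#'
#' @param m Community matrix (incidence).
#' @param taxonomy Named character vector: taxon id -> family.
#' @return List with \code{fam} (per-site family richness, integer) and
#'   \code{abundance} (site x family matrix, cell = number of taxa of that
#'   family present at the site).
#' @export
family_rollup <- function(m, taxonomy) {
  unmapped <- setdiff(colnames(m), names(taxonomy))
  if (length(unmapped))
    stop("taxa without a family mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  fam_of <- taxonomy[colnames(m)]
  fams <- sort(unique(fam_of))
  inc <- (m > 0) + 0
  ab <- sapply(fams, function(f) rowSums(inc[, fam_of == f, drop = FALSE]))
  ab <- matrix(ab, nrow = nrow(m),
               dimnames = list(rownames(m), fams))
  fam <- rowSums(ab > 0)
  storage.mode(fam) <- "integer"
  list(fam = fam, abundance = ab)
}

#' Species accumulation curve over sites
#'
#' Sites are taken in decreasing order of richness (ties broken
#' lexicographically by site id, for determinism) and the cumulative pooled
#' richness recorded at each step; the final value equals the richness of
#' the pooled community.
#'
#' @param m Community matrix.
#' @return Data frame with columns \code{site}, \code{sr},
#'   \code{cumulative_sr}.
#' @export
accumulation_curve <- function(m) {
  sr <- richness(m)
  ord <- order(-sr, rownames(m), method = "radix")
  seen <- rep(FALSE, ncol(m))
  cum <- integer(nrow(m))
  for (k in seq_along(ord)) {
    seen <- seen | (m[ord[k], ] > 0)
    cum[k] <- sum(seen)
  }
  data.frame(site = rownames(m)[ord], sr = as.integer(sr[ord]),
             cumulative_sr = cum, row.names = NULL,
             stringsAsFactors = FALSE)
}

attr_fields <- c("site", "area_ha", "pre_rf_ha", "rem_rf_ha", "pct_rem_rf",
                 "pre_rf_pct_sub", "rem_rf_pct_sub", "re_count", "pct_pa",
                 "pct_pa_and_f")

#' Load a per-site attribute table
#'
#' Expects the columns \code{site, area_ha, pre_rf_ha, rem_rf_ha,
#' pct_rem_rf, pre_rf_pct_sub, rem_rf_pct_sub, re_count, pct_pa,
#' pct_pa_and_f}; empty cells and "na" become missing values. Hectare
#' fields must be non-negative and percentages within [0, 100].
#'
#' @param file CSV path.
#' @param check Also run \code{\link{check_attribute_consistency}} and warn
#'   on disagreements (default TRUE).
#' @return Data frame of attributes.
#' @export
load_attributes <- function(file, check = TRUE) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        na.strings = c("NA", "na", ""))
  missing_cols <- setdiff(attr_fields, names(df))
  if (length(missing_cols))
    stop("attribute CSV lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, attr_fields]
  ha <- c("area_ha", "pre_rf_ha", "rem_rf_ha")
  pct <- c("pct_rem_rf", "pre_rf_pct_sub", "rem_rf_pct_sub", "pct_pa",
           "pct_pa_and_f")
  for (f in ha)
    if (any(df[[f]] < 0, na.rm = TRUE))
      stop("negative hectare field: ", f, call. = FALSE)
  for (f in pct)
    if (any(df[[f]] < 0 | df[[f]] > 100, na.rm = TRUE))
      stop("percentage outside [0,100]: ", f, call. = FALSE)
  if (check) {
    bad <- check_attribute_consistency(df)
    if (nrow(bad))
      warning("attribute rows where printed percentage disagrees with the ",
              "recomputed ratio: ",
              paste(unique(bad$site), collapse = ", "), call. = FALSE)
  }
  df
}

#' Check derived percentage columns against their hectare fields
#'
#' Flags any row where a printed percentage and the ratio recomputed from
#' the corresponding numerator/denominator hectare fields disagree by more
#' than 0.01 after rounding to two decimals.
#'
#' @param attrs Attribute data frame (see \code{\link{load_attributes}}).
#' @return Data frame of offending (site, field, printed, recomputed) rows;
#'   zero rows when everything is consistent.
#' @export
check_attribute_consistency <- function(attrs) {
  checks <- list(
    pct_rem_rf     = c("rem_rf_ha", "pre_rf_ha"),
    pre_rf_pct_sub = c("pre_rf_ha", "area_ha"),
    rem_rf_pct_sub = c("rem_rf_ha", "area_ha")
  )
  out <- list()
  for (field in names(checks)) {
    num <- attrs[[checks[[field]][1]]]
    den <- attrs[[checks[[field]][2]]]
    printed <- attrs[[field]]
    ok <- is.na(printed) | is.na(num) | is.na(den) | den == 0
    recomputed <- round(100 * num / den, 2)
    bad <- !ok & abs(printed - recomputed) > 0.01 + 1e-9
    if (any(bad))
      out[[field]] <- data.frame(site = attrs$site[bad], field = field,
                                 printed = printed[bad],
                                 recomputed = recomputed[bad],
                                 stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(site = character(), field = character(),
                  printed = numeric(), recomputed = numeric(),
                  stringsAsFactors = FALSE)
}

#' Sampling coverage of a known flora
#'
#' @param pooled_sr Pooled species richness of the sampled communities.
#' @param flora_size Size of the known flora the sampling targets.
#' @return Coverage in percent (0-100, unrounded).
#' @export
sampling_coverage <- function(pooled_sr, flora_size) {
  stopifnot(flora_size > 0, pooled_sr >= 0)
  100 * pooled_sr / flora_size
}
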