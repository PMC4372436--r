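#' Configuration for a full assessment run
#'
#' @param tree Path to a Newick chronogram.
#' @param communities Path to the site x taxon incidence CSV.
#' @param taxonomy Optional path to the taxon,family CSV.
#' @param attributes Optional path to the per-site attribute CSV.
#' @param re_incidence Optional path to a site x Regional Ecosystem
#'   incidence CSV (same layout as the community matrix).
#' @param n_rand Randomizations for NRI/NTI (>= 99, default 999).
#' @param n_perm Permutations for matrix correlations (>= 99, default 999).
#' @param nmds_dims Ordination dimensionalities (subset of 2:3).
#' @param exclude_sites Site ids dropped in the second-pass analyses.
#' @param seed Master seed; all stage streams derive from it.
#' @param out_dir Output directory (created if absent).
#' @return Validated list of class \code{run_config}.
#' @export
run_config <- function(tree, communities, taxonomy = NULL, attributes = NULL,
                       re_incidence = NULL, n_rand = 999, n_perm = 999,
                       nmds_dims = c(2L, 3L), exclude_sites = character(),
                       seed = 1L, out_dir = "assessment_out") {
  for (f in c(tree, communities, taxonomy, attributes, re_incidence))
    if (!is.null(f) && !file.exists(f))
      stop("input file does not exist: ", f, call. = FALSE)
  if (n_rand < 99 || n_perm < 99)
    stop("n_rand and n_perm must be >= 99", call. = FALSE)
  stopifnot(all(nmds_dims %in% c(2L, 3L)))
  structure(list(tree = tree, communities = communities, taxonomy = taxonomy,
                 attributes = attributes, re_incidence = re_incidence,
                 n_rand = as.integer(n_rand), n_perm = as.integer(n_perm),
                 nmds_dims = as.integer(nmds_dims),
                 exclude_sites = as.character(exclude_sites),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_table_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full bioregional phylodiversity assessment
#'
#' Executes the whole analysis chain over the configured inputs and writes
#' every product to \code{cfg$out_dir}: the per-site alpha diversity table
#' (with NRI/NTI), the species accumulation curve, the log-log PD~SR
#' regression, six dissimilarity matrices (species/family/RE Bray-Curtis,
#' Dpw, Dnn, UniFrac), 2D/3D ordinations of each matrix with and without the
#' excluded sites, a Mantel/RELATE correlation table over all matrix pairs
#' with Bonferroni adjustment, the diversity-by-attribute correlation suite,
#' a conservation-priority report, and a JSON manifest echoing the
#' configuration and seeds. Deterministic under a fixed master seed. A stage
#' failure aborts with a stage-named error and leaves a FAILED marker file.
#'
#' @param cfg A \code{\link{run_config}}.
#' @return Invisibly, a list of the main in-memory products.
#' @export
run_assessment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  log_lines <- character()
  log_stage <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  tree <- stage("load_tree", parse_newick(paste(readLines(cfg$tree),
                                                collapse = "")))
  cm <- stage("load_communities", load_community(cfg$communities))
  taxonomy <- if (!is.null(cfg$taxonomy)) stage("load_taxonomy",
                                                load_taxonomy(cfg$taxonomy))
  attrs <- if (!is.null(cfg$attributes)) stage("load_attributes",
                                               load_attributes(cfg$attributes))
  re_cm <- if (!is.null(cfg$re_incidence)) stage("load_re",
                                                 load_community(cfg$re_incidence))
  log_stage(sprintf("inputs: %d sites, %d taxa", nrow(cm), ncol(cm)))

  alpha <- stage("alpha", alpha_table(tree, cm, taxonomy,
                                      n_rand = cfg$n_rand, seed = cfg$seed))
  write_table_csv(alpha, file.path(cfg$out_dir, "alpha_diversity.csv"))

  acc <- stage("accumulation", accumulation_curve(cm))
  write_table_csv(acc, file.path(cfg$out_dir, "accumulation_curve.csv"))

  sub_alpha <- alpha[alpha$site != "Total", ]
  reg <- stage("regression", loglog_pd_sr(sub_alpha$sr, sub_alpha$pd))
  write_table_csv(as.data.frame(reg),
                  file.path(cfg$out_dir, "loglog_pd_sr.csv"))

  dist <- patristic_distances(tree)
  mats <- list(
    bray_species = stage("bray_species", bray_curtis(cm, binary = TRUE)),
    dpw = stage("dpw", dpw(dist, cm)),
    dnn = stage("dnn", dnn(dist, cm)),
    unifrac = stage("unifrac", unifrac(tree, cm))
  )
  if (!is.null(taxonomy))
    mats$bray_family <- stage("bray_family",
                              bray_curtis(family_rollup(cm, taxonomy)$abundance,
                                          binary = FALSE))
  if (!is.null(re_cm))
    mats$bray_re <- stage("bray_re", bray_curtis(re_cm, binary = TRUE))
  for (nm in names(mats))
    write_distance_matrix(mats[[nm]],
                          file.path(cfg$out_dir, paste0("dist_", nm, ".csv")))
  log_stage(sprintf("dissimilarity matrices: %s",
                    paste(names(mats), collapse = ", ")))

  subsets <- list(all = rownames(cm))
  if (length(cfg$exclude_sites))
    subsets$excluded <- setdiff(rownames(cm), cfg$exclude_sites)
  ord_meta <- list()
  for (nm in names(mats)) {
    for (sub_name in names(subsets)) {
      keep <- subsets[[sub_name]]
      dsub <- mats[[nm]][keep, keep]
      if (anyNA(dsub)) next
      for (k in cfg$nmds_dims) {
        if (nrow(dsub) < k + 2) next
        tag <- paste(nm, sub_name, paste0(k, "d"), sep = "_")
        fit <- stage(paste0("nmds_", tag),
                     nmds(dsub, k = k, seed = site_seed(cfg$seed, tag)))
        write_table_csv(data.frame(site = rownames(fit$points), fit$points,
                                   stringsAsFactors = FALSE),
                        file.path(cfg$out_dir, paste0("nmds_", tag, ".csv")))
        ord_meta[[tag]] <- list(stress = fit$stress, k = k,
                                converged = fit$converged,
                                subset = sub_name, matrix = nm)
      }
    }
  }

  mantel_rows <- list()
  nm_pairs <- utils::combn(names(mats), 2, simplify = FALSE)
  for (pair in nm_pairs) {
    for (sub_name in names(subsets)) {
      keep <- subsets[[sub_name]]
      a <- mats[[pair[1]]][keep, keep]; b <- mats[[pair[2]]][keep, keep]
      if (anyNA(a) || anyNA(b) || length(keep) < 4) next
      res <- stage(paste0("mantel_", pair[1], "_", pair[2]),
                   mantel_relate(a, b, n_perm = cfg$n_perm,
                                 seed = site_seed(cfg$seed,
                                                  paste(pair, collapse = "|"))))
      mantel_rows[[paste(pair[1], pair[2], sub_name)]] <- data.frame(
        matrix_a = pair[1], matrix_b = pair[2], subset = sub_name,
        n = res$n, rho = res$rho, p = res$p, stringsAsFactors = FALSE)
    }
  }
  mantel_tab <- do.call(rbind, c(mantel_rows, make.row.names = FALSE))
  if (!is.null(mantel_tab)) {
    for (sub_name in unique(mantel_tab$subset)) {
      sel <- mantel_tab$subset == sub_name
      mantel_tab$p_adj[sel] <- bonferroni(mantel_tab$p[sel], m = sum(sel))
    }
    write_table_csv(mantel_tab, file.path(cfg$out_dir, "mantel_relate.csv"))
  }

  cor_tab <- NULL
  report <- NULL
  if (!is.null(attrs)) {
    cor_tab <- stage("correlations",
                     correlation_suite(alpha, attrs,
                                       exclude = cfg$exclude_sites))
    write_table_csv(cor_tab, file.path(cfg$out_dir, "correlation_suite.csv"))
    report <- stage("conservation",
                    conservation_report(alpha, attrs,
                                        unifrac_dist = mats$unifrac))
    write_table_csv(report, file.path(cfg$out_dir, "conservation_report.csv"))
    log_stage(sprintf("regional protection-weighted %%PA coverage: %.1f",
                      attr(report, "weighted_pct_pa")))
  }

  manifest <- list(
    config = cfg[c("tree", "communities", "taxonomy", "attributes",
                   "re_incidence", "n_rand", "n_perm", "nmds_dims",
                   "exclude_sites", "seed")],
    ordination = ord_meta,
    regression = reg,
    n_sites = nrow(cm), n_taxa = ncol(cm)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(list(alpha = alpha, matrices = mats, regression = reg,
                 accumulation = acc, mantel = mantel_tab,
                 correlations = cor_tab, conservation = report,
                 ordination = ord_meta))
}

#' Conservation-priority report
#'
#' Ranks sites by Faith's PD and flags as priorities those in the top third
#' of PD rank whose percentage of remnant rainforest under protected-area
#' tenure falls below \code{pa_threshold} (default 17, echoing the CBD Aichi
#' protection target). Also reports the regional protection-weighted
#' coverage, sum(pct_pa * rem_rf_ha) / sum(rem_rf_ha), as the
#' \code{"weighted_pct_pa"} attribute, and -- when a UniFrac matrix is
#' supplied -- each site's phylogenetic distinctiveness as its mean UniFrac
#' distance to all other sites.
#'
#' @param alpha Alpha diversity table (a "Total" row is ignored).
#' @param attrs Attribute data frame.
#' @param pa_threshold Protection threshold in percent (default 17).
#' @param unifrac_dist Optional site UniFrac matrix for distinctiveness.
#' @return Data frame sorted by descending PD with columns \code{site, pd,
#'   pd_rank, pct_pa, distinctiveness, priority}.
#' @export
conservation_report <- function(alpha, attrs, pa_threshold = 17,
                                unifrac_dist = NULL) {
  alpha <- alpha[alpha$site != "Total", , drop = FALSE]
  merged <- merge(alpha[, c("site", "pd")],
                  attrs[, c("site", "pct_pa", "rem_rf_ha")], by = "site")
  merged$pd_rank <- rank(-merged$pd, ties.method = "min")
  top_third <- merged$pd_rank <= ceiling(nrow(merged) / 3)
  merged$priority <- top_third & !is.na(merged$pct_pa) &
    merged$pct_pa < pa_threshold
  merged$distinctiveness <- NA_real_
  if (!is.null(unifrac_dist)) {
    idx <- match(merged$site, rownames(unifrac_dist))
    ok <- !is.na(idx)
    merged$distinctiveness[ok] <- vapply(idx[ok], function(i) {
      mean(unifrac_dist[i, -i])
    }, numeric(1))
  }
  w_ok <- !is.na(merged$pct_pa) & !is.na(merged$rem_rf_ha)
  weighted <- sum(merged$pct_pa[w_ok] * merged$rem_rf_ha[w_ok]) /
    sum(merged$rem_rf_ha[w_ok])
  out <- merged[order(merged$pd_rank),
                c("site", "pd", "pd_rank", "pct_pa", "distinctiveness",
                  "priority")]
  rownames(out) <- NULL
  attr(out, "weighted_pct_pa") <- weighted
  out
}
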