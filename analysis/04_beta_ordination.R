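#!/usr/bin/env Rscript
# Between-subregion structure of the synthetic system: Bray-Curtis (species
# and family), Dpw, Dnn and unweighted UniFrac dissimilarities, NMDS
# ordinations (2D and 3D), and the Mantel/RELATE correlation structure among
# the matrices.
suppressMessages(library(bioregdiv))

indir <- "results/synthetic_data"
out <- "results/beta"
if (!dir.exists(indir)) stop("run analysis/02_simulate_dataset.R first")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tree <- parse_newick(paste(readLines(file.path(indir, "chronogram.nwk")),
                           collapse = ""))
taxonomy <- load_taxonomy(file.path(indir, "taxonomy.csv"))
cm <- load_community(file.path(indir, "communities_random.csv"))
d <- patristic_distances(tree)

mats <- list(
  bray_species = bray_curtis(cm, binary = TRUE),
  bray_family = bray_curtis(family_rollup(cm, taxonomy)$abundance,
                            binary = FALSE),
  dpw = dpw(d, cm),
  dnn = dnn(d, cm),
  unifrac = unifrac(tree, cm))
for (nm in names(mats))
  write_distance_matrix(mats[[nm]], file.path(out, paste0("dist_", nm, ".csv")))

for (nm in names(mats)) {
  for (k in 2:3) {
    fit <- nmds(mats[[nm]], k = k, seed = 11L)
    write.csv(data.frame(site = rownames(fit$points), fit$points),
              file.path(out, sprintf("nmds_%s_%dd.csv", nm, k)),
              row.names = FALSE)
    message(sprintf("NMDS %-13s k=%d stress %.3f", nm, k, fit$stress))
  }
}

pairs <- combn(names(mats), 2, simplify = FALSE)
rows <- lapply(pairs, function(p) {
  r <- mantel_relate(mats[[p[1]]], mats[[p[2]]], n_perm = 999, seed = 13L)
  data.frame(matrix_a = p[1], matrix_b = p[2], rho = r$rho, p = r$p)
})
mant <- do.call(rbind, rows)
mant$p_adj <- bonferroni(mant$p, m = nrow(mant))
write.csv(mant, file.path(out, "mantel_relate.csv"), row.names = FALSE)
message(sprintf("%d of %d matrix pairs significantly correlated after Bonferroni",
                sum(mant$p_adj < 0.05), nrow(mant)))
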