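#!/usr/bin/env Rscript
# Reproduce everything derivable from the published subregional summary
# tables: the log-log PD~SR regression, the rainforest-extent percentages,
# sampling coverage of the known flora, and the conservation report.
suppressMessages(library(bioregdiv))

out <- "results/published_tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tabs <- fixture_tables()
div <- tabs$diversity[tabs$diversity$site != "Total", ]
ext <- tabs$extent

fit <- loglog_pd_sr(div$sr, div$pd)
message(sprintf("log10(PD) ~ log10(SR) over %d subregions: slope %.4f, intercept %.4f, R^2 %.4f",
                fit$n, fit$slope, fit$intercept, fit$r2))
write.csv(as.data.frame(fit), file.path(out, "loglog_pd_sr.csv"),
          row.names = FALSE)

# derived extent percentages recomputed from the hectare fields
derived <- data.frame(
  site = ext$site,
  pct_rem_rf = round(100 * ext$rem_rf_ha / ext$pre_rf_ha, 2),
  pre_rf_pct_sub = round(100 * ext$pre_rf_ha / ext$area_ha, 2),
  rem_rf_pct_sub = round(100 * ext$rem_rf_ha / ext$area_ha, 2))
write.csv(derived, file.path(out, "extent_derived.csv"), row.names = FALSE)
bad <- check_attribute_consistency(ext)
if (nrow(bad)) {
  message("printed percentages that disagree with their hectare fields:")
  print(bad)
  write.csv(bad, file.path(out, "extent_inconsistencies.csv"),
            row.names = FALSE)
}
ok <- !is.na(ext$pre_rf_ha)
message(sprintf("whole-region preclearing rainforest: %.2f%% of %d ha",
                100 * sum(ext$pre_rf_ha[ok]) / sum(ext$area_ha[ok]),
                sum(ext$area_ha)))

pooled <- tabs$diversity$sr[tabs$diversity$site == "Total"]
message(sprintf("sampling coverage: %d of 870 known species = %.0f%%",
                pooled, sampling_coverage(pooled, 870)))

# conservation priorities from the published tables
alpha_pub <- tabs$diversity[, c("site", "pd")]
alpha_pub$site <- gsub("\\.", "_", alpha_pub$site)
report <- conservation_report(alpha_pub, ext)
message(sprintf("remnant-weighted protected-area coverage: %.0f%%",
                attr(report, "weighted_pct_pa")))
message("priority subregions (top-third PD, <17% protected): ",
        paste(report$site[report$priority], collapse = ", "))
write.csv(report, file.path(out, "conservation_report.csv"),
          row.names = FALSE)

# diversity-by-attribute rank correlations, with and without the five
# depauperate outlying subregions
alpha_cols <- tabs$diversity[tabs$diversity$site != "Total",
                             c("site", "sr", "fam", "pd", "mpd", "mntd")]
alpha_cols$site <- gsub("\\.", "_", alpha_cols$site)
suite <- correlation_suite(alpha_cols, ext,
                           exclude = c("12_11", "11_22", "13_1", "13_2",
                                       "13_3"))
write.csv(suite, file.path(out, "correlation_suite.csv"), row.names = FALSE)
sig <- suite[!is.na(suite$p_adj) & suite$p_adj < 0.05, ]
message(sprintf("%d of %d diversity-attribute pairs significant after Bonferroni",
                nrow(sig), nrow(suite)))
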