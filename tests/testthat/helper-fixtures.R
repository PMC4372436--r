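two_site_cm_acc <- function(tree, ta, tb) {
  m <- matrix(0, 2, length(tree$tip.label),
              dimnames = list(c("A", "B"), tree$tip.label))
  m["A", ta] <- 1
  m["B", tb] <- 1
  m
}

write_synth_inputs_acc <- function(dir, n_taxa = 40, n_sites = 8,
                                   seed = 301L) {
  tree <- simulate_bd_tree(n_taxa, 1, 0.2, seed = seed)
  cm <- assemble_communities(tree, n_sites,
                             scenario_spec("random", 10, seed = seed + 1L))
  alpha_min <- data.frame(site = rownames(cm),
                          pd = sapply(rownames(cm), function(s)
                            faith_pd(tree, colnames(cm)[cm[s, ] > 0])),
                          stringsAsFactors = FALSE)
  attrs <- generate_attributes(alpha_min, target_rho = 0.6, seed = seed + 2L)
  tax <- data.frame(taxon = tree$tip.label,
                    family = paste0("F", rep_len(1:6, n_taxa)))
  paths <- list(tree = file.path(dir, "tree.nwk"),
                communities = file.path(dir, "communities.csv"),
                taxonomy = file.path(dir, "taxonomy.csv"),
                attributes = file.path(dir, "attributes.csv"))
  write_newick(tree, paths$tree)
  write_community(cm, paths$communities)
  utils::write.csv(tax, paths$taxonomy, row.names = FALSE)
  utils::write.csv(attrs, paths$attributes, row.names = FALSE)
  paths
}
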