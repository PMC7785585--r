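#!/usr/bin/env Rscript
# Alpha and beta diversity of the dispersal-limitation scenario: rarefy to
# the lowest sample total, compute richness/Shannon/Faith's PD, screen them
# against environmental variables, and ordinate Bray-Curtis and unweighted
# UniFrac distances by PCoA.

library(sedcomm)

seed <- as.integer(Sys.getenv("SEDCOMM_SEED", "1"))
src <- file.path("results", "scenarios", "dispersal_limitation")
out <- file.path("results", "diversity")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

table <- read_otu_table(file.path(src, "otu_table.tsv"))
tree <- read_newick(file.path(src, "otu_tree.nwk"))
meta <- read_metadata(file.path(src, "sample_metadata.tsv"))

depth <- min(rowSums(table))
cat("rarefying to the lowest sample total:", depth, "reads\n")
table_r <- rarefy_table(table, depth, seed = derive_seed(seed, "rarefy"))
write_otu_table(table_r, file.path(out, "otu_table_rarefied.tsv"))

alpha <- alpha_diversity(table_r, tree)
write_tsv_exact <- sedcomm:::write_tsv_exact
write_tsv_exact(alpha, file.path(out, "alpha_diversity.tsv"))
cat(sprintf("alpha diversity: richness %.0f-%.0f, Shannon %.2f-%.2f bits\n",
            min(alpha$richness), max(alpha$richness),
            min(alpha$shannon), max(alpha$shannon)))

screen <- spearman_screen(alpha[, c("richness", "shannon", "pd")],
                          meta[match(alpha$sample_id, meta$sample_id), ],
                          c("sediment_depth", "water_depth",
                            "bottom_temperature", "bottom_salinity",
                            "clay", "silt", "sand", "env"))
write_tsv_exact(screen, file.path(out, "spearman_screen.tsv"))
sig <- screen[!is.na(screen$p_value) & screen$p_value < 0.05, ]
cat("significant alpha-environment correlations (p < 0.05):",
    nrow(sig), "of", nrow(screen), "\n")

bc <- bray_curtis(table_r)
uf <- unweighted_unifrac(table_r, tree)
write_distance_matrix(bc, file.path(out, "bray_curtis.tsv"))
write_distance_matrix(uf, file.path(out, "unweighted_unifrac.tsv"))
for (nm in c("bray_curtis", "unweighted_unifrac")) {
  dm <- if (nm == "bray_curtis") bc else uf
  ord <- pcoa_ordination(dm)
  write_ordination(ord, file.path(out, paste0("pcoa_", nm, ".tsv")))
  cat(sprintf("PCoA (%s): axes 1+2 explain %.1f%% of variation\n", nm,
              100 * sum(ord$proportion_explained[1:2])))
}
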