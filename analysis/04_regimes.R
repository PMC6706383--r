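#!/usr/bin/env Rscript
# Contrasts two deforestation regimes over seeded replicates: scattered
# loss (every patch in a fresh location, clustering_prob = 0) versus
# compact loss (every patch extends the existing loss complex,
# clustering_prob = 1), holding the patch-size distribution fixed.
# Run from the repository root:  Rscript analysis/04_regimes.R

library(forestfrag)

n_rep <- 20
one <- function(cp, seed) {
  scn <- generate_scenario(scenario_config(
    shape = c(96, 96), n_years = 6, patches_per_year = 4,
    clustering_prob = cp, seed = seed))
  mkT <- derive_yearly_masks(scn$layers, 6)
  c(seed = seed, clustering_prob = cp,
    lambda_cum_loss = lacunarity_profile(mkT$cumulative_loss)$aggregate,
    ffi_drop_cover = compute_ffi(scn$layers$cover_baseline)$ffi -
      compute_ffi(mkT$tree_cover)$ffi,
    fresh_patches = sum(scn$truth$per_year$n_fresh))
}
res <- as.data.frame(rbind(
  t(sapply(seq_len(n_rep), function(s) one(0, s))),
  t(sapply(seq_len(n_rep), function(s) one(1, s)))))
dir.create("results", showWarnings = FALSE)
write.csv(res, "results/regime_comparison.csv", row.names = FALSE)

agg <- aggregate(res[c("lambda_cum_loss", "ffi_drop_cover")],
                 by = res["clustering_prob"], FUN = mean)
print(agg, row.names = FALSE)
cat("\nScattered loss (clustering_prob = 0) erodes the tree-cover FFI\n")
cat("faster: punching many separated holes multiplies the perimeter set.\n")
cat("Compact loss (clustering_prob = 1) concentrates the loss mass and so\n")
cat("yields the HIGHER aggregate lacunarity: Lambda(r) = N * sum(p^2) /\n")
cat("(sum p)^2 is a concentration functional, maximal (= N) when all mass\n")
cat("sits in one box.  Per-replicate values: results/regime_comparison.csv\n")
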