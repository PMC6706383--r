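#!/usr/bin/env Rscript
# Runs the yearly fragmentation time series on the scenario produced by
# analysis/02_simulate.R and writes the report tables.
# Run from the repository root:  Rscript analysis/03_timeseries.R

library(forestfrag)

if (!dir.exists("results/scenario")) {
  stop("run analysis/02_simulate.R first (results/scenario missing)")
}
layers <- read_scenario("results/scenario")
rep <- run_timeseries(layers, timeseries_config(seed = 1))
write_report(rep, "results/report")

df <- rep$report
pick <- function(layer, metric) {
  sel <- df$layer == layer & df$metric == metric
  df$value[sel][order(df$year[sel])]
}
cover <- pick("tree_cover", "area_ha")
ffi <- pick("tree_cover", "ffi")
lam <- pick("cumulative_loss", "lambda_aggregate")
cat(sprintf("tree cover: %.1f -> %.1f ha (%.1f%% change)\n",
            cover[1], cover[length(cover)],
            100 * (cover[length(cover)] - cover[1]) / cover[1]))
cat(sprintf("tree-cover FFI: %.3f -> %.3f (fragmentation %s)\n",
            ffi[1], ffi[length(ffi)],
            ifelse(ffi[length(ffi)] < ffi[1], "increased", "decreased")))
cat(sprintf("cumulative-loss lacunarity aggregate: %.2f -> %.2f\n",
            lam[1], lam[length(lam)]))
if (!is.null(rep$spearman)) {
  cat("\nSpearman matrix over", ncol(rep$spearman), "metric series",
      "written to results/report/spearman.csv\n")
}
cat("full long-format table: results/report/report.csv\n")
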