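#!/usr/bin/env Rscript
# Generates the reference synthetic forest-change scenario (three-layer
# stack plus ground truth) used by the downstream analysis steps.
# Run from the repository root:  Rscript analysis/02_simulate.R [seed]

library(forestfrag)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- scenario_config(seed = seed)   # 128x128, 14 years, defaults
scn <- generate_scenario(cfg)
write_scenario(scn, "results/scenario")

px_ha <- cfg$pixel_size_m^2 / 1e4
cat(sprintf("scenario written to results/scenario (seed %d)\n", seed))
cat(sprintf("baseline cover: %d px = %.1f ha (%.1f%% of the scene)\n",
            scn$truth$baseline_px, scn$truth$baseline_px * px_ha,
            100 * scn$truth$baseline_px / prod(cfg$shape)))
cat(sprintf("total loss: %d px over %d years; gain: %d px\n",
            sum(scn$truth$per_year$loss_px), cfg$n_years, scn$truth$gain_px))
print(scn$truth$per_year, row.names = FALSE)
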