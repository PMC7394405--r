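#!/usr/bin/env Rscript
# Stage 1: generate the synthetic field study.
#
# Three cattle camps (low/intermediate/high stocking: 1.7, 1.5, 0.95 ha/AU)
# plus a small cattle-free camp; monthly transect quadrats in two seasons,
# 30 marked grazed swards per camp and a 4-treatment clipping experiment,
# and bite-scale foraging observations for both herbivores.

suppressPackageStartupMessages(library(grazekit))

out_dir <- "results/study"
config <- default_sim_config(seed = 1L)
files <- stage_simulate(config, out_dir)

camps <- read_table(file.path(out_dir, "data", "camps.csv"), "camps")
camps$stocking_ha_au <- NA_real_
stocked <- camps$n_cows + camps$n_heifers > 0
camps$stocking_ha_au[stocked] <- stocking_rate(
  camps$area_ha[stocked], camps$n_cows[stocked], camps$n_heifers[stocked])
print(as.data.frame(camps))

quads <- read_table(file.path(out_dir, "data", "quadrats.csv"), "quadrats")
obs <- read_table(file.path(out_dir, "data", "observations.csv"), "observations")
bites <- read_table(file.path(out_dir, "data", "bites.csv"), "bites")
cat(sprintf("\nGenerated %d quadrats, %d foraging observations, %d bites, %d files.\n",
            nrow(quads), nrow(obs), nrow(bites), length(files)))
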