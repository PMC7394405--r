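#!/usr/bin/env Rscript
# Stage 5: nutritional intake rates.
#
# Per observation: bite rate, dry-matter intake (mean bite mass x bite rate),
# crude-protein intake rate (per-bite CP mass averaged, times bite rate), and
# mass-weighted digestibility of consumed vegetation; then mean +/- SE per
# herbivore x camp x season.

suppressPackageStartupMessages(library(grazekit))

out_dir <- "results/study"
stage_nutrition(out_dir)

summ <- readr::read_csv(file.path(out_dir, "intake_summary.csv"),
                        show_col_types = FALSE)
oribi_cp <- subset(summ, herbivore == "oribi" & metric == "cp_intake_g_min")
cat("Oribi crude-protein intake rate (g CP/min, mean +/- SE):\n")
print(as.data.frame(oribi_cp), digits = 3)

oribi_omd <- subset(summ, herbivore == "oribi" & metric == "mean_omd_pct")
cat("\nOribi digestibility of consumed vegetation (%):\n")
print(as.data.frame(oribi_omd), digits = 3)
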