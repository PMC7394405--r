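#!/usr/bin/env Rscript
# Stage 2: sward structure and greenness availability.
#
# Summarises the transect quadrats per camp x season: mean height, observed
# range, and the CV of sward height (structural heterogeneity), plus the
# availability distribution over the four greenness categories. Expected
# pattern: heights and CVs fall with stocking density, and only the
# high-stocking camp loses very green grass by the dry season.

suppressPackageStartupMessages(library(grazekit))

out_dir <- "results/study"
stage_sward(out_dir)

het <- readr::read_csv(file.path(out_dir, "heterogeneity.csv"),
                       show_col_types = FALSE)
cat("Structural heterogeneity (CV of sward height, %):\n")
print(as.data.frame(het), digits = 3)

avail <- readr::read_csv(file.path(out_dir, "greenness_availability.csv"),
                         show_col_types = FALSE)
green <- subset(avail, greenness4 %in% c("mainly green", "very green"))
green_tot <- aggregate(proportion ~ camp_id + season, green, sum)
cat("\nTotal green availability per camp x season:\n")
print(green_tot, digits = 2)
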