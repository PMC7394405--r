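# grazekit

Quantitative tools for studying foraging interactions between cattle and
small grazing antelope (oribi, *Ourebia ourebi*) on shared rangeland. The
package is aimed at grazing ecologists who want to move beyond "dietary
overlap = competition" and quantify the mechanisms: how stocking density
changes sward structure and greenness availability, how often swards are
actually grazed, and whether those changes show up in the antelope's
nutritional intake.

It implements, as tested and reusable functions:

- **Sward structure** — per camp × season summaries of transect quadrats:
  mean height, range, and structural heterogeneity as the coefficient of
  variation, CV = 100·sd/mean; Walker eight-point greenness classes collapsed
  to four bins and turned into availability distributions.
- **Defoliation–regrowth calibration** — net relative regrowth of a marked
  sward, y = ln(h_final) − ln(h_initial), regressed on the number of
  defoliation events x in a clipping experiment (y = a·x + b), then inverted
  at a camp's observed regrowth to estimate its grazing frequency,
  x̂ = (y − b)/a. Percentage growth is the back-transform 100·(e^y − 1).
- **Diet composition and overlap** — bite-count dietary contributions (pooled
  or per-feeding-station), top-species selection, Schoener's index
  O_jk = 1 − ½·Σ_i |P_ij − P_ik|, and seasonal diet-expansion summaries.
- **Nutritional intake** — per-observation bite rate (bites/min), dry-matter
  intake rate (mean bite mass × bite rate, g/min), crude-protein intake rate
  (mean per-bite CP mass × bite rate, g CP/min) with the species × greenness
  nutrient lookup and its greenness-bin fallback, and mass-weighted
  digestibility of consumed vegetation.
- **Group comparisons** — Gamma GLMs with log link; likelihood-ratio
  chi-square tests against the null model, pairwise Wald contrasts (with
  Holm adjustment reported alongside), the shift transform for negative
  regrowth, and label pooling.
- **A synthetic-data generator** — camps, transects, sward time series and
  foraging observations with the statistical structure the analyses assume,
  so the whole pipeline is testable end to end without any field data.

## Worked example

The central worked computation: invert the clipping-experiment calibration
line at each camp's observed regrowth to estimate grazing frequency.

```r
library(grazekit)
line <- calibration_line(slope = -0.0606, intercept = 0.6502)
invert_grazing_frequency(line, log(1 + c(46, 56, -20) / 100))
#> # A tibble: 3 × 4
#>   regrowth x_continuous x_rounded out_of_domain
#>      <dbl>        <dbl>     <int> <lgl>
#> 1    0.378         4.48         4 FALSE
#> 2    0.445         3.39         3 FALSE
#> 3   -0.223        14.4         14 FALSE
```

Camps with +46% and +56% growth over the 38-day trial were grazed about 4
and 3 times; the densely stocked camp that *lost* 20% of sward height was
grazed about 14 times.

Diet overlap from contribution vectors:

```r
p <- reference_diet("low", "oribi", "wet")    # bundled reference diet table
q <- reference_diet("low", "cattle", "wet")
schoener_overlap(p, q)
#> Schoener overlap: 0.7548 over 13 diet items
```

## The analysis workflow

The numbered scripts under `analysis/` run the full synthetic study; each is
a thin driver over the package functions and writes its tables under
`results/study/`:

```sh
Rscript analysis/01_simulate.R            # generate the synthetic field study
Rscript analysis/02_sward_structure.R     # heterogeneity + greenness availability
Rscript analysis/03_regrowth_calibration.R
Rscript analysis/04_diet_overlap.R
Rscript analysis/05_nutrition_intake.R
Rscript analysis/06_group_comparisons.R   # Gamma GLM tables + run manifest
```

On the default configuration (seed 1) the calibration stage prints

```
Calibration: regrowth = 0.6221 -0.0563 x events (r^2 = 0.875, n = 90)
```

and the inversion recovers each camp's realized grazing frequency to within
one event. `run_all()` performs the same six stages in one call and writes a
JSON manifest of file digests; two runs with the same config and seed are
byte-identical.

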