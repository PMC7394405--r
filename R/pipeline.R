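# End-to-end orchestration of the synthetic study: simulate -> sward ->
# regrowth -> diet -> nutrition -> compare. Stages communicate only via CSV
# files on disk so each is independently runnable and testable; a manifest of
# input/output digests makes runs reproducible and comparable.

data_path <- function(dir, name) file.path(dir, "data", paste0(name, ".csv"))
out_path <- function(dir, name) file.path(dir, paste0(name, ".csv"))

#' Pipeline stage: simulate the synthetic study
#'
#' @param config Simulation configuration.
#' @param dir Run directory; data tables are written under `dir/data/`.
#' @return Character vector of files written.
#' @export
stage_simulate <- function(config, dir) {
  study <- simulate_study(config)
  write_study(study, file.path(dir, "data"))
  list.files(file.path(dir, "data"), full.names = TRUE)
}

#' Pipeline stage: sward structure summaries
#'
#' Heterogeneity (mean/min/max/CV of sward height) and greenness availability
#' per camp x season, from the quadrat table.
#'
#' @param dir Run directory containing `data/quadrats.csv`.
#' @return Character vector of files written.
#' @export
stage_sward <- function(dir) {
  quadrats <- read_table(data_path(dir, "quadrats"), "quadrats")
  het <- heterogeneity(quadrats)
  avail <- greenness_availability(quadrats)
  readr::write_csv(het, out_path(dir, "heterogeneity"), progress = FALSE)
  readr::write_csv(avail, out_path(dir, "greenness_availability"), progress = FALSE)
  c(out_path(dir, "heterogeneity"), out_path(dir, "greenness_availability"))
}

#' Pipeline stage: regrowth calibration and grazing-frequency inversion
#'
#' Computes per-sward net relative regrowth, fits the calibration line to the
#' clipped swards (the zero-clip treatment excluded), inverts it at each
#' grazed camp's mean regrowth, and back-transforms regrowth to percentage
#' growth.
#'
#' @param dir Run directory containing `data/sward_heights.csv` and
#'   `data/defoliations.csv`.
#' @return Character vector of files written.
#' @export
stage_regrowth <- function(dir) {
  heights <- read_table(data_path(dir, "sward_heights"), "sward_heights")
  defol <- read_table(data_path(dir, "defoliations"), "defoliations")
  per_sward <- heights |>
    dplyr::group_by(.data$sward_id, .data$group_id, .data$mode) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      initial_height_cm = dplyr::first(.data$height_cm),
      final_height_cm = dplyr::last(.data$height_cm),
      regrowth = log(dplyr::last(.data$height_cm)) -
        log(dplyr::first(.data$height_cm)),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_growth = pct_growth(.data$regrowth))
  clip_counts <- defol |> dplyr::count(.data$sward_id, name = "n_defoliations")
  clipped <- per_sward |>
    dplyr::filter(.data$mode == "clipped") |>
    dplyr::left_join(clip_counts, by = "sward_id") |>
    dplyr::mutate(n_defoliations = dplyr::coalesce(.data$n_defoliations, 0L)) |>
    dplyr::filter(.data$n_defoliations > 0)
  line <- fit_calibration(clipped$n_defoliations, clipped$regrowth)
  camp_regrowth <- per_sward |>
    dplyr::filter(.data$mode == "grazed") |>
    dplyr::group_by(camp_id = .data$group_id) |>
    dplyr::summarise(n_swards = dplyr::n(),
                     mean_regrowth = mean(.data$regrowth), .groups = "drop")
  inv <- invert_grazing_frequency(line, camp_regrowth$mean_regrowth)
  estimates <- dplyr::bind_cols(
    camp_regrowth,
    inv[c("x_continuous", "x_rounded", "out_of_domain")]
  ) |>
    dplyr::mutate(pct_growth = pct_growth(.data$mean_regrowth))
  readr::write_csv(per_sward, out_path(dir, "sward_regrowth"), progress = FALSE)
  readr::write_csv(
    tibble::tibble(slope = line$slope, intercept = line$intercept,
                   r_squared = line$r_squared, n_points = line$n_points),
    out_path(dir, "calibration"), progress = FALSE)
  readr::write_csv(estimates, out_path(dir, "camp_grazing_estimates"),
                   progress = FALSE)
  c(out_path(dir, "sward_regrowth"), out_path(dir, "calibration"),
    out_path(dir, "camp_grazing_estimates"))
}

bites_with_meta <- function(dir) {
  obs <- read_table(data_path(dir, "observations"), "observations")
  bites <- read_table(data_path(dir, "bites"), "bites")
  dplyr::inner_join(
    bites, obs[c("observation_id", "camp_id", "herbivore", "season")],
    by = "observation_id")
}

#' Pipeline stage: dietary contributions, overlap and seasonal expansion
#'
#' Pooled-scale dietary contributions per herbivore x camp x season,
#' wet-season cattle-antelope Schoener overlap per camp, cross-season overlap
#' (wet cattle vs dry antelope), and the antelope's wet-vs-dry diet
#' expansion.
#'
#' @param dir Run directory containing `data/observations.csv` and
#'   `data/bites.csv`.
#' @param scale Contribution scale, `"pooled"` (default) or `"station"`.
#' @return Character vector of files written.
#' @export
stage_diet <- function(dir, scale = "pooled") {
  bites <- bites_with_meta(dir)
  groups <- bites |>
    dplyr::group_by(.data$herbivore, .data$camp_id, .data$season) |>
    dplyr::group_split()
  diets <- list()
  contrib_rows <- list()
  for (g in groups) {
    key <- paste(g$herbivore[1], g$camp_id[1], g$season[1], sep = "|")
    d <- diet_contributions(g, scale = scale)
    diets[[key]] <- d
    contrib_rows[[key]] <- tibble::tibble(
      herbivore = g$herbivore[1], camp_id = g$camp_id[1], season = g$season[1],
      species = names(d), proportion = as.numeric(d),
      n_bites = attr(d, "n_bites"), scale = scale
    )
  }
  contributions <- dplyr::bind_rows(contrib_rows)
  cattle_camps <- sort(unique(bites$camp_id[bites$herbivore == "cattle"]))
  get_diet <- function(herb, camp, season) {
    diets[[paste(herb, camp, season, sep = "|")]]
  }
  overlap_rows <- lapply(cattle_camps, function(camp) {
    wet <- schoener_overlap(get_diet("cattle", camp, "wet"),
                            get_diet("oribi", camp, "wet"))
    cross <- schoener_overlap(get_diet("cattle", camp, "wet"),
                              get_diet("oribi", camp, "dry"))
    tibble::tibble(
      camp_id = camp,
      overlap_wet_pct = 100 * wet$schoener,
      overlap_cattle_wet_oribi_dry_pct = 100 * cross$schoener
    )
  })
  expansion_rows <- lapply(cattle_camps, function(camp) {
    ex <- diet_expansion(get_diet("oribi", camp, "wet"),
                         get_diet("oribi", camp, "dry"))
    tibble::tibble(
      camp_id = camp,
      overlap_wet_dry_pct = 100 * ex$overlap,
      newly_included = paste(ex$newly_included, collapse = "; "),
      newly_dropped = paste(ex$newly_dropped, collapse = "; ")
    )
  })
  readr::write_csv(contributions, out_path(dir, "diet_contributions"),
                   progress = FALSE)
  readr::write_csv(dplyr::bind_rows(overlap_rows), out_path(dir, "diet_overlap"),
                   progress = FALSE)
  readr::write_csv(dplyr::bind_rows(expansion_rows),
                   out_path(dir, "diet_expansion"), progress = FALSE)
  c(out_path(dir, "diet_contributions"), out_path(dir, "diet_overlap"),
    out_path(dir, "diet_expansion"))
}

#' Pipeline stage: per-observation intake rates and group summaries
#'
#' @param dir Run directory containing `data/observations.csv`,
#'   `data/bites.csv` and `data/nutrients.csv`.
#' @return Character vector of files written.
#' @export
stage_nutrition <- function(dir) {
  nut_path <- data_path(dir, "nutrients")
  if (!file.exists(nut_path)) {
    stop("nutrient table not found: ", nut_path, call. = FALSE)
  }
  obs <- read_table(data_path(dir, "observations"), "observations")
  bites <- read_table(data_path(dir, "bites"), "bites")
  profiles <- read_table(nut_path, "nutrients")
  intake <- observation_intake(obs, bites, profiles)
  summ <- intake_summary(intake)
  readr::write_csv(intake, out_path(dir, "observation_intake"), progress = FALSE)
  readr::write_csv(summ, out_path(dir, "intake_summary"), progress = FALSE)
  c(out_path(dir, "observation_intake"), out_path(dir, "intake_summary"))
}

glm_row <- function(res, response, season, subset) {
  tibble::tibble(
    response = response, season = season, subset = subset,
    lr_chisq = res$lr_chisq, df = res$df, p_value = res$p_value,
    f_stat = res$f_stat, p_value_f = res$p_value_f,
    dispersion = res$dispersion
  )
}

glm_means_rows <- function(res, response, season, subset) {
  tibble::tibble(
    response = response, season = season, subset = subset,
    group = res$levels, mean = as.numeric(res$group_means), n = res$n
  )
}

#' Pipeline stage: Gamma GLM group comparisons
#'
#' The study's suite of Gamma/log-link comparisons: sward height across camps
#' per season (availability and grazed-by-each-herbivore), intake metrics
#' across camps per season, crude protein and digestibility of camps pooled
#' across stocking rates against the cattle-free camp (wet season), grazed
#' regrowth across camps (shift-transformed), and the green-bite diet
#' proportions.
#'
#' @param dir Run directory; requires the simulate, regrowth and nutrition
#'   stage outputs.
#' @return Character vector of files written.
#' @export
stage_compare <- function(dir) {
  quadrats <- read_table(data_path(dir, "quadrats"), "quadrats")
  intake <- readr::read_csv(out_path(dir, "observation_intake"),
                            show_col_types = FALSE, progress = FALSE)
  regrowth <- readr::read_csv(out_path(dir, "sward_regrowth"),
                              show_col_types = FALSE, progress = FALSE)
  bites <- bites_with_meta(dir)

  results <- list()
  means <- list()
  pairwise <- list()
  add <- function(values, groups, response, season, subset) {
    res <- gamma_glm_compare(values, groups, response = response)
    key <- paste(response, season, subset)
    results[[key]] <<- glm_row(res, response, season, subset)
    means[[key]] <<- glm_means_rows(res, response, season, subset)
    if (length(res$levels) >= 3) {
      pw <- pairwise_contrasts(res)
      pw$response <- response; pw$season <- season; pw$subset <- subset
      pairwise[[key]] <<- pw
    }
  }

  for (season in c("wet", "dry")) {
    q <- quadrats[quadrats$season == season, ]
    add(q$sward_height_cm, q$camp_id, "sward_height_available", season, "camps")
  }
  for (herb in unique(bites$herbivore)) {
    for (season in unique(bites$season[bites$herbivore == herb])) {
      b <- bites[bites$herbivore == herb & bites$season == season &
                   bites$camp_id != "none", ]
      if (length(unique(b$camp_id)) >= 2) {
        add(b$sward_height_cm, b$camp_id,
            paste0("sward_height_grazed_", herb), season, "camps")
      }
    }
  }
  oribi <- intake[intake$herbivore == "oribi", ]
  for (season in c("wet", "dry")) {
    oi <- oribi[oribi$season == season & oribi$camp_id != "none", ]
    add(oi$dmi_g_min, oi$camp_id, "dmi_g_min", season, "camps")
    add(oi$cp_intake_g_min, oi$camp_id, "cp_intake_g_min", season, "camps")
    add(oi$mean_omd_pct, oi$camp_id, "omd_pct", season, "camps")
  }
  # grazed camps pooled vs the cattle-free camp (wet season)
  wet_oribi <- oribi[oribi$season == "wet", ]
  if (any(wet_oribi$camp_id == "none")) {
    pooled <- pool_groups(wet_oribi$camp_id,
                          setdiff(unique(wet_oribi$camp_id), "none"),
                          "cattle")
    add(wet_oribi$cp_intake_g_min, pooled, "cp_intake_g_min", "wet",
        "cattle_vs_none")
    add(wet_oribi$mean_omd_pct, pooled, "omd_pct", "wet", "cattle_vs_none")
  }
  grazed <- regrowth[regrowth$mode == "grazed", ]
  sh <- shift_transform(grazed$regrowth)
  pos <- sh$values
  if (any(pos == 0)) pos[pos == 0] <- min(pos[pos > 0]) * 1e-6
  add(pos, grazed$group_id, "regrowth_shifted", "wet", "camps")

  green <- greenness_diet_proportions(
    bites[bites$herbivore == "oribi" & bites$season == "dry", ])

  readr::write_csv(dplyr::bind_rows(results), out_path(dir, "glm_results"),
                   progress = FALSE)
  readr::write_csv(dplyr::bind_rows(means), out_path(dir, "glm_group_means"),
                   progress = FALSE)
  readr::write_csv(dplyr::bind_rows(pairwise),
                   out_path(dir, "glm_pairwise"), progress = FALSE)
  readr::write_csv(green, out_path(dir, "greenness_diet_proportions"),
                   progress = FALSE)
  c(out_path(dir, "glm_results"), out_path(dir, "glm_group_means"),
    out_path(dir, "glm_pairwise"), out_path(dir, "greenness_diet_proportions"))
}

#' Run the full synthetic study end to end
#'
#' Executes simulate -> sward -> regrowth -> diet -> nutrition -> compare
#' under one configuration and seed, writes all stage outputs plus a
#' plain-text report and a JSON run manifest, and returns the manifest. Any
#' stage error aborts the run naming the failing stage. Re-running with the
#' same config and seed reproduces byte-identical outputs.
#'
#' @param config Simulation configuration (default [default_sim_config()]).
#' @param out_dir Output directory, created if needed.
#' @param seed Optional integer overriding `config$seed`.
#' @return The run manifest (list), invisibly.
#' @export
run_all <- function(config = default_sim_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(
    simulate = function() stage_simulate(config, out_dir),
    sward = function() stage_sward(out_dir),
    regrowth = function() stage_regrowth(out_dir),
    diet = function() stage_diet(out_dir),
    nutrition = function() stage_nutrition(out_dir),
    compare = function() stage_compare(out_dir)
  )
  manifest_stages <- list()
  for (nm in names(stages)) {
    files <- tryCatch(
      stages[[nm]](),
      error = function(e) {
        stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    files <- sort(unname(unlist(files)))
    digests <- unname(tools::md5sum(files))
    message("stage '", nm, "': ", length(files), " file(s) written")
    manifest_stages[[nm]] <- list(
      files = basename(files),
      md5 = digests
    )
  }
  write_report(out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("grazekit")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    stages = manifest_stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_report <- function(dir) {
  grab <- function(name) {
    readr::read_csv(out_path(dir, name), show_col_types = FALSE,
                    progress = FALSE)
  }
  lines <- c(
    "Synthetic grazing-study report",
    "==============================",
    "",
    "Sward structural heterogeneity (per camp x season):",
    utils::capture.output(print.data.frame(as.data.frame(grab("heterogeneity")),
                                           digits = 4, row.names = FALSE)),
    "",
    "Defoliation calibration and per-camp grazing-frequency estimates:",
    utils::capture.output(print.data.frame(as.data.frame(grab("calibration")),
                                           digits = 4, row.names = FALSE)),
    utils::capture.output(print.data.frame(
      as.data.frame(grab("camp_grazing_estimates")), digits = 4,
      row.names = FALSE)),
    "",
    "Dietary overlap (Schoener, %):",
    utils::capture.output(print.data.frame(as.data.frame(grab("diet_overlap")),
                                           digits = 4, row.names = FALSE)),
    "",
    "Seasonal diet expansion of oribi:",
    utils::capture.output(print.data.frame(as.data.frame(grab("diet_expansion")),
                                           digits = 4, row.names = FALSE)),
    "",
    "Intake summaries (mean +/- SE per group):",
    utils::capture.output(print.data.frame(as.data.frame(grab("intake_summary")),
                                           digits = 4, row.names = FALSE)),
    "",
    "Gamma GLM comparisons:",
    utils::capture.output(print.data.frame(as.data.frame(grab("glm_results")),
                                           digits = 4, row.names = FALSE))
  )
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(file.path(dir, "report.txt"))
}
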