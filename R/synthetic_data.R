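# Synthetic field study generator: camps, transect quadrats, marked sward
# height series (grazed and clipped), and foraging observations with bite
# records, with the statistical structure the downstream analyses assume.
#
# Distributional choices: Gamma for sward heights (positive, right-skewed,
# parameterised by mean and CV), multinomials for greenness and species
# composition, lognormal bite masses and grazed heights, Gamma bite rates,
# and Poisson-timed grazing events whose rate scales with stocking density.
# Sward growth is proportional (exponential) between defoliation events and
# each event removes a fixed fraction of height, so the net relative regrowth
# ln(final/initial) is exactly linear in the number of events -- the form the
# defoliation calibration assumes.

stage_seed <- function(seed, stage) {
  offsets <- c(transects = 1L, swards_grazed = 2L, swards_clipped = 3L,
               foraging = 4L)
  stopifnot(stage %in% names(offsets))
  (as.integer(seed) %% 1000000L) * 1013L + offsets[[stage]] * 7919L
}

check_multinomial <- function(p, what) {
  if (length(p) == 0) stop("empty multinomial for ", what, call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("probabilities for ", what, " must be non-negative and sum to 1",
         call. = FALSE)
  }
  invisible(p)
}

#' Synthetic nutrient profile table
#'
#' A synthetic stand-in for the study's laboratory forage-quality table
#' (which is not machine-readable): crude protein and organic matter
#' digestibility for the main dietary grasses in each greenness category.
#' Greener grass is richer and more digestible; *Heteropogon contortus* is
#' given distinctly lower quality, matching its role as the low-quality
#' fallback grass.
#'
#' @return Tibble with schema `nutrients`: `species`, `greenness4`,
#'   `cp_pct`, `omd_pct`.
#' @export
synthetic_nutrient_profiles <- function() {
  quality <- c(
    "Hyparrhenia hirta" = 1.05, "Themeda triandra" = 1.05,
    "Paspalum dilatatum" = 1.00, "Setaria nigrirostris" = 0.95,
    "Paspalum scrobiculatum" = 0.95, "Tristachya leucothrix" = 0.90,
    "Pennisetum clandestinum" = 1.10, "Setaria sphacelata var torta" = 0.95,
    "Sporobolus africanus" = 0.85, "Heteropogon contortus" = 0.70
  )
  cp_base <- c("very brown" = 4, "mainly brown" = 6.5,
               "mainly green" = 10, "very green" = 13.5)
  omd_base <- c("very brown" = 42, "mainly brown" = 50,
                "mainly green" = 58, "very green" = 66)
  grid <- expand.grid(species = names(quality), greenness4 = greenness_bins(),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    species = grid$species,
    greenness4 = grid$greenness4,
    cp_pct = round(unname(cp_base[grid$greenness4] * quality[grid$species]), 2),
    omd_pct = round(unname(pmin(100, omd_base[grid$greenness4] *
                                  (0.6 + 0.4 * quality[grid$species]))), 2)
  )
}

#' Default simulation configuration
#'
#' The bundled study conditions: three cattle camps whose stocking rates
#' (1.7, 1.5 and 0.95 ha/AU), sward-height means and CVs, greenness
#' availability, species composition (from [reference_diet_table()]),
#' foraging effort, and grazing-event rates reproduce the structure of the
#' field study, plus a small cattle-free camp used by the antelope only in
#' the wet season. Per-camp grazing-event rates are the calibration-line
#' inversions of the camps' published regrowth (4.48, 3.39 and 14.41 events
#' per 38-day trial).
#'
#' @param seed Integer seed; per-stage substreams are derived from it
#'   deterministically.
#' @return Nested list understood by the `simulate_*()` generators.
#' @export
default_sim_config <- function(seed = 1L) {
  inv <- (c(log(1.46), log(1.56), log(0.80)) - 0.6502) / (-0.0606)
  names(inv) <- c("low", "intermediate", "high")
  wet_avail <- c("very brown" = 0, "mainly brown" = 0.05,
                 "mainly green" = 0.30, "very green" = 0.65)
  dry_avail <- list(
    low = c("very brown" = 0, "mainly brown" = 0.65,
            "mainly green" = 0.25, "very green" = 0.10),
    intermediate = c("very brown" = 0, "mainly brown" = 0.68,
                     "mainly green" = 0.22, "very green" = 0.10),
    high = c("very brown" = 0.10, "mainly brown" = 0.67,
             "mainly green" = 0.23, "very green" = 0)
  )
  vg_only <- c("mainly green" = 0, "very green" = 1)
  dry_green <- list(
    low = c("mainly green" = 0.65, "very green" = 0.35),
    intermediate = c("mainly green" = 0.64, "very green" = 0.36),
    high = c("mainly green" = 0.99, "very green" = 0.01)
  )
  heights <- list(
    low = list(wet = c(mean = 23, cv = 58), dry = c(mean = 34, cv = 53)),
    intermediate = list(wet = c(mean = 24, cv = 55), dry = c(mean = 34, cv = 53)),
    high = list(wet = c(mean = 18, cv = 47), dry = c(mean = 21, cv = 46))
  )
  grazed_h <- list(
    low = list(oribi = c(wet = 12, dry = 20), cattle = c(wet = 11.83)),
    intermediate = list(oribi = c(wet = 13, dry = 20), cattle = c(wet = 11.83)),
    high = list(oribi = c(wet = 18, dry = 17), cattle = c(wet = 11.83))
  )
  n_obs <- list(
    low = list(oribi = c(wet = 14, dry = 26), cattle = c(wet = 10)),
    intermediate = list(oribi = c(wet = 17, dry = 15), cattle = c(wet = 8)),
    high = list(oribi = c(wet = 8, dry = 23), cattle = c(wet = 20))
  )
  areas <- c(low = 119, intermediate = 105, high = 95)
  cows <- c(low = 70, intermediate = 70, high = 100)
  camps <- lapply(c("low", "intermediate", "high"), function(s) {
    list(
      camp_id = s, stocking_label = s,
      area_ha = areas[[s]], n_cows = cows[[s]], n_heifers = 0,
      height = heights[[s]],
      greenness_avail = list(wet = wet_avail, dry = dry_avail[[s]]),
      grazing_events_per_day = inv[[s]] / 38,
      observations = n_obs[[s]],
      diet = list(
        oribi = list(wet = reference_diet(s, "oribi", "wet", normalize = TRUE),
                     dry = reference_diet(s, "oribi", "dry", normalize = TRUE)),
        cattle = list(wet = reference_diet(s, "cattle", "wet", normalize = TRUE))
      ),
      consumed_greenness = list(
        oribi = list(wet = vg_only, dry = dry_green[[s]]),
        cattle = list(wet = vg_only)
      ),
      grazed_height = grazed_h[[s]]
    )
  })
  # cattle-free camp: antelope only, wet season only
  camps <- c(camps, list(list(
    camp_id = "none", stocking_label = "none",
    area_ha = 15, n_cows = 0, n_heifers = 0,
    height = NULL, greenness_avail = NULL, grazing_events_per_day = 0,
    observations = list(oribi = c(wet = 12)),
    diet = list(oribi = list(
      wet = reference_diet("low", "oribi", "wet", normalize = TRUE))),
    consumed_greenness = list(oribi = list(wet = vg_only)),
    grazed_height = list(oribi = c(wet = 14))
  )))
  names(camps) <- vapply(camps, `[[`, "", "camp_id")
  list(
    seed = as.integer(seed),
    camps = camps,
    transects = list(
      months = list(wet = c("Jan", "Feb"), dry = c("Jun", "Jul", "Aug")),
      n_transects = 2, positions_m = seq(50, 1000, by = 50),
      quadrats_per_position = 2
    ),
    swards = list(
      n_per_group = 30, start_height_cm = 8, defoliation_height_cm = 8,
      trial_days = 38, measurement_days = c(seq(0, 36, by = 3), 38),
      growth_rate_per_day = 0.6502 / 38,      # proportional growth, log scale
      defoliation_log_drop = -0.0606,         # per-event change in log height
      regrowth_noise_sd = 0.06,               # sd of measured net regrowth
      clipping_schedules = list(
        "0" = numeric(0),
        "3" = c(3, 17, 31),
        "5" = c(3, 10, 17, 24, 31),
        "10" = c(3, 7, 10, 14, 17, 21, 24, 28, 31, 35)
      )
    ),
    foraging = list(
      bites_per_station = c(oribi = 5, cattle = 10),
      bite_rate = list(oribi = c(shape = 25, rate = 1),
                       cattle = c(shape = 30, rate = 0.75)),
      bite_mass = list(oribi = c(meanlog = log(0.08), sdlog = 0.35),
                       cattle = c(meanlog = log(1.0), sdlog = 0.35)),
      height_sdlog = 0.15
    ),
    nutrients = synthetic_nutrient_profiles()
  )
}

validate_sim_config <- function(config) {
  stopifnot(is.list(config), is.numeric(config$seed))
  sw <- config$swards
  if (sw$growth_rate_per_day <= 0 || sw$regrowth_noise_sd < 0) {
    stop("config error: sward growth rate must be positive and noise sd non-negative",
         call. = FALSE)
  }
  for (nm in names(sw$clipping_schedules)) {
    days <- sw$clipping_schedules[[nm]]
    if (any(days < 0 | days > sw$trial_days)) {
      stop("config error: clipping schedule '", nm, "' has days outside [0, ",
           sw$trial_days, "]", call. = FALSE)
    }
  }
  for (camp in config$camps) {
    if (!is.null(camp$height)) {
      for (season in names(camp$height)) {
        h <- camp$height[[season]]
        if (h[["mean"]] <= 0 || h[["cv"]] <= 0) {
          stop("config error: camp '", camp$camp_id, "' ", season,
               " sward height mean and CV must be positive (CV 0 gives a ",
               "degenerate Gamma)", call. = FALSE)
        }
      }
    }
    if (!is.null(camp$greenness_avail)) {
      for (season in names(camp$greenness_avail)) {
        check_multinomial(camp$greenness_avail[[season]],
                          paste0(camp$camp_id, " ", season, " greenness"))
      }
    }
    for (herb in names(camp$diet)) {
      for (season in names(camp$diet[[herb]])) {
        check_multinomial(camp$diet[[herb]][[season]],
                          paste0(camp$camp_id, " ", herb, " ", season, " diet"))
      }
    }
    if (camp$grazing_events_per_day < 0) {
      stop("config error: negative grazing-event rate for camp '",
           camp$camp_id, "'", call. = FALSE)
    }
  }
  invisible(config)
}

rgamma_mean_cv <- function(n, mean, cv_pct) {
  cv <- cv_pct / 100
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

draw_walker_from_bin <- function(bins) {
  pairs <- list(
    "very brown" = c("0", "1-10"),
    "mainly brown" = c("11-25", "26-50"),
    "mainly green" = c("51-75", "76-90"),
    "very green" = c("91-99", "100")
  )
  vapply(bins, function(b) sample(pairs[[b]], 1), character(1))
}

#' Simulate transect quadrat records
#'
#' Per camp, month and transect: sward heights drawn from a Gamma
#' distribution with the configured seasonal mean and CV, and Walker
#' greenness classes drawn from the configured seasonal four-bin multinomial
#' (split uniformly between the two Walker classes of each bin).
#'
#' @param config Simulation configuration (see [default_sim_config()]).
#' @return Quadrat tibble (schema `quadrats`).
#' @export
simulate_transects <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "transects"))
  tr <- config$transects
  rows <- list()
  for (camp in config$camps) {
    if (is.null(camp$height)) next
    for (season in names(camp$height)) {
      h <- camp$height[[season]]
      p_bins <- camp$greenness_avail[[season]]
      for (month in tr$months[[season]]) {
        for (t in seq_len(tr$n_transects)) {
          n <- length(tr$positions_m) * tr$quadrats_per_position
          bins <- sample(names(p_bins), n, replace = TRUE, prob = p_bins)
          rows[[length(rows) + 1]] <- tibble::tibble(
            camp_id = camp$camp_id,
            season = season,
            month = month,
            transect_id = paste0(month, "_T", t),
            position_m = rep(tr$positions_m, each = tr$quadrats_per_position),
            sward_height_cm = rgamma_mean_cv(n, h[["mean"]], h[["cv"]]),
            greenness_pct_class = draw_walker_from_bin(bins)
          )
        }
      }
    }
  }
  validate_table(dplyr::bind_rows(rows), "quadrats")
}

sward_trajectory <- function(event_days, sw) {
  meas_sd <- sw$regrowth_noise_sd / sqrt(2)
  days <- sw$measurement_days
  n_events <- vapply(days, function(d) sum(event_days <= d), numeric(1))
  log_h <- log(sw$start_height_cm) + sw$growth_rate_per_day * days +
    n_events * sw$defoliation_log_drop +
    stats::rnorm(length(days), sd = meas_sd)
  exp(log_h)
}

#' Simulate marked-sward height series
#'
#' Heights grow proportionally at the configured daily rate between
#' defoliation events; each event removes a fixed fraction of height (the
#' configured log drop), so net relative regrowth is linear in the event
#' count. Measured heights carry multiplicative lognormal noise. In
#' `"clipped"` mode events follow the configured schedules; in `"grazed"`
#' mode each camp's events are a Poisson process at the camp's configured
#' rate over the trial window.
#'
#' @param config Simulation configuration.
#' @param mode `"grazed"` or `"clipped"`.
#' @return List: `heights` (schema `sward_heights`), `defoliations`
#'   (schema `defoliations`; the true event days — known by design in clipped
#'   mode, generator truth in grazed mode), `true_events` (tibble of
#'   per-sward event counts, generator truth for validation).
#' @export
simulate_sward_series <- function(config, mode = c("grazed", "clipped")) {
  mode <- match.arg(mode)
  validate_sim_config(config)
  sw <- config$swards
  set.seed(stage_seed(config$seed,
                      if (mode == "grazed") "swards_grazed" else "swards_clipped"))
  heights <- list()
  defol <- list()
  truth <- list()
  emit <- function(sward_id, group_id, event_days) {
    heights[[length(heights) + 1]] <<- tibble::tibble(
      sward_id = sward_id, group_id = group_id, mode = mode,
      day = sw$measurement_days,
      height_cm = sward_trajectory(event_days, sw)
    )
    if (length(event_days) > 0) {
      defol[[length(defol) + 1]] <<- tibble::tibble(
        sward_id = sward_id, day = event_days
      )
    }
    truth[[length(truth) + 1]] <<- tibble::tibble(
      sward_id = sward_id, group_id = group_id,
      n_events = length(event_days)
    )
  }
  if (mode == "clipped") {
    if (length(sw$clipping_schedules) == 0) {
      stop("clipped mode requires clipping schedules in the config",
           call. = FALSE)
    }
    for (nm in names(sw$clipping_schedules)) {
      schedule <- sw$clipping_schedules[[nm]]
      for (i in seq_len(sw$n_per_group)) {
        emit(sprintf("clip%s_s%02d", nm, i), paste0("clip_", nm), schedule)
      }
    }
  } else {
    grazed_camps <- Filter(function(c) c$grazing_events_per_day > 0,
                           config$camps)
    if (length(grazed_camps) == 0) {
      stop("grazed mode requires at least one camp with a positive ",
           "grazing-event rate", call. = FALSE)
    }
    for (camp in grazed_camps) {
      lambda <- camp$grazing_events_per_day * sw$trial_days
      for (i in seq_len(sw$n_per_group)) {
        n_ev <- stats::rpois(1, lambda)
        event_days <- sort(stats::runif(n_ev, 0, sw$trial_days))
        emit(sprintf("%s_s%02d", camp$camp_id, i), camp$camp_id, event_days)
      }
    }
  }
  list(
    heights = validate_table(dplyr::bind_rows(heights), "sward_heights"),
    defoliations = if (length(defol) > 0) {
      validate_table(dplyr::bind_rows(defol), "defoliations")
    } else {
      tibble::tibble(sward_id = character(0), day = numeric(0))
    },
    true_events = dplyr::bind_rows(truth)
  )
}

#' Simulate foraging observations and bite records
#'
#' Per camp x season x herbivore: the configured number of observations, each
#' spanning five feeding stations. Bite species follow the camp's species
#' multinomial, consumed greenness the herbivore's seasonal greenness
#' multinomial, bite masses are lognormal per herbivore, grazed sward heights
#' lognormal around the camp mean, and total bites with elapsed time are
#' drawn so the bite rate follows the configured Gamma.
#'
#' @param config Simulation configuration.
#' @return List: `observations` (schema `observations`), `bites`
#'   (schema `bites`).
#' @export
simulate_foraging <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "foraging"))
  fo <- config$foraging
  obs_rows <- list()
  bite_rows <- list()
  for (camp in config$camps) {
    for (herb in names(camp$observations)) {
      for (season in names(camp$observations[[herb]])) {
        n_obs <- camp$observations[[herb]][[season]]
        if (n_obs == 0) next
        p_species <- camp$diet[[herb]][[season]]
        check_multinomial(p_species, "species composition")
        p_green <- camp$consumed_greenness[[herb]][[season]]
        h_mean <- camp$grazed_height[[herb]][[season]]
        bm <- fo$bite_mass[[herb]]
        br <- fo$bite_rate[[herb]]
        for (i in seq_len(n_obs)) {
          obs_id <- sprintf("%s_%s_%s_%02d", herb, camp$camp_id, season, i)
          n_per_station <- 1 + stats::rpois(5, fo$bites_per_station[[herb]] - 1)
          n_bites <- sum(n_per_station)
          rate <- stats::rgamma(1, shape = br[["shape"]], rate = br[["rate"]])
          obs_rows[[length(obs_rows) + 1]] <- tibble::tibble(
            observation_id = obs_id, camp_id = camp$camp_id,
            herbivore = herb, season = season,
            total_bites = n_bites, elapsed_min = n_bites / rate
          )
          bite_rows[[length(bite_rows) + 1]] <- tibble::tibble(
            observation_id = obs_id,
            station_index = rep(1:5, times = n_per_station),
            species = sample(names(p_species), n_bites, replace = TRUE,
                             prob = p_species),
            greenness4 = sample(names(p_green), n_bites, replace = TRUE,
                                prob = p_green),
            sward_height_cm = stats::rlnorm(
              n_bites, meanlog = log(h_mean) - fo$height_sdlog^2 / 2,
              sdlog = fo$height_sdlog),
            bite_mass_g = stats::rlnorm(n_bites, meanlog = bm[["meanlog"]],
                                        sdlog = bm[["sdlog"]])
          )
        }
      }
    }
  }
  list(
    observations = validate_table(dplyr::bind_rows(obs_rows), "observations"),
    bites = validate_table(dplyr::bind_rows(bite_rows), "bites")
  )
}

#' Camp configuration table from a simulation config
#'
#' @param config Simulation configuration.
#' @return Camp tibble (schema `camps`); cattle-stocked camps carry season
#'   `"wet"` (the season cattle are present).
#' @export
simulate_camp_table <- function(config) {
  validate_sim_config(config)
  rows <- lapply(config$camps, function(c) {
    tibble::tibble(
      camp_id = c$camp_id, stocking_label = c$stocking_label,
      area_ha = c$area_ha, n_cows = c$n_cows, n_heifers = c$n_heifers,
      season = "wet"
    )
  })
  validate_table(dplyr::bind_rows(rows), "camps")
}

#' Simulate the full synthetic study
#'
#' Runs every generator stage under per-stage substreams of one seed.
#'
#' @param config Simulation configuration (default [default_sim_config()]).
#' @return Named list of tables: `camps`, `quadrats`, `sward_heights`,
#'   `defoliations`, `true_events`, `observations`, `bites`, `nutrients`.
#' @export
simulate_study <- function(config = default_sim_config()) {
  validate_sim_config(config)
  grazed <- simulate_sward_series(config, "grazed")
  clipped <- simulate_sward_series(config, "clipped")
  foraging <- simulate_foraging(config)
  list(
    camps = simulate_camp_table(config),
    quadrats = simulate_transects(config),
    sward_heights = dplyr::bind_rows(grazed$heights, clipped$heights),
    defoliations = dplyr::bind_rows(grazed$defoliations, clipped$defoliations),
    true_events = dplyr::bind_rows(grazed$true_events, clipped$true_events),
    observations = foraging$observations,
    bites = foraging$bites,
    nutrients = if (is.null(config$nutrients)) NULL else
      validate_table(config$nutrients, "nutrients")
  )
}

#' Write a simulated study to CSV files
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schema_of <- c(camps = "camps", quadrats = "quadrats",
                 sward_heights = "sward_heights", defoliations = "defoliations",
                 observations = "observations", bites = "bites",
                 nutrients = "nutrients")
  for (nm in names(schema_of)) {
    if (is.null(study[[nm]])) next
    write_table(study[[nm]], file.path(dir, paste0(nm, ".csv")), schema_of[[nm]])
  }
  # generator truth, kept for validation only
  readr::write_csv(study$true_events, file.path(dir, "true_events.csv"),
                   progress = FALSE)
  invisible(dir)
}
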