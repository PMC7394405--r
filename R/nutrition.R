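# Bite-scale nutrient assignment and per-observation intake rates: bite rate,
# dry-matter intake, crude-protein intake, and digestibility of consumed
# vegetation.

#' Bite rate of a foraging observation
#'
#' Total bites over the five feeding stations divided by the time taken.
#'
#' @param total_bites Bite count (>= 0). Vectorised.
#' @param elapsed_min Elapsed time in minutes (> 0).
#' @return Bites per minute.
#' @export
bite_rate <- function(total_bites, elapsed_min) {
  stopifnot(is.numeric(total_bites), is.numeric(elapsed_min))
  if (any(elapsed_min <= 0)) stop("elapsed time must be positive", call. = FALSE)
  if (any(total_bites < 0)) stop("bite count must be non-negative", call. = FALSE)
  total_bites / elapsed_min
}

#' Dry matter intake rate of a foraging observation
#'
#' Mean bite mass across the observation's bites multiplied by its bite rate.
#'
#' @param bite_mass_g Bite masses (g dry mass) of the observation's bites.
#' @param rate Bite rate in bites/min (see [bite_rate()]).
#' @return Intake rate in g/min.
#' @export
dry_matter_intake <- function(bite_mass_g, rate) {
  if (length(bite_mass_g) == 0) stop("no bite masses recorded", call. = FALSE)
  stopifnot(is.numeric(bite_mass_g), all(bite_mass_g >= 0))
  mean(bite_mass_g) * rate
}

#' Assign nutrient concentrations to bites
#'
#' Each bite gets the crude protein (CP) and organic matter digestibility
#' (OMD) of its species in its greenness category. Bites of species without a
#' profile fall back to the unweighted mean of all profiled species in that
#' greenness category, and are flagged. A greenness category with no profiles
#' at all is an error.
#'
#' @param bites Bite table with `species` and `greenness4` columns.
#' @param profiles Nutrient table (schema `nutrients`): `species`,
#'   `greenness4`, `cp_pct`, `omd_pct`.
#' @return `bites` with `cp_pct`, `omd_pct`, `fallback` columns appended.
#' @export
assign_nutrients <- function(bites, profiles) {
  stopifnot(all(c("species", "greenness4") %in% names(bites)),
            all(c("species", "greenness4", "cp_pct", "omd_pct") %in% names(profiles)))
  if (anyDuplicated(profiles[c("species", "greenness4")]) > 0) {
    stop("duplicate (species, greenness) rows in nutrient table", call. = FALSE)
  }
  bin_means <- profiles |>
    dplyr::group_by(.data$greenness4) |>
    dplyr::summarise(cp_bin = mean(.data$cp_pct), omd_bin = mean(.data$omd_pct),
                     .groups = "drop")
  missing_bins <- setdiff(unique(bites$greenness4), bin_means$greenness4)
  if (length(missing_bins) > 0) {
    stop("no nutrient profiles for greenness categor(ies): ",
         paste(missing_bins, collapse = ", "), call. = FALSE)
  }
  out <- bites |>
    dplyr::left_join(profiles[c("species", "greenness4", "cp_pct", "omd_pct")],
                     by = c("species", "greenness4")) |>
    dplyr::left_join(bin_means, by = "greenness4") |>
    dplyr::mutate(
      fallback = is.na(.data$cp_pct),
      cp_pct = ifelse(.data$fallback, .data$cp_bin, .data$cp_pct),
      omd_pct = ifelse(.data$fallback, .data$omd_bin, .data$omd_pct)
    ) |>
    dplyr::select(-"cp_bin", -"omd_bin")
  out
}

#' Crude protein intake rate of a foraging observation
#'
#' CP mass per bite (CP fraction x bite mass) averaged over the observation's
#' bites, multiplied by the bite rate. Composing per-bite before averaging is
#' deliberate: it differs from mean concentration x mean mass whenever CP and
#' mass covary across bites.
#'
#' @param cp_pct Per-bite CP, percent of dry mass (see [assign_nutrients()]).
#' @param bite_mass_g Per-bite dry mass in g.
#' @param rate Bite rate in bites/min.
#' @return CP intake rate in g CP/min.
#' @export
cp_intake_rate <- function(cp_pct, bite_mass_g, rate) {
  stopifnot(length(cp_pct) == length(bite_mass_g))
  if (length(cp_pct) == 0) stop("no bites", call. = FALSE)
  mean(cp_pct / 100 * bite_mass_g) * rate
}

#' Digestibility of vegetation consumed in an observation
#'
#' Mean OMD (percent) over the observation's bites. The default weights bites
#' by their mass (the digestibility of what was actually ingested); the
#' unweighted per-bite mean is available via `weighted = FALSE`. If all
#' masses are zero the unweighted mean is returned.
#'
#' @param omd_pct Per-bite OMD percent.
#' @param bite_mass_g Per-bite dry mass in g (ignored when
#'   `weighted = FALSE`).
#' @param weighted Mass-weight the mean (default TRUE).
#' @return OMD percent in \[0, 100\].
#' @export
observation_omd <- function(omd_pct, bite_mass_g = NULL, weighted = TRUE) {
  if (length(omd_pct) == 0) stop("no bites", call. = FALSE)
  if (!weighted || is.null(bite_mass_g) || sum(bite_mass_g) == 0) {
    return(mean(omd_pct))
  }
  stopifnot(length(omd_pct) == length(bite_mass_g))
  stats::weighted.mean(omd_pct, bite_mass_g)
}

#' Per-observation intake table
#'
#' Combines observations, their bites and the nutrient table into one row per
#' foraging observation: bite rate, mean bite mass, dry matter intake rate,
#' CP intake rate, OMD of consumed vegetation (mass-weighted and unweighted),
#' an OMD "intake" analogue (g digestible fraction-weighted mass/min), mean
#' grazed sward height, and fallback bookkeeping.
#'
#' @param observations Observation table (schema `observations`).
#' @param bites Bite table (schema `bites`).
#' @param profiles Nutrient table (schema `nutrients`).
#' @return Tibble with one row per observation carrying camp/herbivore/season
#'   metadata and the `ObservationIntake` quantities.
#' @export
observation_intake <- function(observations, bites, profiles) {
  bites_n <- assign_nutrients(bites, profiles)
  per_obs <- bites_n |>
    dplyr::group_by(.data$observation_id) |>
    dplyr::summarise(
      n_bites_recorded = dplyr::n(),
      mean_bite_mass_g = mean(.data$bite_mass_g),
      mean_height_cm = mean(.data$sward_height_cm),
      cp_mass_per_bite_g = mean(.data$cp_pct / 100 * .data$bite_mass_g),
      omd_mass_per_bite_g = mean(.data$omd_pct / 100 * .data$bite_mass_g),
      mean_omd_pct = observation_omd(.data$omd_pct, .data$bite_mass_g),
      mean_omd_pct_unweighted = observation_omd(.data$omd_pct, weighted = FALSE),
      n_fallback_bites = sum(.data$fallback),
      .groups = "drop"
    )
  out <- observations |>
    dplyr::inner_join(per_obs, by = "observation_id") |>
    dplyr::mutate(
      bite_rate_min = bite_rate(.data$total_bites, .data$elapsed_min),
      dmi_g_min = .data$mean_bite_mass_g * .data$bite_rate_min,
      cp_intake_g_min = .data$cp_mass_per_bite_g * .data$bite_rate_min,
      omd_intake_g_min = .data$omd_mass_per_bite_g * .data$bite_rate_min
    ) |>
    dplyr::select(-"cp_mass_per_bite_g", -"omd_mass_per_bite_g")
  dropped <- setdiff(observations$observation_id, out$observation_id)
  if (length(dropped) > 0) {
    warning(length(dropped), " observation(s) had no bite records and were dropped",
            call. = FALSE)
  }
  out
}

#' Group-level intake summaries
#'
#' Mean and standard error of the per-observation intake quantities per
#' herbivore x camp x season.
#'
#' @param intake Output of [observation_intake()].
#' @return Long tibble: grouping columns, `metric`, `mean`, `se`, `n`.
#' @export
intake_summary <- function(intake) {
  metrics <- c("bite_rate_min", "mean_bite_mass_g", "dmi_g_min",
               "cp_intake_g_min", "mean_omd_pct", "mean_height_cm")
  intake |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    dplyr::group_by(.data$herbivore, .data$camp_id, .data$season, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}
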