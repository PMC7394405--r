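# Fixtures built in code: trimmed-down simulation configs and small tables.

# One camp, one season, enough quadrats for law-of-large-numbers checks.
single_camp_config <- function(seed = 7L, mean_cm = 23, cv_pct = 58,
                               n_quadrats = 10000) {
  cfg <- default_sim_config(seed)
  camp <- cfg$camps$low
  camp$height <- list(wet = c(mean = mean_cm, cv = cv_pct))
  camp$greenness_avail <- list(wet = camp$greenness_avail$wet)
  cfg$camps <- list(low = camp)
  cfg$transects$months <- list(wet = "Jan")
  cfg$transects$n_transects <- 1
  cfg$transects$quadrats_per_position <- 2
  cfg$transects$positions_m <- seq_len(n_quadrats / 2)
  cfg
}

# A two-camp foraging-only config with prescribed species multinomials.
two_diet_config <- function(p, q, n_obs = 400, seed = 11L) {
  cfg <- default_sim_config(seed)
  mk <- function(id, probs) {
    list(
      camp_id = id, stocking_label = id, area_ha = 100, n_cows = 50,
      n_heifers = 0, height = NULL, greenness_avail = NULL,
      grazing_events_per_day = 0,
      observations = list(oribi = c(wet = n_obs)),
      diet = list(oribi = list(wet = probs)),
      consumed_greenness = list(oribi = list(
        wet = c("mainly green" = 0, "very green" = 1))),
      grazed_height = list(oribi = c(wet = 12))
    )
  }
  cfg$camps <- list(a = mk("a", p), b = mk("b", q))
  cfg
}

tiny_bites <- function() {
  tibble::tibble(
    observation_id = "obs1",
    station_index = c(1L, 1L, 2L, 2L),
    species = c("A", "A", "B", "A"),
    greenness4 = "very green",
    sward_height_cm = c(10, 12, 11, 9),
    bite_mass_g = c(0.1, 0.2, 0.15, 0.05)
  )
}

tiny_profiles <- function() {
  tibble::tibble(
    species = c("A", "B"),
    greenness4 = "very green",
    cp_pct = c(12, 8),
    omd_pct = c(70, 60)
  )
}
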