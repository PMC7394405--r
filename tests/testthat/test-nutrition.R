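test_that("bite rate divides bites by time", {
  expect_equal(bite_rate(60, 2), 30)
  expect_equal(bite_rate(45, 1.5), 30)
  expect_equal(bite_rate(0, 1), 0)
  expect_error(bite_rate(10, 0), "positive")
})

test_that("dry matter intake is mean bite mass times bite rate", {
  expect_equal(dry_matter_intake(c(0.1, 0.1), 30), 3.0)
  expect_equal(dry_matter_intake(c(0.05, 0.15), 20), 2.0)
  expect_equal(dry_matter_intake(c(0, 0), 25), 0)
  expect_error(dry_matter_intake(numeric(0), 30), "no bite masses")
})

test_that("nutrient assignment matches exactly and falls back to bin means", {
  bites <- tibble::tibble(
    species = c("A", "Z"), greenness4 = "very green",
    bite_mass_g = c(0.1, 0.1), sward_height_cm = 10
  )
  out <- assign_nutrients(bites, tiny_profiles())
  expect_equal(out$cp_pct, c(12, 10))   # Z falls back to mean(12, 8)
  expect_equal(out$fallback, c(FALSE, TRUE))
  bad <- dplyr::mutate(bites, greenness4 = "very brown")
  expect_error(assign_nutrients(bad, tiny_profiles()),
               "no nutrient profiles.*very brown")
  dup <- dplyr::bind_rows(tiny_profiles(), tiny_profiles()[1, ])
  expect_error(assign_nutrients(bites, dup), "duplicate")
})

test_that("CP intake composes per bite then scales by bite rate", {
  expect_equal(cp_intake_rate(10, 0.1, 30), 0.3)
  expect_equal(cp_intake_rate(c(0, 0), c(0.1, 0.2), 30), 0)
  # factorization identity: uniform CP c implies cp_intake = c/100 * dmi
  set.seed(8)
  for (i in 1:10) {
    m <- rlnorm(25, log(0.1), 0.4)
    r <- runif(1, 10, 60)
    cc <- runif(1, 2, 20)
    expect_equal(cp_intake_rate(rep(cc, 25), m, r),
                 cc / 100 * dry_matter_intake(m, r), tolerance = 1e-12)
  }
})

test_that("observation OMD is mass-weighted by default", {
  expect_equal(observation_omd(c(60, 60, 60), c(1, 2, 3)), 60)
  expect_equal(observation_omd(c(50, 70), c(1, 3)), 65)
  expect_equal(observation_omd(c(50, 70), weighted = FALSE), 60)
  expect_equal(observation_omd(c(50, 70), c(0, 0)), 60)  # degenerate weights
})

test_that("observation intake table integrates bites, time and nutrients", {
  obs <- tibble::tibble(
    observation_id = c("obs1", "obs2"), camp_id = "low", herbivore = "oribi",
    season = "wet", total_bites = c(4L, 10L), elapsed_min = c(2, 1)
  )
  expect_warning(observation_intake(obs, tiny_bites(), tiny_profiles()),
                 "no bite records")
  out <- suppressWarnings(observation_intake(obs, tiny_bites(), tiny_profiles()))
  expect_equal(nrow(out), 1)
  expect_equal(out$bite_rate_min, 2)
  expect_equal(out$mean_bite_mass_g, 0.125)
  expect_equal(out$dmi_g_min, 0.25)
  # cp mass per bite: mean(cp/100 * mass); A=12%, B=8%
  cp_bite <- mean(c(12, 12, 8, 12) / 100 * c(0.1, 0.2, 0.15, 0.05))
  expect_equal(out$cp_intake_g_min, cp_bite * 2)
  expect_equal(out$mean_omd_pct,
               weighted.mean(c(70, 70, 60, 70), c(0.1, 0.2, 0.15, 0.05)))
  expect_equal(out$n_fallback_bites, 0L)
})

test_that("simulated CP intake matches its analytic expectation", {
  p <- c("Hyparrhenia hirta" = 0.7, "Heteropogon contortus" = 0.3)
  cfg <- two_diet_config(p, p["Hyparrhenia hirta"] / 0.7, n_obs = 300, seed = 17)
  f <- simulate_foraging(cfg)
  keep <- f$observations$camp_id == "a"
  obs <- f$observations[keep, ]
  bites <- f$bites[f$bites$observation_id %in% obs$observation_id, ]
  intake <- observation_intake(obs, bites, cfg$nutrients)
  prof <- cfg$nutrients[cfg$nutrients$greenness4 == "very green", ]
  cp <- setNames(prof$cp_pct, prof$species)
  bm <- cfg$foraging$bite_mass$oribi
  br <- cfg$foraging$bite_rate$oribi
  expected <- sum(p * cp[names(p)] / 100) *
    exp(bm[["meanlog"]] + bm[["sdlog"]]^2 / 2) *
    br[["shape"]] / br[["rate"]]
  expect_lt(abs(mean(intake$cp_intake_g_min) - expected) / expected, 0.05)
})
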