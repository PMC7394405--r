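test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_study(default_sim_config(5))
  s2 <- simulate_study(default_sim_config(5))
  expect_equal(s1, s2)
  s3 <- simulate_study(default_sim_config(6))
  expect_false(identical(s1$quadrats, s3$quadrats))
})

test_that("generated tables pass their schema validations", {
  study <- simulate_study(default_sim_config(2))
  expect_silent(validate_table(study$quadrats, "quadrats"))
  expect_silent(validate_table(study$bites, "bites"))
  expect_silent(validate_table(study$observations, "observations"))
  expect_silent(validate_table(study$sward_heights, "sward_heights"))
  # every attached bite belongs to an observation and stations are 1..5
  expect_true(all(study$bites$observation_id %in%
                    study$observations$observation_id))
  expect_true(all(study$bites$station_index %in% 1:5))
  # observation invariant: total bites >= attached bite records
  per_obs <- table(study$bites$observation_id)
  expect_true(all(study$observations$total_bites >=
                    per_obs[study$observations$observation_id]))
})

test_that("degenerate height configs are rejected", {
  cfg <- single_camp_config()
  cfg$camps$low$height$wet[["cv"]] <- 0
  expect_error(simulate_transects(cfg), "degenerate Gamma")
  cfg2 <- single_camp_config()
  cfg2$camps$low$height$wet[["mean"]] <- -3
  expect_error(simulate_transects(cfg2), "positive")
  cfg3 <- default_sim_config(1)
  cfg3$swards$clipping_schedules[["5"]] <- c(3, 10, 44)
  expect_error(simulate_sward_series(cfg3, "clipped"), "outside")
  cfg4 <- default_sim_config(1)
  cfg4$camps$low$diet$oribi$wet <- c(a = 0.7, b = 0.6)
  expect_error(simulate_foraging(cfg4), "sum to 1")
})

test_that("noiseless zero-event swards follow the closed-form growth curve", {
  cfg <- default_sim_config(1)
  cfg$swards$regrowth_noise_sd <- 0
  cl <- simulate_sward_series(cfg, "clipped")
  zero <- cl$heights[cl$heights$group_id == "clip_0", ]
  one <- zero[zero$sward_id == zero$sward_id[1], ]
  expect_equal(one$height_cm[one$day == 0], 8)
  expect_equal(one$height_cm[one$day == 38], 8 * exp(0.6502), tolerance = 1e-10)
  expect_equal(relative_regrowth(one), 0.6502, tolerance = 1e-10)
})

test_that("a weekly clipping schedule produces exactly five height drops", {
  cfg <- default_sim_config(1)
  cfg$swards$regrowth_noise_sd <- 0
  cl <- simulate_sward_series(cfg, "clipped")
  five <- cl$heights[cl$heights$group_id == "clip_5", ]
  one <- five[five$sward_id == five$sward_id[1], ]
  one <- one[order(one$day), ]
  drops <- sum(diff(one$height_cm) < 0)
  expect_equal(drops, 5)
  expect_equal(sum(cl$defoliations$sward_id == one$sward_id[1]), 5)
})

test_that("grazed-mode event counts match the configured Poisson rate", {
  cfg <- default_sim_config(19)
  cfg$camps <- cfg$camps["high"]
  cfg$camps$high$grazing_events_per_day <- 14 / 38
  cfg$swards$n_per_group <- 1000
  gr <- simulate_sward_series(cfg, "grazed")
  expect_lt(abs(mean(gr$true_events$n_events) - 14) / 14, 0.05)
})

test_that("foraging respects degenerate species multinomials", {
  p <- c("Hyparrhenia hirta" = 1)
  cfg <- two_diet_config(p, p, n_obs = 5, seed = 23)
  f <- simulate_foraging(cfg)
  expect_true(all(f$bites$species == "Hyparrhenia hirta"))
  d <- diet_contributions(f$bites$species)
  expect_equal(as.numeric(d), 1)
  # five stations per observation
  stations <- tapply(f$bites$station_index, f$bites$observation_id,
                     function(s) sort(unique(s)))
  expect_true(all(vapply(stations, identical, logical(1), 1:5)))
})
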