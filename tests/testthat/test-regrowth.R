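test_that("relative regrowth is the log height ratio", {
  expect_equal(relative_regrowth(c(8, 8)), 0)
  expect_equal(relative_regrowth(c(10, 14.6)), log(1.46))
  expect_equal(relative_regrowth(c(10, 8)), log(0.8))
  # data-frame input is ordered by day, not row order
  s <- tibble::tibble(day = c(38, 0, 19), height_cm = c(14.6, 10, 12))
  expect_equal(relative_regrowth(s), log(1.46))
  expect_error(relative_regrowth(c(10, -2)), "positive")
  expect_error(relative_regrowth(10), "2 time points")
})

test_that("percentage growth back-transform matches the log ratio exactly", {
  expect_equal(pct_growth(0), 0)
  expect_equal(pct_growth(log(1.56)), 56)
  expect_equal(pct_growth(log(0.80)), -20)
  # composition identity: pct_growth(relative_regrowth(s)) = 100*(final/initial - 1)
  set.seed(2)
  for (i in 1:10) {
    h <- runif(2, 5, 40)
    expect_equal(pct_growth(relative_regrowth(h)), 100 * (h[2] / h[1] - 1))
  }
})

test_that("calibration fit recovers an exact line and degenerate cases error", {
  x <- c(3, 5, 10)
  y <- -0.0606 * x + 0.6502
  line <- fit_calibration(x, y)
  expect_equal(line$slope, -0.0606, tolerance = 1e-12)
  expect_equal(line$intercept, 0.6502, tolerance = 1e-12)
  expect_equal(line$r_squared, 1)
  expect_equal(fit_calibration(c(2, 9), c(0.4, 0.1))$r_squared, 1)
  expect_error(fit_calibration(c(5, 5, 5), c(1, 2, 3)), "identical")
  expect_error(fit_calibration(3, 1), "at least 2")
})

test_that("inversion reproduces the published worked example", {
  line <- calibration_line(slope = -0.0606, intercept = 0.6502)
  inv <- invert_grazing_frequency(line, log(c(1.46, 1.56, 0.80)))
  expect_equal(inv$x_rounded, c(4L, 3L, 14L))
  expect_equal(inv$x_continuous, c(4.4845, 3.3913, 14.4116), tolerance = 1e-4)
  expect_false(any(inv$out_of_domain))
  neg <- invert_grazing_frequency(line, 0.9)
  expect_true(neg$out_of_domain)
  expect_error(
    invert_grazing_frequency(calibration_line(0, 0.5), 0.2), "slope")
})

test_that("fit-then-invert is the identity on noiseless lines", {
  set.seed(9)
  for (i in 1:15) {
    slope <- runif(1, -0.2, 0.2)
    if (abs(slope) < 1e-3) slope <- 0.05
    intercept <- runif(1, -1, 1)
    x <- sample(0:20, 6)
    line <- fit_calibration(x, slope * x + intercept)
    x0 <- runif(1, 0, 15)
    inv <- invert_grazing_frequency(line, slope * x0 + intercept)
    expect_equal(inv$x_continuous, x0, tolerance = 1e-8)
  }
})

test_that("shift transform removes negatives and is invertible", {
  s <- shift_transform(c(-0.3, 0.1))
  expect_equal(s$values, c(0.0, 0.4))
  expect_equal(s$constant, 0.3)
  s2 <- shift_transform(c(0.2, 0.5))
  expect_equal(s2$values, c(0.2, 0.5))
  expect_equal(s2$constant, 0)
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(20)
    s <- shift_transform(x)
    expect_gte(min(s$values), 0)
    expect_equal(s$values - s$constant, x)
  }
  expect_error(shift_transform(numeric(0)), "empty")
})

test_that("calibration slope is recovered from noisy simulated clippings", {
  cfg <- default_sim_config(13)
  cl <- simulate_sward_series(cfg, "clipped")
  reg <- cl$heights |>
    dplyr::group_by(sward_id) |>
    dplyr::summarise(y = relative_regrowth(dplyr::pick(day, height_cm)),
                     .groups = "drop")
  counts <- dplyr::count(cl$defoliations, sward_id, name = "k")
  d <- dplyr::inner_join(reg, counts, by = "sward_id")  # drops zero-clip swards
  expect_setequal(unique(d$k), c(3, 5, 10))
  line <- fit_calibration(d$k, d$y)
  true_slope <- cfg$swards$defoliation_log_drop
  expect_lt(abs(line$slope - true_slope) / abs(true_slope), 0.2)
  expect_lt(abs(line$intercept - 0.6502), 0.1)
})
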