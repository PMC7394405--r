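test_that("null data give a near-zero statistic and fitted means equal sample means", {
  v <- c(rgamma(30, 5, 1))
  res <- gamma_glm_compare(c(v, v), rep(c("a", "b"), each = 30))
  expect_lt(res$lr_chisq, 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-6)

  set.seed(12)
  vals <- rgamma(90, 6, 0.5)
  grp <- rep(c("a", "b", "c"), each = 30)
  res2 <- gamma_glm_compare(vals, grp)
  fitted_means <- tapply(fitted(res2$model), grp, unique)
  expect_equal(unname(unlist(fitted_means)),
               unname(tapply(vals, grp, mean)), tolerance = 1e-8)
  expect_equal(res2$df, 2L)
})

test_that("input contract: positivity, group count and sizes", {
  expect_error(gamma_glm_compare(c(-1, 2, 3, 4), rep(c("a", "b"), 2)),
               "shift_transform")
  expect_error(gamma_glm_compare(rgamma(10, 2), rep("a", 10)), "2 groups")
  expect_error(gamma_glm_compare(c(1, 2, 3), c("a", "a", "b")), "at least 2 values")
})

test_that("statistic is invariant to rescaling the response", {
  set.seed(3)
  vals <- rgamma(80, 4, 2)
  grp <- rep(c("a", "b"), each = 40)
  r1 <- gamma_glm_compare(vals, grp)
  r2 <- gamma_glm_compare(vals * 273.5, grp)
  expect_equal(r1$lr_chisq, r2$lr_chisq, tolerance = 1e-8)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
})

test_that("a mean difference of the study's size is detected reliably", {
  # means 18 vs 23 cm, shape 8, n = 200/group
  hits <- vapply(1:100, function(s) {
    set.seed(4000 + s)
    vals <- c(rgamma(200, 8, 8 / 18), rgamma(200, 8, 8 / 23))
    gamma_glm_compare(vals, rep(c("lo", "hi"), each = 200))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pairwise contrasts separate the distinct group", {
  set.seed(77)
  vals <- c(rgamma(60, 8, 8 / 20), rgamma(60, 8, 8 / 20), rgamma(60, 8, 8 / 40))
  grp <- rep(c("a", "b", "c"), each = 60)
  res <- gamma_glm_compare(vals, grp)
  pw <- pairwise_contrasts(res)
  expect_equal(nrow(pw), 3)
  ab <- pw[pw$group_a == "a" & pw$group_b == "b", ]
  expect_gt(ab$p_value, 0.05)
  expect_lt(max(pw$p_value[!(pw$group_a == "a" & pw$group_b == "b")]), 0.05)
  expect_true(all(pw$p_holm >= pw$p_value))

  flat <- gamma_glm_compare(rep(c(1, 2, 3, 4, 5), 3),
                            rep(c("a", "b", "c"), each = 5))
  pw_flat <- pairwise_contrasts(flat)
  expect_equal(pw_flat$p_value, rep(1, 3), tolerance = 1e-8)
  two <- gamma_glm_compare(rgamma(20, 3), rep(c("a", "b"), each = 10))
  expect_error(pairwise_contrasts(two), "3 groups")
})

test_that("pooling relabels without touching values", {
  g <- c("low", "intermediate", "high", "none", "low")
  pooled <- pool_groups(g, c("low", "intermediate", "high"), "cattle")
  expect_equal(pooled, c("cattle", "cattle", "cattle", "none", "cattle"))
  expect_length(pooled, length(g))
  expect_equal(sort(unique(pooled)), c("cattle", "none"))  # 2-level factor
  expect_equal(pool_groups(g, "none", "none"), g)          # identity pool
  expect_error(pool_groups(g, "missing"), "unknown group label")
})

test_that("green-bite diet proportions are per camp over the two green bins", {
  b <- tibble::tibble(
    camp_id = rep(c("high", "low"), c(100, 4)),
    greenness4 = c(rep("mainly green", 99), "very green",
                   rep("very green", 3), "mainly brown")
  )
  gp <- greenness_diet_proportions(b)
  high <- gp[gp$camp_id == "high", ]
  expect_equal(high$proportion[high$greenness4 == "mainly green"], 0.99)
  expect_equal(high$proportion[high$greenness4 == "very green"], 0.01)
  low <- gp[gp$camp_id == "low", ]
  expect_equal(low$proportion[low$greenness4 == "very green"], 1)
  expect_equal(low$proportion[low$greenness4 == "mainly green"], 0)
  sums <- tapply(gp$proportion, gp$camp_id, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_error(greenness_diet_proportions(
    tibble::tibble(camp_id = "x", greenness4 = "very brown")), "no bites")
})
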