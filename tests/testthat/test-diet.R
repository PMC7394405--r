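test_that("diet contributions count bites on the pooled scale", {
  expect_equal(as.numeric(diet_contributions(rep("A", 10))), 1)
  p <- diet_contributions(c(rep("A", 6), rep("B", 4)))
  expect_equal(p[["A"]], 0.6)
  expect_equal(p[["B"]], 0.4)
  expect_equal(attr(p, "n_bites"), 10L)
  expect_error(diet_contributions(character(0)), "no bites")
})

test_that("pooled and station scales diverge with unequal station effort", {
  b <- tibble::tibble(
    species = c(rep("A", 10), rep("B", 2)),
    station_index = c(rep(1L, 10), rep(2L, 2))
  )
  pooled <- diet_contributions(b, scale = "pooled")
  expect_equal(pooled[["A"]], 10 / 12)
  expect_equal(pooled[["B"]], 2 / 12)
  station <- diet_contributions(b, scale = "station")
  expect_equal(station[["A"]], 0.5)
  expect_equal(station[["B"]], 0.5)
  expect_error(diet_contributions(tibble::tibble(species = "A"),
                                  scale = "station"), "station_index")
})

test_that("top-species selection is the smallest sufficient prefix", {
  expect_equal(names(top_species(c(A = 0.95, B = 0.05), 0.9)), "A")
  expect_equal(names(top_species(c(A = 0.5, B = 0.3, C = 0.2, D = 0), 1.0)),
               c("A", "B", "C"))
  # deterministic tie-break by label
  expect_equal(names(top_species(c(Z = 0.4, A = 0.4, M = 0.2), 0.5)),
               c("A", "Z"))
  expect_error(top_species(c(A = 1), 0), "threshold")
})

test_that("six largest contributions exceed 90% of every reference oribi diet", {
  combos <- expand.grid(stocking = c("low", "intermediate", "high"),
                        season = c("wet", "dry"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    p <- reference_diet(combos$stocking[i], "oribi", combos$season[i])
    six <- sum(sort(p, decreasing = TRUE)[1:6], na.rm = TRUE)
    expect_gt(six, 0.9)
  }
  # worked selection on the low/wet column
  sel <- top_species(reference_diet("low", "oribi", "wet"), 0.9)
  expect_equal(names(sel)[1], "Hyparrhenia hirta")
  expect_gt(sum(sel), 0.9)
})

test_that("Schoener overlap matches hand arithmetic and its bounds", {
  expect_equal(schoener_overlap(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5))$schoener, 1)
  expect_equal(schoener_overlap(c(A = 1), c(B = 1))$schoener, 0)
  expect_equal(schoener_overlap(c(A = 0.7, B = 0.3), c(A = 0.3, B = 0.7))$schoener, 0.6)
  expect_error(
    schoener_overlap(
      structure(c(A = 1), scale = "pooled"),
      structure(c(A = 1), scale = "station")),
    "scale mismatch")
})

test_that("Schoener overlap is symmetric, bounded, and zero-padding invariant", {
  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    p <- setNames(as.numeric(rmultinom(1, 100, runif(n1))) / 100, LETTERS[1:n1])
    q <- setNames(as.numeric(rmultinom(1, 100, runif(n2))) / 100,
                  LETTERS[sample(1:10, n2)])
    o1 <- schoener_overlap(p, q)$schoener
    o2 <- schoener_overlap(q, p)$schoener
    expect_equal(o1, o2)
    expect_gte(o1, 0); expect_lte(o1, 1)
    expect_equal(schoener_overlap(p, p)$schoener, 1)
    padded <- c(p, setNames(0, "ZZ"))
    expect_equal(schoener_overlap(padded, q)$schoener, o1)
  }
})

test_that("diet expansion reports overlap and species turnover", {
  same <- diet_expansion(c(A = 0.6, B = 0.4), c(A = 0.6, B = 0.4))
  expect_equal(same$overlap, 1)
  expect_length(same$newly_included, 0)
  expect_length(same$newly_dropped, 0)
  flip <- diet_expansion(c(A = 1), c(B = 1))
  expect_equal(flip$overlap, 0)
  expect_equal(flip$newly_included, "B")
  expect_equal(flip$newly_dropped, "A")
  # in the high-stocking camp the antelope add H. contortus in the dry season
  ex <- diet_expansion(reference_diet("high", "oribi", "wet"),
                       reference_diet("high", "oribi", "dry"))
  expect_true("Heteropogon contortus" %in% ex$newly_included)
})

test_that("overlap of identically-sampled camps approaches 1", {
  p <- c("Hyparrhenia hirta" = 0.6, "Themeda triandra" = 0.4)
  cfg <- two_diet_config(p, p, n_obs = 200, seed = 31)
  f <- simulate_foraging(cfg)
  bites <- dplyr::inner_join(
    f$bites, f$observations[c("observation_id", "camp_id")],
    by = "observation_id")
  da <- diet_contributions(bites$species[bites$camp_id == "a"])
  db <- diet_contributions(bites$species[bites$camp_id == "b"])
  expect_gt(schoener_overlap(da, db)$schoener, 0.97)
})
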