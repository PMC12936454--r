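test_that("productivity arithmetic on a constructed single-crop cycle", {
  cfg <- default_config()
  cfg$crops$WW$cu_per_mg <- 1
  cfg$crops$WW$price <- 200
  cfg$crops$WW$fixed_cost <- 500
  s <- make_seasons("WW", 10, year_index = 1)
  p <- productivity(s, config = cfg)
  expect_equal(p$productivity_mass, 10)
  expect_equal(p$productivity_energy, 10)
  expect_equal(p$productivity_econ, 10 * 200 - 500)

  # empty season list: no cycles, empty table
  p0 <- productivity(s[0, ], config = cfg)
  expect_equal(nrow(p0), 0)

  # missing value-table entry
  s2 <- make_seasons("XX", 1)
  expect_error(productivity(s2, config = cfg), "no value-table entry")
})

test_that("zero livestock output leaves productivity unchanged", {
  sim <- simulate_region(2, scenarios = "historical", rotations = "ICLS",
                         n_years = 8, seed = 5)
  lv0 <- sheep_production(
    dplyr::mutate(feed_supply(sim$seasons), dm_intake = 0))
  no_lv <- productivity(sim$seasons)
  with_lv0 <- productivity(sim$seasons, lv0)
  expect_equal(with_lv0, no_lv)
  # and real intake adds to all three metrics
  lv <- sheep_production(feed_supply(sim$seasons))
  with_lv <- productivity(sim$seasons, lv)
  expect_true(all(with_lv$productivity_mass >= no_lv$productivity_mass))
  expect_true(any(with_lv$productivity_econ > no_lv$productivity_econ))
})

test_that("stability is mu/sigma with flags and scale invariance", {
  st <- stability(c(10, 12, 14))
  expect_equal(st$mu, 12)
  expect_equal(st$sigma, 2)
  expect_equal(st$stability, 6)
  expect_true(st$defined)

  const <- stability(c(7, 7, 7))
  expect_false(const$defined)
  expect_true(is.na(const$stability))

  # scaling by k > 0 leaves stability unchanged
  for (k in c(0.1, 3, 1000)) {
    expect_equal(stability(k * c(10, 12, 14))$stability, 6)
  }
  expect_error(stability(5), "two rotation cycles")
})

test_that("yield standardization is a within-group z-score x 100", {
  w <- tibble::tibble(uid = "S1", scenario = "historical",
                      yield = c(6, 8, 10))
  z <- standardize_yields(w)
  expect_equal(z$std_yield, c(-100, 0, 100))
  expect_equal(mean(z$std_yield), 0)

  # all-equal yields are flagged, not divided by zero
  w2 <- tibble::tibble(uid = "S1", scenario = "historical", yield = rep(5, 4))
  z2 <- standardize_yields(w2)
  expect_true(all(!z2$std_defined))
  expect_true(all(is.na(z2$std_yield)))

  # groups standardize independently
  w3 <- dplyr::bind_rows(
    tibble::tibble(uid = "S1", scenario = "historical", yield = c(6, 8, 10)),
    tibble::tibble(uid = "S2", scenario = "historical", yield = c(60, 80, 100))
  )
  z3 <- standardize_yields(w3)
  expect_equal(z3$std_yield[z3$uid == "S1"], z3$std_yield[z3$uid == "S2"])
})

test_that("resistance is the reciprocal absolute deviation from normal-year mean", {
  wheat <- tibble::tibble(
    uid = "S1", scenario = "historical", rotation = "BAU",
    std_yield = c(-10, 0, 10, 25, -0.5, 0.5),
    label = factor(c("normal", "normal", "normal", "extreme_wet",
                     "moderate_dry", "moderate_wet"),
                   levels = levels(agrocycle:::event_label(0, c(q10 = -1, q25 = -0.5,
                                                                q75 = 0.5, q90 = 1))))
  )
  r <- resistance(wheat)
  expect_equal(r$y_normal_mean, rep(0, 3))
  # Ye = 25 vs normal mean 0: omega = 1/25
  expect_equal(r$omega[r$label == "extreme_wet"], 0.04)
  # symmetric deviations give equal omega
  expect_equal(r$omega[r$label == "moderate_dry"],
               r$omega[r$label == "moderate_wet"])
  expect_equal(r$omega[r$label == "moderate_dry"], 2)

  # doubling the deviation halves omega
  wheat2 <- wheat
  wheat2$std_yield[4] <- 50
  r2 <- resistance(wheat2)
  expect_equal(r2$omega[r2$label == "extreme_wet"],
               r$omega[r$label == "extreme_wet"] / 2)

  # no normal seasons: error
  wheat3 <- wheat
  wheat3$label[1:3] <- "extreme_dry"
  expect_error(resistance(wheat3), "no normal seasons")

  # degenerate deviation: capped at 1/eps and flagged
  wheat4 <- wheat
  wheat4$std_yield[4] <- 1e-9
  r4 <- resistance(wheat4)
  expect_true(r4$capped[r4$label == "extreme_wet"])
  expect_equal(r4$omega[r4$label == "extreme_wet"], 1e6)
})

test_that("the omega2 variant folds in the normal-year level", {
  wheat <- tibble::tibble(
    uid = "S1", scenario = "historical", rotation = "BAU",
    std_yield = c(10, 20, 30, 45),
    label = factor(c("normal", "normal", "normal", "extreme_wet"),
                   levels = c("extreme_dry", "moderate_dry", "normal",
                              "moderate_wet", "extreme_wet"))
  )
  r1 <- resistance(wheat)
  r2 <- resistance(wheat, use_omega2 = TRUE)
  expect_equal(r1$omega, 1 / 25)
  expect_equal(r2$omega, 20 / 25)
})

test_that("multi-criteria normalization sets BAU to 100 (or -100) and is idempotent", {
  panel <- tibble::tibble(
    criterion = rep(c("ghg", "soc"), each = 3),
    rotation = rep(c("BAU", "Vegan", "ICLS"), 2),
    value = c(2.6, 1.6, 1.3, -0.1, 0.05, 0.3)
  )
  n1 <- multicriteria_normalize(panel)
  expect_equal(n1$index[n1$criterion == "ghg" & n1$rotation == "BAU"], 100)
  expect_equal(n1$index[n1$criterion == "ghg" & n1$rotation == "ICLS"],
               1.3 / 2.6 * 100)
  # SOC sign-preserving rule: BAU = -100, sequestering rotations positive
  expect_equal(n1$index[n1$criterion == "soc" & n1$rotation == "BAU"], -100)
  expect_equal(n1$index[n1$criterion == "soc" & n1$rotation == "ICLS"], 300)

  # a half-of-BAU criterion indexes at 50
  expect_equal(multicriteria_normalize(
    tibble::tibble(criterion = "x", rotation = c("BAU", "ICLS"),
                   value = c(4, 2)))$index, c(100, 50))

  # idempotence: renormalizing the normalized panel is a no-op
  n2 <- multicriteria_normalize(
    dplyr::select(n1, "criterion", "rotation", value = "index"))
  expect_equal(n2$index, n1$index)

  expect_error(multicriteria_normalize(
    tibble::tibble(criterion = "x", rotation = c("BAU", "ICLS"),
                   value = c(0, 1))), "zero")
})

test_that("the yield-evolution estimator recovers configured shifts exactly without noise", {
  cfg <- deterministic_config()
  sim <- simulate_region(2, scenarios = c("historical", "plus4"),
                         rotations = c("BAU", "Vegan"), n_years = 8, seed = 2,
                         config = cfg)
  ye <- yield_evolution(sim$seasons)
  for (cr in c("SB", "WW", "PT", "RS")) {
    expect_equal(
      ye$change_pct[ye$crop == cr & ye$scenario == "plus4"],
      (cfg$yield_multipliers[[cr]][["4"]] - 1) * 100,
      tolerance = 1e-9, info = cr)
  }
  expect_error(yield_evolution(dplyr::filter(sim$seasons, scenario == "plus4")),
               "reference scenario")
})
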