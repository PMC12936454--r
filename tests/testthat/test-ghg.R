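test_that("soil CO2 term converts and sign-flips the SOC change", {
  expect_equal(soil_co2(rep(0, 24)), 0)
  # steady sequestration of 0.3 Mg C/ha/yr: -1.10 Mg CO2/ha/yr
  expect_equal(soil_co2(rep(0.3, 24)), -0.3 * 44 / 12)
  expect_equal(soil_co2(rep(0.3, 24)), -1.1, tolerance = 1e-3)
  # steady loss of 0.23 Mg C/ha/yr: +0.843 Mg CO2/ha/yr
  expect_equal(soil_co2(rep(-0.23, 24)), 0.23 * 44 / 12)
  expect_equal(soil_co2(rep(-0.23, 24)), 0.843, tolerance = 1e-3)
  expect_error(soil_co2(rep(0, 10), n_years = 24), "length")
})

test_that("indirect N2O applies 0.75% to leached and 0.1% to applied N", {
  expect_equal(indirect_n2o(0, 0), 0)
  expect_equal(indirect_n2o(100, 0), 0.75)
  expect_equal(indirect_n2o(0, 200), 0.2)
  expect_equal(indirect_n2o(40, 160), 0.0075 * 40 + 0.001 * 160)
  expect_error(indirect_n2o(-1, 0), "non-negative")
})

test_that("management CO2 follows the printed fuel and carbon factors", {
  expect_equal(management_co2(0, 0, 0), 0)
  expect_equal(management_co2(1, 0, 0), 20.5 * 0.81 * 3.67)
  expect_equal(management_co2(1, 0, 0), 60.94, tolerance = 1e-3)
  expect_equal(management_co2(0, 1, 2), (27.6 + 2 * 5.6) * 0.81 * 3.67)
  expect_equal(management_co2(0, 1, 2), 115.34, tolerance = 1e-3)
  # vectorized over operation counts
  expect_equal(management_co2(c(1, 0), c(0, 1), c(0, 2)),
               c(20.5, 38.8) * 0.81 * 3.67)
})

test_that("fertilizer CO2 is 6.17 kg CO2-eq per kg N", {
  expect_equal(fertilizer_co2(0), 0)
  expect_equal(fertilizer_co2(1), 6.17)
  expect_equal(fertilizer_co2(160), 987.2)
  expect_error(fertilizer_co2(-5), "non-negative")
})

test_that("GWP* closed forms: constant, pulse and zero series", {
  gwp <- default_config()$gwp
  expect_equal(gwp_star_series(rep(0, 24)), rep(0, 24))
  # constant emission rate: every year 0.25 x GWP100 x E
  e <- gwp_star_series(rep(10, 24))
  expect_equal(e, rep(0.25 * gwp$gwp100_ch4 * 10, 24))
  # a fresh pulse against a zero history: 4 x GWP100 x E at the pulse year
  series <- c(rep(0, 21), 5, 0, 0)
  expect_equal(gwp_star_series(series)[22], 4 * gwp$gwp100_ch4 * 5)
  # rate-change structure: a decline in rate is negative warming-equivalent
  decl <- gwp_star_series(c(rep(10, 21), rep(0, 3)))
  expect_lt(decl[22], 0)
})

test_that("budget assembly composes the terms and nets them exactly", {
  zero <- assemble_budget(make_seasons("WW", rep(1, 24)), make_soc(24),
                          metric = "GWP100")
  terms <- c("co2_soil", "co2_fertilizer", "co2_management", "n2o_direct",
             "n2o_indirect", "ch4_total", "manure_n2o")
  expect_equal(unlist(zero[terms]), rlang::set_names(rep(0, 7), terms))
  expect_equal(zero$net, 0)

  # fertilizer only: 100 kg N/yr -> 0.617 Mg CO2-eq plus its indirect N2O
  fert <- assemble_budget(make_seasons("WW", rep(1, 24), n_fertilizer = 100),
                          make_soc(24), metric = "GWP100")
  expect_equal(fert$co2_fertilizer, 0.617)
  gwp <- default_config()$gwp
  expect_equal(fert$n2o_indirect, 0.001 * 100 * 44 / 28 * gwp$gwp100_n2o / 1000)
  expect_equal(fert$net, fert$co2_fertilizer + fert$n2o_indirect)
  expect_equal(unlist(fert[setdiff(terms, c("co2_fertilizer", "n2o_indirect"))]),
               rlang::set_names(rep(0, 5),
                                setdiff(terms, c("co2_fertilizer", "n2o_indirect"))))
})

test_that("budget terms are additive across independent sources", {
  s_fert <- make_seasons("WW", rep(1, 24), n_fertilizer = 120)
  s_leach <- make_seasons("WW", rep(1, 24), no3_leached = 8)
  s_ops <- make_seasons("WW", rep(1, 24), n_combine = 1, n_plough = 1)
  s_all <- make_seasons("WW", rep(1, 24), n_fertilizer = 120, no3_leached = 8,
                        n_combine = 1, n_plough = 1)
  soc0 <- make_soc(24)
  terms <- c("co2_soil", "co2_fertilizer", "co2_management", "n2o_direct",
             "n2o_indirect", "ch4_total", "manure_n2o", "net")
  b <- lapply(list(s_fert, s_leach, s_ops, s_all),
              function(s) assemble_budget(s, soc0, metric = "GWP100"))
  for (tm in terms) {
    expect_equal(b[[4]][[tm]], b[[1]][[tm]] + b[[2]][[tm]] + b[[3]][[tm]],
                 info = tm)
  }
})

test_that("net equals the sum of the seven terms on simulated data", {
  sim <- simulate_region(3, scenarios = "historical", n_years = 8, seed = 8)
  lv <- sheep_production(feed_supply(sim$seasons))
  for (m in c("GWP100", "GWPstar")) {
    b <- assemble_budget(sim$seasons, sim$soc, lv, metric = m)
    expect_equal(b$net,
                 b$co2_soil + b$co2_fertilizer + b$co2_management +
                   b$n2o_direct + b$n2o_indirect + b$ch4_total + b$manure_n2o,
                 tolerance = 1e-9, info = m)
    # soil CO2 is the only term allowed to be negative
    expect_true(all(b$co2_fertilizer >= 0 & b$co2_management >= 0 &
                      b$n2o_direct >= 0 & b$n2o_indirect >= 0 &
                      b$manure_n2o >= 0), info = m)
  }
})

test_that("a stable CH4 source shrinks under GWP* but keeps the ranking", {
  sim <- simulate_region(4, scenarios = "historical", n_years = 24, seed = 9)
  lv <- sheep_production(feed_supply(sim$seasons))
  b100 <- assemble_budget(sim$seasons, sim$soc, lv, metric = "GWP100")
  bstar <- assemble_budget(sim$seasons, sim$soc, lv, metric = "GWPstar")
  icls100 <- b100[b100$rotation == "ICLS", ]
  iclsstar <- bstar[bstar$rotation == "ICLS", ]
  # CH4 > 0: the warming-equivalent term is smaller than the GWP100 term
  expect_true(all(iclsstar$ch4_total < icls100$ch4_total))
  expect_true(all(iclsstar$net < icls100$net))
  # and the scenario ranking is metric-invariant under the defaults
  rank100 <- tapply(b100$net, b100$rotation, mean)
  rankstar <- tapply(bstar$net, bstar$rotation, mean)
  expect_equal(names(sort(rank100)), names(sort(rankstar)))
})

test_that("seasons and SOC coverage must match", {
  expect_error(
    assemble_budget(make_seasons("WW", rep(1, 24)), make_soc(16),
                    metric = "GWP100"),
    "same site-years")
})
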