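test_that("site generation is seeded, validated, and hits the regional SOC mean", {
  expect_identical(generate_sites(1, seed = 1), generate_sites(1, seed = 1))
  expect_error(generate_sites(0, seed = 1), "positive")
  expect_error(generate_sites(-3, seed = 1), "positive")

  s <- generate_sites(500, seed = 7)
  expect_equal(nrow(s), 500)
  # regional average topsoil SOC stock: 78 Mg C/ha within 5%
  expect_lt(abs(mean(s$soc0_topsoil) / 78 - 1), 0.05)
  expect_true(all(s$soc0_profile >= s$soc0_topsoil))
  expect_true(all(s$soc0_topsoil > 0))
  expect_true(all(s$leach_propensity >= 0))
})

test_that("historical weather matches the configured climate normals", {
  cfg <- default_config()
  site <- generate_sites(1, seed = 2)
  w <- generate_weather(site, cfg$scenarios$historical, 30, seed = 11)
  expect_equal(nrow(w), 30 * 365)
  expect_true(all(w$tmax >= w$tmin))
  expect_true(all(w$precip >= 0))
  expect_true(all(w$pet >= 0))
  # mean annual precipitation within 5% of 837 mm
  expect_lt(abs(sum(w$precip) / 30 / 837 - 1), 0.05)
  # mean temperature near 11 degC
  expect_lt(abs(mean((w$tmin + w$tmax) / 2) - 11), 0.5)
})

test_that("warming is a deterministic transform of the same draws", {
  cfg <- default_config()
  site <- generate_sites(1, seed = 2)
  hist <- generate_weather(site, cfg$scenarios$historical, 10, seed = 3)
  plus4 <- cfg$scenarios$plus4
  plus4$esm_label <- cfg$scenarios$historical$esm_label  # same noise stream
  warm <- generate_weather(site, plus4, 10, seed = 3)
  # additive offset: mean daily temperature difference exactly 4 degC
  expect_equal(mean((warm$tmin + warm$tmax) / 2) -
                 mean((hist$tmin + hist$tmax) / 2), 4, tolerance = 1e-12)
  # summer precipitation strictly lower, winter/spring higher
  jja <- function(x) sum(x$precip[x$month %in% 6:8])
  djf_mam <- function(x) sum(x$precip[x$month %in% c(12, 1, 2, 3, 4, 5)])
  expect_lt(jja(warm), jja(hist))
  expect_gt(djf_mam(warm), djf_mam(hist))
  # PET rises with temperature
  expect_gt(sum(warm$pet), sum(hist$pet))
})

test_that("season outcomes have one record per year and a full SOC trajectory", {
  cfg <- default_config()
  site <- generate_sites(1, seed = 5)
  rot <- build_rotation("ICLS", cfg)
  w <- generate_weather(site, cfg$scenarios$historical, 24, seed = 5)
  out <- generate_season_outcomes(site, cfg$scenarios$historical, rot, w,
                                  seed = 5, cfg)
  expect_equal(nrow(out$seasons), 24)
  expect_equal(out$seasons$position, rep(1:8, 3))
  expect_equal(nrow(out$soc), 24)
  expect_true(all(out$soc$delta_profile >= out$soc$delta_topsoil - 1e-9))
  expect_true(all(out$seasons$yield >= 0))
  expect_true(all(out$seasons$no3_leached >= 0))
  # weather not covering whole cycles is rejected
  w10 <- generate_weather(site, cfg$scenarios$historical, 10, seed = 5)
  expect_error(generate_season_outcomes(site, cfg$scenarios$historical, rot,
                                        w10, seed = 5, cfg),
               "whole number of rotation cycles")
})

test_that("degenerate noise gives yields exactly base x multiplier", {
  cfg <- deterministic_config()
  site <- generate_sites(1, seed = 1)
  rot <- build_rotation("BAU", cfg)
  crops <- crop_table(cfg)
  for (sc_name in c("historical", "plus4")) {
    sc <- cfg$scenarios[[sc_name]]
    w <- generate_weather(site, sc, 8, seed = 1, cfg)
    out <- generate_season_outcomes(site, sc, rot, w, seed = 1, cfg)
    expected <- crops$base_yield[match(rot$crop, crops$crop)] *
      vapply(rot$crop, function(cr)
        cfg$yield_multipliers[[cr]][[as.character(sc$warming_offset)]], 1.0) *
      rot$year_fraction
    expect_equal(out$seasons$yield, unname(expected), tolerance = 1e-12,
                 info = sc_name)
  }
})

test_that("regional simulation is reproducible and correctly sized", {
  a <- simulate_region(3, scenarios = c("historical", "plus2"),
                       rotations = c("BAU", "ICLS"), n_years = 8, seed = 42)
  b <- simulate_region(3, scenarios = c("historical", "plus2"),
                       rotations = c("BAU", "ICLS"), n_years = 8, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a$seasons), 3 * 2 * 2 * 8)
  expect_equal(nrow(a$soc), 3 * 2 * 2 * 8)
  expect_equal(nrow(a$monthly_balance), 3 * 2 * 8 * 12)
  expect_error(simulate_region(2, scenarios = "plus9", n_years = 8, seed = 1),
               "plus9")
})

test_that("leaching scales with site propensity and rotation multipliers", {
  cfg <- deterministic_config()
  site <- generate_sites(1, seed = 3)
  w <- generate_weather(site, cfg$scenarios$historical, 8, seed = 3)
  leach <- vapply(c("BAU", "Vegan", "ICLS"), function(rn) {
    rot <- build_rotation(rn, cfg)
    out <- generate_season_outcomes(site, cfg$scenarios$historical, rot, w,
                                    seed = 3, cfg)
    mean(out$seasons$no3_leached)
  }, 1.0)
  expected <- 4.5 * site$leach_propensity *
    vapply(c("BAU", "Vegan", "ICLS"),
           function(rn) cfg$leaching$multipliers[[rn]][["0"]], 1.0)
  expect_equal(unname(leach), unname(expected), tolerance = 1e-12)
})
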