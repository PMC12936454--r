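# Shared fixtures for the test suite. Everything is generated in code.

# configuration with all stochastic components switched off: yields become
# exactly base x multiplier, fluxes sit at their configured means
deterministic_config <- function() {
  cfg <- default_config()
  for (cr in names(cfg$crops)) cfg$crops[[cr]]$cv <- 0
  cfg$wheat_wet_coupling[] <- 0
  cfg$leaching$cv <- 0
  cfg$n2o$cv <- 0
  cfg$soc_change$topsoil_sd <- 0
  cfg$soc_change$extra_sd <- 1e-12
  cfg
}

# hand-built seasons table for arithmetic checks
make_seasons <- function(crop, yield, year_index = seq_along(yield),
                         uid = "S1", scenario = "historical", rotation = "BAU",
                         n_fertilizer = 0, n2o_direct = 0, no3_leached = 0,
                         manure_n_applied = 0, n_combine = 0, n_plough = 0,
                         n_surface_tillage = 0, year_fraction = 1) {
  tibble::tibble(
    uid = uid, scenario = scenario, rotation = rotation,
    year_index = year_index, position = year_index, crop = crop,
    yield = yield, n_fertilizer = n_fertilizer, n2o_direct = n2o_direct,
    no3_leached = no3_leached, residue_fate = "incorporated",
    manure_n_applied = manure_n_applied, cover_crop = FALSE,
    year_fraction = year_fraction, n_combine = n_combine,
    n_plough = n_plough, n_surface_tillage = n_surface_tillage,
    mam_balance = 0, mam_z = 0
  )
}

make_soc <- function(n_years, delta_topsoil = 0, delta_profile = 0,
                     uid = "S1", scenario = "historical", rotation = "BAU") {
  tibble::tibble(
    uid = uid, scenario = scenario, rotation = rotation,
    year_index = seq_len(n_years),
    delta_topsoil = rep_len(delta_topsoil, n_years),
    delta_profile = rep_len(delta_profile, n_years)
  )
}

# generalized-logistic random sample (inverse-CDF), for fit-recovery tests
rglo <- function(n, xi, alpha, k) {
  u <- stats::runif(n)
  y <- log(u / (1 - u))
  if (abs(k) < 1e-8) xi + alpha * y else xi + alpha * (1 - exp(-k * y)) / k
}
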