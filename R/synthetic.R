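#' Generate synthetic simulation sites
#'
#' Draws a set of virtual field sites with the between-site heterogeneity the
#' downstream analysis assumes: initial soil organic carbon stocks at 0-30 cm
#' (mean 78 Mg C/ha, matching the regional average) and over the full 0-200 cm
#' profile, and a dimensionless nitrate-leaching propensity (mean 1) standing
#' in for soil texture and drainage differences.
#'
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed; identical `(n_sites, seed)` yield identical sites.
#' @param config A configuration list, see [default_config()].
#' @return A tibble with columns `uid`, `soc0_topsoil`, `soc0_profile`,
#'   `leach_propensity`.
#' @export
#' @examples
#' generate_sites(3, seed = 1)
generate_sites <- function(n_sites, seed, config = default_config()) {
  if (!is.numeric(n_sites) || length(n_sites) != 1 || n_sites < 1) {
    stop("n_sites must be a single positive integer", call. = FALSE)
  }
  n_sites <- as.integer(n_sites)
  p <- config$sites
  with_seed_(derive_seed(seed, "sites"), {
    topsoil <- pmax(stats::rnorm(n_sites, p$soc0_topsoil_mean, p$soc0_topsoil_sd),
                    p$soc0_topsoil_min)
    extra <- pmax(stats::rnorm(n_sites, p$soc0_extra_mean, p$soc0_extra_sd),
                  p$soc0_extra_min)
    sdl <- p$leach_propensity_sdlog
    leach <- stats::rlnorm(n_sites, meanlog = -sdl^2 / 2, sdlog = sdl)
    tibble::tibble(
      uid = sprintf("S%05d", seq_len(n_sites)),
      soc0_topsoil = topsoil,
      soc0_profile = topsoil + extra,
      leach_propensity = leach
    )
  })
}

#' Generate daily weather for one site under a climate scenario
#'
#' Produces a daily series (365-day years, no leap days) of minimum and
#' maximum temperature, precipitation and Hargreaves reference
#' evapotranspiration. The historical scenario targets the configured regional
#' climate (837 mm/yr, 11 degC annual mean). Warmed scenarios reuse the
#' *same* stochastic draws — the warming offset is added to temperatures,
#' seasonal precipitation multipliers are applied (summers dry, winters and
#' springs wetten), and PET is recomputed from the shifted temperatures — so a
#' warmed series is exactly comparable day-by-day with its historical twin.
#' Distinct `esm_label`s select independent noise streams, emulating
#' replication across climate-model forcings.
#'
#' @param site A one-row site tibble from [generate_sites()], or a uid string.
#' @param scenario A scenario list/row with `name` (or `scenario`),
#'   `warming_offset` and `esm_label`; see [climate_scenarios()].
#' @param n_years Number of years (>= 1).
#' @param seed Integer seed.
#' @param config A configuration list.
#' @return A tibble with columns `uid`, `scenario`, `date`, `year`, `month`,
#'   `doy`, `tmin`, `tmax`, `precip`, `pet`.
#' @export
generate_weather <- function(site, scenario, n_years, seed,
                             config = default_config()) {
  stopifnot(n_years >= 1)
  uid <- if (is.character(site)) site else site$uid[[1]]
  sc <- as_scenario(scenario)
  cl <- config$climate

  ndays <- n_years * 365L
  doy <- rep(seq_len(365L), n_years)
  year <- rep(seq_len(n_years), each = 365L)
  month <- month_of_doy(doy)

  stream <- derive_seed(seed, "weather", uid, sc$esm_label)
  base <- with_seed_(stream, {
    # seasonal temperature cycle with AR(1) anomalies
    tcycle <- cl$mean_temp_c -
      cl$temp_amplitude_c * cos(2 * pi * (doy - cl$temp_phase_doy) / 365)
    eps <- stats::rnorm(ndays, 0, cl$temp_noise_sd * sqrt(1 - cl$temp_noise_ar1^2))
    anom <- stats::filter(eps, cl$temp_noise_ar1, method = "recursive")
    tmean <- tcycle + as.numeric(anom)
    drange <- pmax(stats::rnorm(ndays, cl$diurnal_range_mean, cl$diurnal_range_sd),
                   cl$diurnal_range_min)
    # precipitation: Bernoulli occurrence, gamma amounts, uniform monthly target
    daily_target <- cl$annual_precip_mm / 365
    wet <- stats::rbinom(ndays, 1, cl$wet_day_prob)
    shape <- cl$precip_gamma_shape
    amount <- stats::rgamma(ndays, shape = shape,
                            scale = daily_target / cl$wet_day_prob / shape)
    list(tmean = tmean, drange = drange, precip = wet * amount)
  })

  tmean <- base$tmean + sc$warming_offset
  tmax <- tmean + base$drange / 2
  tmin <- tmean - base$drange / 2
  precip <- base$precip * precip_season_multiplier(month, sc$warming_offset, cl)
  pet <- hargreaves_pet(doy, tmin, tmax, cl$latitude_deg)

  tibble::tibble(
    uid = uid, scenario = sc$name,
    date = as.Date(sprintf("%04d-01-01", 2000 + year)) + (doy - 1L),
    year = year, month = month, doy = doy,
    tmin = tmin, tmax = tmax, precip = precip, pet = pet
  )
}

# seasonal precipitation multiplier under a warming offset
precip_season_multiplier <- function(month, offset, cl) {
  mult <- rep(1, length(month))
  jja <- month %in% 6:8
  djf_mam <- month %in% c(12, 1, 2, 3, 4, 5)
  mult[jja] <- 1 + cl$summer_precip_slope * offset
  mult[djf_mam] <- 1 + cl$winter_spring_precip_slope * offset
  pmax(mult, 0)
}

# Hargreaves-Samani reference evapotranspiration (mm/day) with FAO-56
# extraterrestrial radiation; temperature-only, so warming raises PET.
hargreaves_pet <- function(doy, tmin, tmax, latitude_deg) {
  phi <- latitude_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(delta), -1), 1))
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  ra_mm <- 0.408 * ra
  tmean <- (tmin + tmax) / 2
  pmax(0.0023 * ra_mm * (tmean + 17.8) * sqrt(pmax(tmax - tmin, 0)), 0)
}

as_scenario <- function(scenario) {
  if (is.data.frame(scenario)) scenario <- as.list(scenario[1, ])
  list(
    name = scenario$name %||% scenario$scenario,
    warming_offset = scenario$warming_offset,
    co2_ppm = scenario$co2_ppm %||% NA_real_,
    esm_label = scenario$esm_label %||% "ERA"
  )
}

#' Generate crop-season outcomes and a SOC trajectory
#'
#' Emulates the annual outputs of a process-based soil-crop simulation for one
#' site, one climate scenario and one rotation: per-season yields (baseline x
#' warming-dependent multiplier x lognormal noise, with winter-wheat noise
#' additionally coupled to the standardized March-May water balance so wet
#' extremes depress wheat yields), nitrogen fluxes (fertilizer applied, direct
#' N2O-N, nitrate-N leached around the regional 4.5 kg N/ha/yr baseline), and
#' annual soil-organic-carbon change at 0-30 cm and 0-200 cm. The same seed
#' produces paired noise across climate scenarios, so scenario contrasts are
#' estimated on matched draws.
#'
#' @param site A one-row site tibble from [generate_sites()].
#' @param scenario A climate scenario (list or row); see [climate_scenarios()].
#' @param rotation A `rotation_plan` from [build_rotation()].
#' @param weather A daily weather tibble from [generate_weather()] covering a
#'   whole number of rotation cycles.
#' @param seed Integer seed.
#' @param config A configuration list.
#' @return A list with elements `seasons` (one row per crop season) and `soc`
#'   (one row per year with `delta_topsoil` and `delta_profile`, Mg C/ha/yr).
#' @export
generate_season_outcomes <- function(site, scenario, rotation, weather, seed,
                                     config = default_config()) {
  sc <- as_scenario(scenario)
  uid <- site$uid[[1]]
  rot_name <- attr(rotation, "rotation_name")
  L <- nrow(rotation)
  n_years <- length(unique(weather$year))
  if (n_years %% L != 0) {
    stop("weather must cover a whole number of rotation cycles (",
         n_years, " years vs rotation length ", L, ")", call. = FALSE)
  }
  wkey <- as.character(sc$warming_offset)

  crops <- crop_table(config)
  year_index <- seq_len(n_years)
  position <- (year_index - 1L) %% L + 1L
  plan <- rotation[position, ]
  base <- crops$base_yield[match(plan$crop, crops$crop)]
  cv <- crops$cv[match(plan$crop, crops$crop)]
  mult <- vapply(plan$crop, function(cr) config$yield_multipliers[[cr]][[wkey]], 1.0)

  # standardized March-May water balance of each year (wet year => z > 0)
  mam <- weather |>
    dplyr::filter(.data$month %in% 3:5) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(d = sum(.data$precip - .data$pet), .groups = "drop")
  mam_sd <- if (n_years > 1) stats::sd(mam$d) else 0
  z <- if (isTRUE(mam_sd > 0)) (mam$d - mean(mam$d)) / mam_sd else rep(0, n_years)

  k_wet <- config$wheat_wet_coupling[[rot_name]] %||% 0
  leach_mult <- config$leaching$multipliers[[rot_name]][[wkey]]
  n2o_mean <- config$n2o$direct_mean[[rot_name]] *
    (1 + config$n2o$warming_slope * sc$warming_offset)

  stream <- derive_seed(seed, "seasons", uid, rot_name, sc$esm_label)
  out <- with_seed_(stream, {
    sdlog <- sqrt(log(1 + cv^2))
    yield_noise <- stats::rlnorm(n_years, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    n2o_sdlog <- sqrt(log(1 + config$n2o$cv^2))
    n2o_noise <- stats::rlnorm(n_years, -n2o_sdlog^2 / 2, n2o_sdlog)
    le_sdlog <- sqrt(log(1 + config$leaching$cv^2))
    leach_noise <- stats::rlnorm(n_years, -le_sdlog^2 / 2, le_sdlog)
    soc_top_noise <- stats::rnorm(n_years, 0, config$soc_change$topsoil_sd)
    gap_mean <- config$soc_change$profile_mean[[rot_name]] -
      config$soc_change$topsoil_mean[[rot_name]]
    extra <- soc_extra_draw(n_years, gap_mean, config$soc_change$extra_sd)
    list(yield_noise = yield_noise, n2o_noise = n2o_noise,
         leach_noise = leach_noise, soc_top_noise = soc_top_noise, extra = extra)
  })

  # mean-one monotone wet penalty: exp(-k z - k^2/2) halves nothing on average
  # but pushes wet-extreme wheat seasons down
  wet_factor <- ifelse(plan$crop == "WW", exp(-k_wet * z - k_wet^2 / 2), 1)
  yield <- unname(base * mult * out$yield_noise * wet_factor * plan$year_fraction)

  seasons <- tibble::tibble(
    uid = uid, scenario = sc$name, rotation = rot_name,
    year_index = year_index, position = position,
    crop = plan$crop,
    yield = yield,
    n_fertilizer = plan$fertilizer_n,
    n2o_direct = n2o_mean * out$n2o_noise,
    no3_leached = config$leaching$base_kg_n * site$leach_propensity[[1]] *
      leach_mult * out$leach_noise,
    residue_fate = plan$residue_fate,
    manure_n_applied = plan$manure_n,
    cover_crop = plan$cover_crop,
    year_fraction = plan$year_fraction,
    n_combine = plan$combine, n_plough = plan$plough,
    n_surface_tillage = plan$surface_tillage,
    mam_balance = mam$d, mam_z = z
  )

  decline <- config$soc_change$warming_decline[[wkey]]
  delta_topsoil <- config$soc_change$topsoil_mean[[rot_name]] - decline +
    out$soc_top_noise
  soc <- tibble::tibble(
    uid = uid, scenario = sc$name, rotation = rot_name,
    year_index = year_index,
    delta_topsoil = delta_topsoil,
    delta_profile = delta_topsoil + out$extra
  )

  list(seasons = seasons, soc = soc)
}

# non-negative subsoil SOC contribution (mineralization below 30 cm treated as
# negligible, so the profile never changes less than the topsoil)
soc_extra_draw <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

#' Simulate a region: sites x climate scenarios x rotations
#'
#' Convenience driver looping [generate_weather()] and
#' [generate_season_outcomes()] over a site set, reusing each site's weather
#' across the three rotations. Returns pooled tables plus the monthly
#' precipitation-minus-PET balance needed by the drought-index stage.
#'
#' @param n_sites Number of sites.
#' @param scenarios Character vector of climate scenario names (keys of
#'   `config$scenarios`).
#' @param rotations Character vector of rotation names.
#' @param n_years Simulation length in years (default from config, 24).
#' @param seed Integer seed.
#' @param config A configuration list.
#' @return A list with tibbles `sites`, `seasons`, `soc`, `monthly_balance`.
#' @export
#' @examples
#' sim <- simulate_region(2, scenarios = "historical", rotations = "BAU",
#'                        n_years = 8, seed = 1)
#' nrow(sim$seasons)
simulate_region <- function(n_sites,
                            scenarios = names(config$scenarios),
                            rotations = c("BAU", "Vegan", "ICLS"),
                            n_years = config$simulation$n_years,
                            seed = 1,
                            config = default_config()) {
  unknown <- setdiff(scenarios, names(config$scenarios))
  if (length(unknown) > 0) {
    stop("unknown climate scenario: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sites <- generate_sites(n_sites, seed, config)
  plans <- lapply(rotations, build_rotation, config = config)
  names(plans) <- rotations

  seasons <- vector("list", n_sites * length(scenarios) * length(rotations))
  socs <- seasons
  monthly <- vector("list", n_sites * length(scenarios))
  i <- 0L; j <- 0L
  for (s in seq_len(n_sites)) {
    site <- sites[s, ]
    for (sc_name in scenarios) {
      sc <- config$scenarios[[sc_name]]
      weather <- generate_weather(site, sc, n_years, seed, config)
      j <- j + 1L
      monthly[[j]] <- monthly_balance(weather)
      for (rot in rotations) {
        out <- generate_season_outcomes(site, sc, plans[[rot]], weather, seed, config)
        i <- i + 1L
        seasons[[i]] <- out$seasons
        socs[[i]] <- out$soc
      }
    }
  }
  list(
    sites = sites,
    seasons = dplyr::bind_rows(seasons),
    soc = dplyr::bind_rows(socs),
    monthly_balance = dplyr::bind_rows(monthly)
  )
}
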