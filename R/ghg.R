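#' Soil CO2 term of the farm-gate budget
#'
#' The soil term is the 24-year (or series-length) mean annual change in soil
#' organic carbon over the whole 0-200 cm profile, converted to CO2 with the
#' stoichiometric 44/12 and *sign-flipped*: carbon sequestration (positive
#' SOC change) is a negative emission.
#'
#' @param delta_soc_profile Numeric vector of annual SOC change at 0-200 cm
#'   (Mg C/ha/yr), one value per simulated year.
#' @param n_years Expected series length (default: take the series as given).
#' @return Mean annual soil CO2 flux, Mg CO2/ha/yr (emission positive).
#' @export
#' @examples
#' soil_co2(rep(0.3, 24))   # sequestration: -1.1 Mg CO2/ha/yr
soil_co2 <- function(delta_soc_profile, n_years = length(delta_soc_profile)) {
  if (length(delta_soc_profile) != n_years) {
    stop("SOC trajectory has length ", length(delta_soc_profile),
         ", expected ", n_years, call. = FALSE)
  }
  -mean(delta_soc_profile) * 44 / 12
}

#' Indirect N2O from leaching and fertilizer application
#'
#' IPCC-factor bookkeeping: 0.75% of the nitrogen lost through leaching plus
#' 0.1% of the nitrogen applied as fertilizer is counted as indirect N2O-N.
#' The result is in N2O-N; multiply by 44/28 downstream for gas mass.
#'
#' @param n_leached Nitrogen leached (kg N/ha).
#' @param n_applied Fertilizer nitrogen applied (kg N/ha).
#' @return Indirect N2O-N (kg N/ha).
#' @export
#' @examples
#' indirect_n2o(100, 0)  # 0.75
indirect_n2o <- function(n_leached, n_applied) {
  if (any(n_leached < 0) || any(n_applied < 0)) {
    stop("nitrogen inputs must be non-negative", call. = FALSE)
  }
  0.0075 * n_leached + 0.001 * n_applied
}

#' Fossil CO2 from field operations
#'
#' Fuel use per pass — combine harvester 20.5 L/ha, ploughing 27.6 L/ha,
#' surface tillage 5.6 L/ha — times 0.81 kg C per litre of fuel, times 3.67
#' kg CO2 per kg C.
#'
#' @param n_combine,n_plough,n_surface_tillage Operation counts (vectors
#'   recycle).
#' @return CO2 emitted (kg CO2/ha).
#' @export
#' @examples
#' management_co2(1, 0, 0)  # 60.94
management_co2 <- function(n_combine = 0, n_plough = 0, n_surface_tillage = 0) {
  fuel <- 20.5 * n_combine + 27.6 * n_plough + 5.6 * n_surface_tillage
  fuel * 0.81 * 3.67
}

#' CO2 from nitrogen fertilizer synthesis
#'
#' Urea-ammonium-nitrate manufacture: 6.17 kg CO2-eq per kg N applied.
#'
#' @param n_applied Fertilizer nitrogen applied (kg N/ha).
#' @return CO2-eq emitted (kg/ha).
#' @export
fertilizer_co2 <- function(n_applied) {
  if (any(n_applied < 0)) stop("n_applied must be non-negative", call. = FALSE)
  6.17 * n_applied
}

#' GWP* CO2-warming-equivalent series for methane
#'
#' GWP* treats a change in the emission *rate* of a short-lived climate
#' pollutant as a CO2 pulse: E_co2we(t) = GWP100_CH4 x ( (r H / dt) x
#' (E(t) - E(t - dt)) + s x E(t) ). With the default r = 0.75, s = 0.25,
#' H = 100 and dt = 20 this is GWP100 x (4 E(t) - 3.75 E(t - dt)). Years
#' before the series start assume emissions equal to year 1 (stable herd), so
#' a constant series maps to 0.25 x GWP100 x E.
#'
#' @param ch4_annual Numeric vector of annual CH4 emissions (kg CH4/ha/yr).
#' @param gwp GWP parameter list (defaults `config$gwp`).
#' @param config A configuration list.
#' @return Numeric vector of CO2-warming-equivalent emissions (kg CO2-we/ha/yr).
#' @export
#' @examples
#' gwp_star_series(rep(10, 5))  # 0.25 * 27.2 * 10 each year
gwp_star_series <- function(ch4_annual, gwp = config$gwp,
                            config = default_config()) {
  n <- length(ch4_annual)
  stopifnot(n >= 1)
  p <- gwp$gwpstar
  t_prev <- seq_len(n) - p$dt
  e_prev <- ifelse(t_prev >= 1, ch4_annual[pmax(t_prev, 1)], ch4_annual[1])
  gwp$gwp100_ch4 * ((p$r * p$H / p$dt) * (ch4_annual - e_prev) + p$s * ch4_annual)
}

#' Assemble the seven-term farm-gate GHG budget
#'
#' Aggregates season records, the SOC trajectory and (optionally) livestock
#' and manure flows into the farm-gate budget per site x climate scenario x
#' rotation, expressed as 24-year mean annual fluxes in Mg CO2-eq/ha/yr:
#' soil CO2 (the only term allowed to be negative), fertilizer-synthesis CO2,
#' management (fuel) CO2, direct and indirect N2O, total CH4 (enteric +
#' manure storage + spreading), and manure-storage N2O. N2O-N is converted to
#' gas with 44/28 and weighted by GWP100(N2O); CH4 is weighted by GWP100(CH4)
#' or converted through [gwp_star_series()] according to `metric`.
#'
#' @param seasons Seasons tibble ([simulate_region()]).
#' @param soc SOC tibble ([simulate_region()]).
#' @param livestock Optional livestock tibble ([sheep_production()] applied to
#'   [feed_supply()]); required for rotations with on-farm sheep.
#' @param gwp GWP parameter list (defaults `config$gwp`).
#' @param metric `"GWP100"` or `"GWPstar"`.
#' @param config A configuration list.
#' @return A tibble of class `ghg_budget` with one row per uid x scenario x
#'   rotation and columns `co2_soil`, `co2_fertilizer`, `co2_management`,
#'   `n2o_direct`, `n2o_indirect`, `ch4_total`, `manure_n2o`, `net`, `metric`.
#' @export
assemble_budget <- function(seasons, soc, livestock = NULL,
                            gwp = config$gwp,
                            metric = c("GWP100", "GWPstar"),
                            config = default_config()) {
  metric <- match.arg(metric)
  lp <- config$livestock
  n2o_gas <- 44 / 28

  key <- c("uid", "scenario", "rotation")
  soc_cov <- dplyr::count(soc, dplyr::across(dplyr::all_of(key)))
  sea_cov <- dplyr::count(seasons, dplyr::across(dplyr::all_of(key)))
  cov <- dplyr::inner_join(soc_cov, sea_cov, by = key, suffix = c("_soc", "_sea"))
  if (nrow(cov) != nrow(soc_cov) || nrow(cov) != nrow(sea_cov) ||
      any(cov$n_soc != cov$n_sea)) {
    stop("seasons and SOC trajectories do not cover the same site-years",
         call. = FALSE)
  }

  # per-year manure flows: on-farm flocks contribute storage + spreading of
  # their own excreta; importing rotations spread purchased manure only
  linkage <- purrr::map_chr(
    rlang::set_names(unique(seasons$rotation)),
    function(r) config$rotations[[r]]$livestock_linkage %||% "none"
  )
  yearly <- seasons |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "year_index")))) |>
    dplyr::summarise(
      n_fertilizer = sum(.data$n_fertilizer),
      n2o_direct_n = sum(.data$n2o_direct),
      no3_leached = sum(.data$no3_leached),
      manure_n_applied = sum(.data$manure_n_applied),
      mgmt_co2 = sum(management_co2(.data$n_combine, .data$n_plough,
                                    .data$n_surface_tillage)),
      .groups = "drop"
    )

  if (!is.null(livestock)) {
    yearly <- dplyr::left_join(
      yearly,
      dplyr::select(livestock, dplyr::all_of(c(key, "year_index")),
                    "ch4_enteric", "manure_n", "manure_vs"),
      by = c(key, "year_index")
    ) |>
      dplyr::mutate(dplyr::across(c("ch4_enteric", "manure_n", "manure_vs"),
                                  ~ tidyr::replace_na(.x, 0)))
  } else {
    yearly <- dplyr::mutate(yearly, ch4_enteric = 0, manure_n = 0, manure_vs = 0)
  }
  if (any(linkage[unique(yearly$rotation)] == "on_farm_sheep") &&
      is.null(livestock)) {
    stop("rotations with on-farm sheep need a livestock table", call. = FALSE)
  }

  yearly <- yearly |>
    dplyr::mutate(
      on_farm = linkage[.data$rotation] == "on_farm_sheep",
      vs_handled = ifelse(.data$on_farm, .data$manure_vs,
                          .data$manure_n_applied * lp$vs_per_kg_manure_n),
      n_handled = ifelse(.data$on_farm, .data$manure_n, 0)
    )
  em_full <- manure_emissions(yearly$n_handled, yearly$vs_handled, "icls_full",
                              lp, config)
  em_spread <- manure_emissions(0 * yearly$n_handled, yearly$vs_handled,
                                "bau_spreading_only", lp, config)
  yearly <- yearly |>
    dplyr::mutate(
      ch4_manure = ifelse(.data$on_farm,
                          em_full$ch4_storage + em_full$ch4_spreading,
                          em_spread$ch4_spreading),
      n2o_manure_gas = ifelse(.data$on_farm,
                              em_full$n2o_storage_direct + em_full$n2o_storage_indirect,
                              0),
      ch4_year = .data$ch4_enteric + .data$ch4_manure
    )

  soc_mean <- soc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(co2_soil = soil_co2(.data$delta_profile), .groups = "drop")

  budgets <- yearly |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::arrange(.data$year_index, .by_group = TRUE) |>
    dplyr::summarise(
      co2_fertilizer = mean(fertilizer_co2(.data$n_fertilizer)) / 1000,
      co2_management = mean(.data$mgmt_co2) / 1000,
      n2o_direct = mean(.data$n2o_direct_n) * n2o_gas * gwp$gwp100_n2o / 1000,
      n2o_indirect = mean(indirect_n2o(.data$no3_leached, .data$n_fertilizer)) *
        n2o_gas * gwp$gwp100_n2o / 1000,
      ch4_total = if (metric == "GWP100") {
        mean(.data$ch4_year) * gwp$gwp100_ch4 / 1000
      } else {
        # farm-level emission rate: every rotation phase is present on the
        # farm each year, so the rate the warming-equivalent metric sees is
        # the cycle-average of the per-field series, not its sawtooth
        cyc <- (.data$year_index - 1) %/% config$simulation$rotation_length
        farm_rate <- stats::ave(.data$ch4_year, cyc)
        mean(gwp_star_series(farm_rate, gwp, config)) / 1000
      },
      manure_n2o = mean(.data$n2o_manure_gas) * gwp$gwp100_n2o / 1000,
      .groups = "drop"
    ) |>
    dplyr::left_join(soc_mean, by = key) |>
    dplyr::mutate(
      net = .data$co2_soil + .data$co2_fertilizer + .data$co2_management +
        .data$n2o_direct + .data$n2o_indirect + .data$ch4_total +
        .data$manure_n2o,
      metric = metric
    ) |>
    dplyr::relocate("co2_soil", .after = "rotation")

  structure(budgets, class = c("ghg_budget", class(budgets)))
}
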