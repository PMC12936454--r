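#' Productivity totals per rotation cycle
#'
#' Sums each 8-year rotation cycle's output in three metrics: mass (Mg/ha,
#' grain, roots/tubers fresh-equivalent, and pasture biomass plus sheep
#' live-weight gain), energy (cereal units, from per-crop metabolizable-energy
#' coefficients), and economic value (euro/ha, yield x price minus per-crop
#' fixed costs, plus retail meat value for rotations with on-farm sheep).
#'
#' @param seasons Seasons tibble ([simulate_region()]).
#' @param livestock Optional livestock tibble ([sheep_production()]).
#' @param per Aggregation grain: `"cycle"` (default, 8-year rotation cycles)
#'   or `"year"` (annual totals, the alternative basis for stability).
#' @param config A configuration list (crop value tables and livestock prices).
#' @return A tibble with one row per uid x scenario x rotation x cycle and
#'   columns `productivity_mass`, `productivity_energy`, `productivity_econ`.
#' @export
productivity <- function(seasons, livestock = NULL, per = c("cycle", "year"),
                         config = default_config()) {
  per <- match.arg(per)
  crops <- crop_table(config)
  missing <- setdiff(unique(seasons$crop), crops$crop)
  if (length(missing) > 0) {
    stop("no value-table entry for crop(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  L <- config$simulation$rotation_length
  lp <- config$livestock

  per_season <- seasons |>
    dplyr::left_join(crops, by = "crop") |>
    dplyr::mutate(
      cycle = if (per == "cycle") (.data$year_index - 1) %/% L + 1
              else .data$year_index,
      mass = .data$yield,
      energy = .data$yield * .data$cu_per_mg,
      econ = .data$yield * .data$price - .data$fixed_cost * .data$year_fraction
    )

  totals <- per_season |>
    dplyr::group_by(.data$uid, .data$scenario, .data$rotation, .data$cycle) |>
    dplyr::summarise(
      productivity_mass = sum(.data$mass),
      productivity_energy = sum(.data$energy),
      productivity_econ = sum(.data$econ),
      .groups = "drop"
    )

  if (!is.null(livestock) && nrow(livestock) > 0) {
    lv <- livestock |>
      dplyr::mutate(cycle = if (per == "cycle") (.data$year_index - 1) %/% L + 1
                            else .data$year_index) |>
      dplyr::group_by(.data$uid, .data$scenario, .data$rotation, .data$cycle) |>
      dplyr::summarise(
        lwg_mg = sum(.data$lwg) / 1000,
        meat_value = sum(.data$meat_retail) * lp$price_per_kg_retail,
        .groups = "drop"
      )
    totals <- totals |>
      dplyr::left_join(lv, by = c("uid", "scenario", "rotation", "cycle")) |>
      dplyr::mutate(
        lwg_mg = tidyr::replace_na(.data$lwg_mg, 0),
        meat_value = tidyr::replace_na(.data$meat_value, 0),
        productivity_mass = .data$productivity_mass + .data$lwg_mg,
        productivity_energy = .data$productivity_energy +
          .data$lwg_mg * lp$cu_per_mg_lwg,
        productivity_econ = .data$productivity_econ + .data$meat_value
      ) |>
      dplyr::select(-"lwg_mg", -"meat_value")
  }
  totals
}

#' Stability of productivity
#'
#' Stability = mu / sigma of per-cycle productivity totals: the mean of the
#' 8-year rotation-cycle totals over the simulated period divided by their
#' sample (n-1) standard deviation. A zero-variance series is flagged
#' undefined rather than mapped to infinity so downstream aggregation can
#' exclude it.
#'
#' @param totals Numeric vector of per-cycle productivity totals (length >= 2).
#' @return A one-row tibble with `mu`, `sigma`, `stability`, `defined`.
#' @export
#' @examples
#' stability(c(10, 12, 14))  # stability 6
stability <- function(totals) {
  if (length(totals) < 2) stop("need at least two rotation cycles", call. = FALSE)
  mu <- mean(totals)
  sigma <- stats::sd(totals)
  tibble::tibble(
    mu = mu, sigma = sigma,
    stability = ifelse(sigma > 0, mu / sigma, NA_real_),
    defined = sigma > 0
  )
}

#' Stability panel over a productivity table
#'
#' Applies [stability()] per uid x scenario x rotation and productivity
#' metric. The grain of the variability (8-year cycle totals, the default, or
#' annual totals) is decided by the `per` argument of [productivity()].
#'
#' @param prod Output of [productivity()].
#' @return A long tibble with columns `metric`, `mu`, `sigma`, `stability`,
#'   `defined` per uid x scenario x rotation.
#' @export
stability_panel <- function(prod) {
  prod |>
    tidyr::pivot_longer(dplyr::starts_with("productivity_"),
                        names_to = "metric", names_prefix = "productivity_",
                        values_to = "total") |>
    dplyr::group_by(.data$uid, .data$scenario, .data$rotation, .data$metric) |>
    dplyr::summarise(stability(.data$total), .groups = "drop")
}

#' Standardize wheat yields within site x climate scenario
#'
#' Z-scores x 100 within each uid x scenario group (sample standard
#' deviation), putting wheat seasons from different sites and climates on a
#' common percent-of-variability scale; differences between classes can
#' therefore exceed 100 in magnitude. The wheat seasons of all rotations are
#' pooled within a group — they occur in the same years, and a shared
#' yardstick is what makes the rotations' event responses comparable — so a
#' rotation whose wheat shrugs off a wet extreme genuinely shows a smaller
#' standardized deviation. Groups with fewer than 3 seasons or zero variance
#' are flagged undefined (`std_yield` = NA).
#'
#' @param wheat A tibble of wheat seasons with columns `uid`, `scenario`,
#'   `yield`.
#' @param group Extra grouping columns beyond uid and scenario (default
#'   none; pass `"rotation"` to standardize each rotation against itself).
#' @return The input with added `std_yield` and `std_defined` columns.
#' @export
standardize_yields <- function(wheat, group = character()) {
  keys <- c("uid", "scenario", group)
  wheat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      .n = dplyr::n(),
      .sd = stats::sd(.data$yield),
      std_defined = .data$.n >= 3 & !is.na(.data$.sd) & .data$.sd > 0,
      std_yield = ifelse(.data$std_defined,
                         (.data$yield - mean(.data$yield)) / .data$.sd * 100,
                         NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".n", -".sd")
}

#' Resistance of wheat yields to classified climatic events
#'
#' Omega = 1 / |Ye - Yn_bar|: the reciprocal of the absolute deviation of an
#' event season's (standardized) yield Ye from the mean yield over
#' normal-labelled seasons Yn_bar of the same group. Deviations below `eps`
#' are capped at 1/eps and flagged. The variant Omega2 = Yn_bar / |Ye -
#' Yn_bar| (which mixes in the normal-year level) is available behind
#' `use_omega2`.
#'
#' @param wheat A tibble with columns `uid`, `scenario`, `rotation`,
#'   `std_yield` and `label` (an event-class factor; see
#'   [classify_seasons()]).
#' @param eps Degeneracy guard on |Ye - Yn_bar| (default from config).
#' @param use_omega2 Use the Omega2 variant (default FALSE).
#' @param config A configuration list.
#' @return A tibble of event seasons with columns `label`, `y_event`,
#'   `y_normal_mean`, `omega`, `capped`.
#' @export
resistance <- function(wheat, eps = config$resistance$eps,
                       use_omega2 = config$resistance$use_omega2,
                       config = default_config()) {
  keys <- intersect(c("uid", "scenario", "rotation"), names(wheat))
  wheat |>
    dplyr::filter(!is.na(.data$std_yield)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      normals <- df$std_yield[df$label == "normal"]
      if (length(normals) == 0) {
        stop("no normal seasons in group; resistance undefined", call. = FALSE)
      }
      yn <- mean(normals)
      ev <- df[df$label != "normal", ]
      dev <- abs(ev$std_yield - yn)
      capped <- dev < eps
      dev <- pmax(dev, eps)
      omega <- if (use_omega2) yn / dev else 1 / dev
      tibble::tibble(
        label = ev$label, y_event = ev$std_yield,
        y_normal_mean = yn, omega = omega, capped = capped
      )
    }) |>
    dplyr::ungroup()
}

#' Summarise resistance by scenario and event class
#'
#' Group medians of Omega with 1.5 x IQR outlier removal (see
#' [iqr_outliers()]).
#'
#' @param res Output of [resistance()].
#' @param config A configuration list (IQR multiplier).
#' @return A tibble with columns `scenario`, `rotation`, `label`,
#'   `omega_median`, `n`, `n_outliers`.
#' @export
summarise_resistance <- function(res, config = default_config()) {
  k <- config$stats$iqr_multiplier
  res |>
    dplyr::group_by(.data$scenario, .data$rotation, .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_outliers = if (dplyr::n() >= 4) sum(iqr_outliers(.data$omega, k)) else 0L,
      omega_median = {
        keep <- if (dplyr::n() >= 4) !iqr_outliers(.data$omega, k)
                else rep(TRUE, dplyr::n())
        stats::median(.data$omega[keep])
      },
      .groups = "drop"
    )
}

#' Multi-criteria normalization against the business-as-usual reference
#'
#' Each criterion is expressed as an index with the BAU rotation at 100:
#' index = value / value_BAU x 100. When the BAU value is negative while
#' other rotations may be positive (the soil-carbon case: BAU loses carbon,
#' the others gain), the index divides by |value_BAU| instead, so BAU sits at
#' -100 and a sequestering rotation keeps a positive sign. Normalizing an
#' already-normalized panel returns it unchanged.
#'
#' @param panel A tibble with columns `criterion`, `rotation`, `value`.
#' @param reference Reference rotation name (default `"BAU"`).
#' @return The input with an added `index` column.
#' @export
#' @examples
#' multicriteria_normalize(tibble::tibble(
#'   criterion = "soc", rotation = c("BAU", "ICLS"), value = c(-0.1, 0.3)))
multicriteria_normalize <- function(panel, reference = "BAU") {
  panel |>
    dplyr::group_by(.data$criterion) |>
    dplyr::group_modify(function(df, key) {
      ref <- df$value[df$rotation == reference]
      if (length(ref) != 1) {
        stop("criterion '", key$criterion, "' lacks a single ", reference,
             " reference value", call. = FALSE)
      }
      if (ref == 0) {
        stop("criterion '", key$criterion, "': reference value is zero",
             call. = FALSE)
      }
      df$index <- if (ref > 0) df$value / ref * 100 else df$value / abs(ref) * 100
      df
    }) |>
    dplyr::ungroup()
}

#' Mean yield change relative to the historical climate
#'
#' Per crop and climate scenario, the relative change (%) of the mean yield
#' against the historical scenario, pooling all rotations and sites. This is
#' the estimator the generator's configured warming effect sizes are recovered
#' with.
#'
#' @param seasons Seasons tibble covering the historical scenario and at least
#'   one other.
#' @param historical Name of the reference scenario (default `"historical"`).
#' @return A tibble with columns `crop`, `scenario`, `mean_yield`,
#'   `change_pct` (NA for the reference itself).
#' @export
yield_evolution <- function(seasons, historical = "historical") {
  if (!historical %in% seasons$scenario) {
    stop("seasons do not include the reference scenario '", historical, "'",
         call. = FALSE)
  }
  means <- seasons |>
    dplyr::group_by(.data$crop, .data$scenario) |>
    dplyr::summarise(mean_yield = mean(.data$yield), .groups = "drop")
  ref <- means |>
    dplyr::filter(.data$scenario == historical) |>
    dplyr::select("crop", ref_yield = "mean_yield")
  means |>
    dplyr::left_join(ref, by = "crop") |>
    dplyr::mutate(
      change_pct = ifelse(.data$scenario == historical, NA_real_,
                          (.data$mean_yield / .data$ref_yield - 1) * 100)
    ) |>
    dplyr::select(-"ref_yield")
}
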