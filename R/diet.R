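#' Food and feed supply of a rotation
#'
#' Maps crop outputs (main products and by-products) and, for rotations with
#' on-farm sheep, retail meat to annual per-hectare energy supply by
#' commodity. Fruits, vegetables and tree nuts are produced outside the
#' rotation and therefore never appear on the supply side.
#'
#' @param seasons Seasons tibble ([simulate_region()]), typically one
#'   rotation x scenario at a time or grouped by both.
#' @param livestock Optional livestock tibble ([sheep_production()]).
#' @param config A configuration list (conversion tables under `diet`).
#' @return A tibble with columns `rotation`, `scenario`, `commodity`,
#'   `supply` (kcal/ha/yr, averaged over simulated site-years).
#' @export
rotation_supply <- function(seasons, livestock = NULL,
                            config = default_config()) {
  map <- config$diet$supply_map
  unmapped <- setdiff(unique(seasons$crop), names(map))
  if (length(unmapped) > 0) {
    stop("no commodity mapping for crop(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  conv <- purrr::imap_dfr(map, function(entries, crop) {
    tibble::tibble(crop = crop, commodity = names(entries),
                   kcal_per_mg = unlist(entries))
  })
  # mean annual yield per crop per ha of rotation (site-years averaged, but
  # each rotation year contributes its crop: divide by years simulated)
  n_years_sites <- seasons |>
    dplyr::group_by(.data$rotation, .data$scenario) |>
    dplyr::summarise(ny = dplyr::n_distinct(.data$uid) *
                       dplyr::n_distinct(.data$year_index), .groups = "drop")

  crop_supply <- seasons |>
    dplyr::group_by(.data$rotation, .data$scenario, .data$crop) |>
    dplyr::summarise(total_yield = sum(.data$yield), .groups = "drop") |>
    dplyr::left_join(n_years_sites, by = c("rotation", "scenario")) |>
    dplyr::mutate(yield_per_ha_yr = .data$total_yield / .data$ny) |>
    dplyr::inner_join(conv, by = "crop", relationship = "many-to-many") |>
    dplyr::group_by(.data$rotation, .data$scenario, .data$commodity) |>
    dplyr::summarise(supply = sum(.data$yield_per_ha_yr * .data$kcal_per_mg),
                     .groups = "drop")

  # cover-crop biomass fed to sheep also enters the forage supply
  cover_feed <- seasons |>
    dplyr::filter(.data$cover_crop) |>
    dplyr::group_by(.data$rotation, .data$scenario) |>
    dplyr::summarise(n_cover = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(n_years_sites, by = c("rotation", "scenario")) |>
    dplyr::mutate(
      feed = purrr::map_chr(.data$rotation,
                            ~ config$rotations[[.x]]$cover_fate %||% "incorporated"),
      supply = ifelse(.data$feed == "removed_feed",
                      .data$n_cover / .data$ny * config$crops$cover$base_yield *
                        config$diet$supply_map$cover$feed_forage, 0),
      commodity = "feed_forage"
    ) |>
    dplyr::filter(.data$supply > 0) |>
    dplyr::select("rotation", "scenario", "commodity", "supply")

  meat_supply <- NULL
  if (!is.null(livestock) && nrow(livestock) > 0) {
    meat_supply <- livestock |>
      dplyr::group_by(.data$rotation, .data$scenario) |>
      dplyr::summarise(
        meat_mg = sum(.data$meat_retail) / 1000 /
          (dplyr::n_distinct(.data$uid) * dplyr::n_distinct(.data$year_index)),
        .groups = "drop"
      ) |>
      dplyr::mutate(commodity = "meat",
                    supply = .data$meat_mg * config$diet$meat_kcal_per_mg) |>
      dplyr::filter(.data$supply > 0) |>
      dplyr::select("rotation", "scenario", "commodity", "supply")
  }

  dplyr::bind_rows(crop_supply, cover_feed, meat_supply) |>
    dplyr::group_by(.data$rotation, .data$scenario, .data$commodity) |>
    dplyr::summarise(supply = sum(.data$supply), .groups = "drop") |>
    dplyr::arrange(.data$rotation, .data$scenario, .data$commodity)
}

#' Commodity intake bounds for a diet mode
#'
#' Per-commodity lower/upper intake bounds (kcal/person/day) in the spirit of
#' a planetary-health reference diet. The vegan mode forces animal-commodity
#' bounds to zero; the ovo-lacto mode zeroes meat only.
#'
#' @param mode `"omnivorous"`, `"ovo_lacto"` or `"vegan"`.
#' @param config A configuration list.
#' @return A tibble with columns `commodity`, `lower`, `upper`.
#' @export
diet_bounds <- function(mode = c("omnivorous", "ovo_lacto", "vegan"),
                        config = default_config()) {
  mode <- match.arg(mode)
  b <- purrr::imap_dfr(config$diet$bounds, function(lu, com) {
    tibble::tibble(commodity = com, lower = lu[[1]], upper = lu[[2]])
  })
  animal <- c("meat", "dairy", "eggs")
  zero_out <- switch(mode, vegan = animal, ovo_lacto = "meat", character())
  b |>
    dplyr::mutate(
      lower = ifelse(.data$commodity %in% zero_out, 0, .data$lower),
      upper = ifelse(.data$commodity %in% zero_out, 0, .data$upper)
    )
}

#' Match a rotation's supply to a reference-diet demand by random search
#'
#' Samples candidate diets — per-commodity intakes within their bounds and a
#' number of people fed per hectare within its prior — and scores each by a
#' weighted objective: the relative gap between total dietary energy and the
#' target (weight `w_energy`, the larger weight) plus the relative sum of
#' commodity deficits and surpluses (weight `w_balance`). Animal-commodity
#' intakes induce feed demand through feed-conversion factors. The incumbent
#' best never worsens with more iterations, and a fixed seed makes the search
#' deterministic.
#'
#' @param supply A tibble with columns `commodity`, `supply` (kcal/ha/yr) for
#'   one rotation under one scenario (see [rotation_supply()]).
#' @param bounds A bounds tibble from [diet_bounds()].
#' @param n_iter Number of random draws (>= 1).
#' @param seed Integer seed.
#' @param config A configuration list.
#' @return An object of class `diet_fit`: a list with `intake` (named vector,
#'   kcal/person/day), `people_per_ha`, `balance` (per-commodity supply,
#'   demand, deficit, surplus), `objective`, `energy_intake`, `trace` (running
#'   best objective) and `n_iter`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
optimize_diet <- function(supply, bounds, n_iter = config$diet$n_iter,
                          seed = 1, config = default_config()) {
  stopifnot(n_iter >= 1)
  if (any(bounds$lower > bounds$upper)) {
    stop("infeasible bounds: lower > upper", call. = FALSE)
  }
  dt <- config$diet
  feed_coms <- c("feed_forage", "feed_concentrate")
  commodities <- union(bounds$commodity, union(supply$commodity, feed_coms))
  sup <- rlang::set_names(rep(0, length(commodities)), commodities)
  sup[supply$commodity] <- supply$supply

  lower <- rlang::set_names(rep(0, length(commodities)), commodities)
  upper <- lower
  lower[bounds$commodity] <- bounds$lower
  upper[bounds$commodity] <- bounds$upper
  food_coms <- bounds$commodity

  ff <- dt$feed_factors
  with_seed_(derive_seed(seed, "diet"), {
    intakes <- vapply(commodities, function(com) {
      stats::runif(n_iter, lower[[com]], upper[[com]])
    }, numeric(n_iter))
    if (n_iter == 1) intakes <- matrix(intakes, nrow = 1,
                                       dimnames = list(NULL, commodities))
    people <- stats::runif(n_iter, dt$people_prior[1], dt$people_prior[2])

    # demand matrix: food intake scaled to the hectare, plus induced feed
    demand <- intakes * 365 * people
    for (fc in feed_coms) {
      induced <- rep(0, n_iter)
      for (animal in names(ff)) {
        if (animal %in% commodities) {
          induced <- induced + intakes[, animal] * (ff[[animal]][[fc]] %||% 0)
        }
      }
      demand[, fc] <- induced * 365 * people
    }

    supmat <- matrix(sup, nrow = n_iter, ncol = length(commodities),
                     byrow = TRUE, dimnames = list(NULL, commodities))
    deficit <- pmax(demand - supmat, 0)
    surplus <- pmax(supmat - demand, 0)
    energy_intake <- rowSums(intakes[, food_coms, drop = FALSE]) + dt$external_kcal
    gap <- abs(energy_intake - dt$energy_target_kcal) / dt$energy_target_kcal
    imbalance <- rowSums(deficit + surplus) / max(sum(sup), 1)
    objective <- dt$weights$energy * gap + dt$weights$balance * imbalance

    best <- which.min(objective)
    balance <- tibble::tibble(
      commodity = commodities,
      supply = unname(sup),
      demand = unname(demand[best, ]),
      deficit = unname(deficit[best, ]),
      surplus = unname(surplus[best, ])
    )
    structure(
      list(
        intake = intakes[best, ],
        people_per_ha = people[best],
        balance = balance,
        objective = objective[best],
        energy_intake = energy_intake[best],
        trace = cummin(objective),
        n_iter = n_iter
      ),
      class = "diet_fit"
    )
  })
}

#' @export
print.diet_fit <- function(x, ...) {
  cat("<diet_fit> objective", format(x$objective, digits = 4),
      "| people/ha", format(x$people_per_ha, digits = 3),
      "| energy", round(x$energy_intake), "kcal/person/day\n")
  print(x$balance)
  invisible(x)
}

#' Tidy a diet fit into its commodity balance
#'
#' @param x A `diet_fit` object.
#' @param ... Unused.
#' @return The per-commodity balance tibble with the optimal intake attached.
#' @export
tidy.diet_fit <- function(x, ...) {
  x$balance |>
    dplyr::mutate(intake_kcal_day = unname(x$intake[.data$commodity]))
}

#' One-row summary of a diet fit
#'
#' @param x A `diet_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: objective, people fed per hectare, energy intake,
#'   total deficit and surplus, iterations.
#' @export
glance.diet_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    people_per_ha = x$people_per_ha,
    energy_intake = x$energy_intake,
    total_deficit = sum(x$balance$deficit),
    total_surplus = sum(x$balance$surplus),
    n_iter = x$n_iter
  )
}
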