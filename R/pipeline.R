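#' Run the full circularity-scenario pipeline
#'
#' Orchestrates the stages end-to-end: synthetic site/weather/season
#' generation, livestock conversion, GHG budgets under the chosen metric(s),
#' SPEI-3 fitting on the historical scenario with event classification of
#' wheat seasons under every scenario (historical coefficients and
#' thresholds, so future events are judged against today's climate),
#' productivity/stability/resistance, the diet optimizer per rotation, the
#' scenario rank tests, and the BAU-referenced multi-criteria panel.
#' Deterministic for a fixed `(config, seed)`.
#'
#' @param config A configuration list, see [default_config()].
#' @param n_sites Number of synthetic sites.
#' @param scenarios Climate scenario names (default: all configured).
#' @param rotations Rotation names (default: the three circularity
#'   scenarios).
#' @param seed Integer seed for every stochastic stage.
#' @param metrics GHG metrics to assemble (`"GWP100"`, `"GWPstar"` or both).
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV with a JSON schema sidecar.
#' @param quiet Suppress stage logging (default `FALSE`; messages go to
#'   stderr).
#' @return A named list of tibbles: `sites`, `seasons`, `soc`, `livestock`,
#'   `budgets`, `spei`, `season_class`, `productivity`, `stability`,
#'   `resistance`, `resistance_summary`, `yield_evolution`, `diet_balance`,
#'   `comparisons`, `multicriteria`.
#' @export
run_pipeline <- function(config = default_config(),
                         n_sites = 20,
                         scenarios = names(config$scenarios),
                         rotations = c("BAU", "Vegan", "ICLS"),
                         seed = 1,
                         metrics = c("GWPstar", "GWP100"),
                         out_dir = NULL,
                         quiet = FALSE) {
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  t0 <- Sys.time()
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  say("simulate", "generating ", n_sites, " sites x ",
      length(scenarios), " climate scenario(s) x ", length(rotations),
      " rotation(s)")
  sim <- stage_wrap("simulate",
    simulate_region(n_sites, scenarios, rotations,
                    n_years = config$simulation$n_years, seed = seed,
                    config = config))
  say("simulate", nrow(sim$seasons), " season records")

  say("livestock", "converting forage to sheep outputs")
  lv <- stage_wrap("livestock", {
    fs <- feed_supply(sim$seasons, config)
    sheep_production(fs, config$livestock, config)
  })

  say("budget", "assembling GHG budgets (", paste(metrics, collapse = ", "), ")")
  budgets <- stage_wrap("budget", purrr::map_dfr(metrics, function(m) {
    assemble_budget(sim$seasons, sim$soc, lv, config$gwp, m, config)
  }))

  say("climate", "fitting SPEI-3 and classifying wheat seasons")
  cls <- stage_wrap("climate",
    classify_pipeline(sim$monthly_balance, sim$seasons, config))

  say("performance", "productivity, stability, resistance")
  prod <- stage_wrap("performance", productivity(sim$seasons, lv, config = config))
  stab <- stage_wrap("performance", stability_panel(prod))
  wheat <- sim$seasons |>
    dplyr::filter(.data$crop == "WW") |>
    dplyr::inner_join(cls$season_class,
                      by = c("uid", "scenario", "year_index" = "year")) |>
    standardize_yields() |>
    # judged against historical yardsticks, a warmed scenario can have no
    # normal-labelled wheat season at a site; such groups carry no reference
    # and are left out of the resistance computation
    dplyr::group_by(.data$uid, .data$scenario, .data$rotation) |>
    dplyr::filter(any(.data$label == "normal")) |>
    dplyr::ungroup()
  res <- stage_wrap("performance", resistance(wheat, config = config))
  res_sum <- summarise_resistance(res, config)
  yev <- if ("historical" %in% sim$seasons$scenario) {
    yield_evolution(sim$seasons)
  } else NULL

  say("diet", "optimizing diet supply-demand per rotation")
  diet <- stage_wrap("diet", {
    supplies <- rotation_supply(
      dplyr::filter(sim$seasons, .data$scenario == scenarios[[1]]),
      dplyr::filter(lv, .data$scenario == scenarios[[1]]), config)
    purrr::map_dfr(rotations, function(rot) {
      sup <- dplyr::filter(supplies, .data$rotation == rot) |>
        dplyr::select("commodity", "supply")
      mode <- if (rot == "Vegan") "vegan" else "omnivorous"
      fit <- optimize_diet(sup, diet_bounds(mode, config),
                           n_iter = config$diet$n_iter,
                           seed = derive_seed(seed, "diet", rot),
                           config = config)
      tidy.diet_fit(fit) |>
        dplyr::mutate(rotation = rot, people_per_ha = fit$people_per_ha,
                      objective = fit$objective, .before = 1)
    })
  })

  say("stats", "scenario comparisons (Kruskal-Wallis + Dunn)")
  comparisons <- stage_wrap("stats", {
    net <- budgets |>
      dplyr::filter(.data$metric == metrics[[1]]) |>
      compare_groups(net, rotation,
                     subsample_fraction = config$stats$subsample_fraction,
                     seed = seed, config = config)
    leach <- sim$seasons |>
      dplyr::group_by(.data$uid, .data$scenario, .data$rotation) |>
      dplyr::summarise(no3 = mean(.data$no3_leached), .groups = "drop") |>
      compare_groups(no3, rotation,
                     subsample_fraction = config$stats$subsample_fraction,
                     seed = seed, config = config)
    dplyr::bind_rows(
      dplyr::mutate(net$letters, criterion = "net_ghg", .before = 1),
      dplyr::mutate(leach$letters, criterion = "no3_leaching", .before = 1)
    )
  })

  say("multicriteria", "normalizing the criteria panel (BAU = 100)")
  panel <- stage_wrap("multicriteria",
    multicriteria_panel(sim, budgets, stab, res_sum, metrics[[1]]))

  out <- list(
    sites = sim$sites, seasons = sim$seasons, soc = sim$soc,
    livestock = lv, budgets = budgets,
    spei = cls$spei, season_class = cls$season_class,
    productivity = prod, stability = stab,
    resistance = res, resistance_summary = res_sum,
    yield_evolution = yev,
    diet_balance = diet,
    comparisons = comparisons,
    multicriteria = panel
  )
  out <- out[!vapply(out, is.null, logical(1))]

  if (!is.null(out_dir)) {
    say("write", "writing tables to ", out_dir)
    write_outputs(out, out_dir)
  }
  say("done", "elapsed ", format(round(difftime(Sys.time(), t0, units = "secs"), 1)))
  invisible(out)
}

# SPEI fitting + classification across uids/scenarios: calibrate on the
# historical scenario of each uid, apply the same coefficients and thresholds
# to future scenarios of that uid
classify_pipeline <- function(monthly, seasons, config) {
  has_hist <- "historical" %in% monthly$scenario
  spei_all <- list(); class_all <- list(); i <- 0L
  for (id in unique(monthly$uid)) {
    coefs <- NULL; thr <- NULL
    sc_names <- unique(monthly$scenario[monthly$uid == id])
    sc_names <- c(intersect("historical", sc_names),
                  setdiff(sc_names, "historical"))
    for (sc in sc_names) {
      d <- monthly[monthly$uid == id & monthly$scenario == sc, ]
      if (sc == "historical" || !has_hist) {
        sp <- fit_spei(d, window = config$spei$window, config = config)
        coefs <- attr(sp, "coefficients")
        thr <- spei_thresholds(sp$spei[sp$month == 5 & !is.na(sp$spei)])
      } else {
        sp <- fit_spei(d, window = config$spei$window, coefficients = coefs,
                       config = config)
      }
      wheat_years <- sort(unique(
        seasons$year_index[seasons$uid == id & seasons$scenario == sc &
                             seasons$crop == "WW"]))
      cl <- classify_seasons(sp, wheat_years, thresholds = thr)
      i <- i + 1L
      spei_all[[i]] <- dplyr::mutate(sp, uid = id, scenario = sc, .before = 1)
      class_all[[i]] <- dplyr::mutate(cl, uid = id, scenario = sc, .before = 1)
    }
  }
  list(spei = dplyr::bind_rows(spei_all),
       season_class = dplyr::bind_rows(class_all))
}

# criterion panel averaged over climate scenarios, normalized to BAU
multicriteria_panel <- function(sim, budgets, stab, res_sum, metric) {
  soc_mean <- sim$soc |>
    dplyr::group_by(.data$rotation) |>
    dplyr::summarise(value = mean(.data$delta_profile), .groups = "drop") |>
    dplyr::mutate(criterion = "soc_change")
  ghg <- budgets |>
    dplyr::filter(.data$metric == !!metric) |>
    dplyr::group_by(.data$rotation) |>
    dplyr::summarise(value = mean(.data$net), .groups = "drop") |>
    dplyr::mutate(criterion = "net_ghg")
  leach <- sim$seasons |>
    dplyr::group_by(.data$rotation) |>
    dplyr::summarise(value = mean(.data$no3_leached), .groups = "drop") |>
    dplyr::mutate(criterion = "no3_leaching")
  prod_m <- sim$seasons |>
    dplyr::group_by(.data$rotation) |>
    dplyr::summarise(value = mean(.data$yield), .groups = "drop") |>
    dplyr::mutate(criterion = "productivity_mass")
  stab_m <- stab |>
    dplyr::filter(.data$defined, .data$metric == "econ") |>
    dplyr::group_by(.data$rotation) |>
    dplyr::summarise(value = mean(.data$stability), .groups = "drop") |>
    dplyr::mutate(criterion = "stability_econ")
  wet <- res_sum |>
    dplyr::filter(.data$label %in% c("moderate_wet", "extreme_wet")) |>
    dplyr::group_by(.data$rotation) |>
    dplyr::summarise(value = mean(.data$omega_median), .groups = "drop") |>
    dplyr::mutate(criterion = "resistance_wet")
  dplyr::bind_rows(soc_mean, ghg, leach, prod_m, stab_m, wet) |>
    dplyr::select("criterion", "rotation", "value") |>
    multicriteria_normalize()
}

# CSV writer with JSON schema sidecars; schemas are validated against the
# table before writing
write_outputs <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (!is.data.frame(tb)) next
    schema <- lapply(tb, function(col) class(col)[1])
    stopifnot(length(schema) == ncol(tb), all(names(schema) == names(tb)))
    readr::write_csv(tb, file.path(out_dir, paste0(nm, ".csv")))
    writeLines(
      paste0("{", paste0('"', names(schema), '": "', unlist(schema), '"',
                         collapse = ", "), "}"),
      file.path(out_dir, paste0(nm, ".schema.json"))
    )
  }
  invisible(out_dir)
}
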