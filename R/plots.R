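#' Stacked GHG-budget plot
#'
#' Mirrors the canonical budget figure: one stacked bar of signed emission
#' terms per rotation (averaged over sites), with the net budget overlaid as
#' a point, faceted by climate scenario.
#'
#' @param budgets A `ghg_budget` tibble from [assemble_budget()].
#' @return A ggplot object.
#' @export
plot_budget <- function(budgets) {
  terms <- c("co2_soil", "co2_fertilizer", "co2_management",
             "n2o_direct", "n2o_indirect", "ch4_total", "manure_n2o")
  means <- budgets |>
    dplyr::group_by(.data$scenario, .data$rotation, .data$metric) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c(terms, "net")), mean),
                     .groups = "drop")
  long <- means |>
    tidyr::pivot_longer(dplyr::all_of(terms), names_to = "term",
                        values_to = "flux")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rotation)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$flux, fill = .data$term)) +
    ggplot2::geom_point(data = means, ggplot2::aes(y = .data$net),
                        shape = 21, fill = "black", size = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(metric ~ scenario) +
    ggplot2::labs(x = NULL, y = expression(Mg~CO[2]*"-eq"~ha^-1~yr^-1),
                  fill = "term") +
    ggplot2::theme_minimal()
}

#' Yield-evolution plot
#'
#' Per-crop mean yield change relative to the historical climate.
#'
#' @param yev Output of [yield_evolution()].
#' @return A ggplot object.
#' @export
plot_yield_evolution <- function(yev) {
  yev |>
    dplyr::filter(!is.na(.data$change_pct)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$crop, y = .data$change_pct,
                                 fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "yield change vs historical (%)",
                  fill = "scenario") +
    ggplot2::theme_minimal()
}

#' Resistance distribution plot
#'
#' Boxplots of the resistance index by rotation and event class.
#'
#' @param res Output of [resistance()].
#' @param classes Event classes to show (default the wet and dry extremes).
#' @return A ggplot object.
#' @export
plot_resistance <- function(res, classes = c("extreme_dry", "extreme_wet")) {
  res |>
    dplyr::filter(.data$label %in% classes) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$rotation, y = .data$omega,
                                 fill = .data$rotation)) +
    ggplot2::geom_boxplot(outliers = FALSE) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(Omega)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Multi-criteria radar-style panel
#'
#' Dot plot of the BAU-normalized indices per criterion and rotation.
#'
#' @param panel Output of [multicriteria_normalize()] (columns `criterion`,
#'   `rotation`, `index`).
#' @return A ggplot object.
#' @export
plot_multicriteria <- function(panel) {
  ggplot2::ggplot(panel, ggplot2::aes(x = .data$criterion, y = .data$index,
                                      colour = .data$rotation)) +
    ggplot2::geom_point(size = 3, position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "index (BAU = 100; SOC: BAU = -100)",
                  colour = "rotation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.ghg_budget <- function(object, ...) plot_budget(object)

#' @export
autoplot.diet_fit <- function(object, ...) {
  tidy.diet_fit(object) |>
    tidyr::pivot_longer(c("deficit", "surplus"), names_to = "side",
                        values_to = "kcal") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$commodity, y = .data$kcal,
                                 fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "kcal/ha/yr", fill = NULL) +
    ggplot2::theme_minimal()
}
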