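#' Feed supply available to sheep in an integrated rotation
#'
#' Collects, per site x scenario x year, the dry matter harvested for sheep:
#' mown pasture biomass plus cover-crop biomass when the rotation's cover
#' crops are harvested as feed. Rotations without on-farm livestock yield zero
#' intake rows.
#'
#' @param seasons A seasons tibble from [generate_season_outcomes()] /
#'   [simulate_region()].
#' @param config A configuration list.
#' @return A tibble with columns `uid`, `scenario`, `rotation`, `year_index`,
#'   `dm_intake` (kg DM/ha).
#' @export
feed_supply <- function(seasons, config = default_config()) {
  linkage <- purrr::map_chr(
    rlang::set_names(unique(seasons$rotation)),
    function(r) config$rotations[[r]]$livestock_linkage %||% "none"
  )
  cover_fate <- purrr::map_chr(
    rlang::set_names(unique(seasons$rotation)),
    function(r) config$rotations[[r]]$cover_fate %||% "incorporated"
  )
  cover_dm <- config$crops$cover$base_yield * 1000
  seasons |>
    dplyr::mutate(
      on_farm = linkage[.data$rotation] == "on_farm_sheep",
      dm_intake =
        ifelse(.data$on_farm & .data$crop == "GR", .data$yield * 1000, 0) +
        ifelse(.data$on_farm & .data$cover_crop &
                 cover_fate[.data$rotation] == "removed_feed", cover_dm, 0)
    ) |>
    dplyr::group_by(.data$uid, .data$scenario, .data$rotation, .data$year_index) |>
    dplyr::summarise(dm_intake = sum(.data$dm_intake), .groups = "drop")
}

#' Sheep production from dry matter intake
#'
#' Converts dry matter intake into live-weight gain (via a feed-conversion
#' ratio), retail meat (dressing percentage x retail fraction), enteric
#' methane (Tier-1 yield per kg intake), and manure nitrogen and volatile
#' solids (intake-proportional excretion). All relationships are linear, so
#' outputs scale with intake.
#'
#' @param feed A tibble with a `dm_intake` column (kg DM/ha), e.g. from
#'   [feed_supply()]; other columns are carried through.
#' @param params Livestock parameter list (defaults `config$livestock`).
#' @param config A configuration list.
#' @return The input tibble with added columns `lwg` (kg live weight/ha),
#'   `meat_retail` (kg/ha), `ch4_enteric` (kg CH4/ha), `manure_n` (kg N/ha),
#'   `manure_vs` (kg VS/ha).
#' @export
#' @examples
#' sheep_production(tibble::tibble(dm_intake = 1000))
sheep_production <- function(feed, params = config$livestock,
                             config = default_config()) {
  stopifnot(all(c("fcr", "dressing", "retail_fraction", "ch4_yield") %in% names(params)))
  if (any(feed$dm_intake < 0)) stop("negative dry matter intake", call. = FALSE)
  if (any(unlist(params[c("fcr", "dressing", "retail_fraction", "ch4_yield")]) <= 0)) {
    stop("livestock parameters must be positive", call. = FALSE)
  }
  feed |>
    dplyr::mutate(
      lwg = .data$dm_intake / params$fcr,
      meat_retail = .data$lwg * params$dressing * params$retail_fraction,
      ch4_enteric = .data$dm_intake * params$ch4_yield,
      manure_n = .data$dm_intake * params$n_content * (1 - params$n_retention),
      manure_vs = .data$dm_intake * params$vs_per_kg_dmi
    )
}

#' Manure storage and spreading emissions
#'
#' Tier-1 style manure emissions. For an on-farm flock (`context =
#' "icls_full"`) the full chain is counted: storage CH4
#' (`VS x B0 x 0.67 x MCF_storage`), spreading CH4, and direct plus indirect
#' (volatilization) storage N2O. For a specialised crop farm importing manure
#' (`context = "bau_spreading_only"`) the animals are off-farm, so only the
#' CH4 released by manure decomposing on the field is attributed to the farm
#' gate; storage terms are zero.
#'
#' @param manure_n Manure nitrogen handled (kg N).
#' @param manure_vs Manure volatile solids handled (kg VS).
#' @param context `"icls_full"` or `"bau_spreading_only"`.
#' @param params Livestock parameter list (defaults `config$livestock`).
#' @param config A configuration list.
#' @return A tibble with columns `ch4_storage`, `ch4_spreading` (kg CH4),
#'   `n2o_storage_direct`, `n2o_storage_indirect` (kg N2O gas).
#' @export
#' @examples
#' manure_emissions(100, 1000, "icls_full")
manure_emissions <- function(manure_n, manure_vs,
                             context = c("icls_full", "bau_spreading_only"),
                             params = config$livestock,
                             config = default_config()) {
  context <- match.arg(context)
  if (any(manure_n < 0) || any(manure_vs < 0)) {
    stop("manure inputs must be non-negative", call. = FALSE)
  }
  n2o_gas <- 44 / 28
  ch4_spreading <- manure_vs * params$b0 * params$ch4_density * params$mcf_spreading
  if (context == "icls_full") {
    tibble::tibble(
      ch4_storage = manure_vs * params$b0 * params$ch4_density * params$mcf_storage,
      ch4_spreading = ch4_spreading,
      n2o_storage_direct = manure_n * params$ef_direct * n2o_gas,
      n2o_storage_indirect = manure_n * params$frac_volatilized *
        params$ef_indirect * n2o_gas
    )
  } else {
    tibble::tibble(
      ch4_storage = 0 * manure_vs,
      ch4_spreading = ch4_spreading,
      n2o_storage_direct = 0 * manure_n,
      n2o_storage_indirect = 0 * manure_n
    )
  }
}
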