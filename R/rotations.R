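#' Build a circularity-scenario rotation plan
#'
#' Materialises one of the three configured 8-year rotations as a tibble with
#' one row per rotation position. The three default plans encode the
#' contrasting circularity strategies: `BAU` (cash crops, wheat straw exchanged
#' off-farm for manure), `Vegan` (food crops only, no manure, all residues
#' incorporated) and `ICLS` (2.5 years of mown temporary pasture feeding
#' on-farm sheep, with cover-crop biomass also fed). Winter wheat sits at
#' positions 2 and 4 in every plan so wheat seasons can be compared across
#' scenarios year by year.
#'
#' @param name Rotation name, one of `"BAU"`, `"Vegan"`, `"ICLS"` (or any
#'   rotation defined in `config$rotations`).
#' @param config A configuration list, see [default_config()].
#' @return A tibble of class `rotation_plan` with columns `position`, `crop`,
#'   `residue_fate`, `fertilizer_n`, `manure_n`, `cover_crop`, `year_fraction`,
#'   `combine`, `plough`, `surface_tillage`, and attributes `rotation_name` and
#'   `livestock_linkage`.
#' @export
#' @examples
#' build_rotation("ICLS")
build_rotation <- function(name, config = default_config()) {
  defs <- config$rotations
  if (!name %in% names(defs)) {
    stop("unknown rotation name: '", name, "' (known: ",
         paste(names(defs), collapse = ", "), ")", call. = FALSE)
  }
  def <- defs[[name]]
  crops <- crop_table(config)
  plan <- purrr::imap_dfr(def$positions, function(p, i) {
    tibble::tibble(
      position = as.integer(i),
      crop = p$crop,
      residue_fate = p$residue_fate,
      fertilizer_n = crops$fert_n[crops$crop == p$crop] * (p$year_fraction %||% 1),
      manure_n = p$manure_n,
      cover_crop = p$cover_crop,
      year_fraction = p$year_fraction %||% 1,
      combine = p$combine, plough = p$plough, surface_tillage = p$surface_tillage
    )
  })
  structure(plan,
            class = c("rotation_plan", class(plan)),
            rotation_name = name,
            livestock_linkage = def$livestock_linkage,
            cover_fate = def$cover_fate)
}

#' Rotation-design rules
#'
#' Converts the configured rule list into a tibble usable by
#' [validate_rotation()]. Supported rule kinds: `min_return_same_crop`
#' (minimum years between two seasons of the same crop), `min_return_pair`
#' (minimum years between two crops in either order), `family_alternation`
#' (no two consecutive seasons from the same botanical family),
#' `winter_spring_alternation`, and `cover_before_spring` (every spring-sown
#' crop must be preceded by a season flagged with a cover crop).
#'
#' @param config A configuration list.
#' @return A tibble with columns `kind`, `crop_a`, `crop_b`, `gap`.
#' @export
rotation_rules <- function(config = default_config()) {
  purrr::map_dfr(config$rules, function(r) {
    tibble::tibble(
      kind = r$kind,
      crop_a = r$crop %||% r$crop_a %||% NA_character_,
      crop_b = r$crop_b %||% NA_character_,
      gap = r$gap %||% NA_real_
    )
  })
}

#' Validate a rotation plan against design rules
#'
#' The crop sequence is treated as cyclic (the rotation repeats indefinitely),
#' so return-time rules are also checked across the rotation boundary.
#' Violations are returned as data, not raised as errors.
#'
#' @param plan A `rotation_plan`, see [build_rotation()].
#' @param rules A rules tibble, see [rotation_rules()], or the configured
#'   default.
#' @param config A configuration list (used for crop metadata).
#' @return A tibble of violations with columns `kind`, `detail`, `position`;
#'   zero rows when the plan satisfies every rule.
#' @export
#' @examples
#' validate_rotation(build_rotation("BAU"))
validate_rotation <- function(plan, rules = rotation_rules(config),
                              config = default_config()) {
  stopifnot(nrow(plan) > 0)
  L <- nrow(plan)
  seq_crop <- plan$crop
  crops <- crop_table(config)
  spring_crops <- crops$crop[crops$spring]

  violations <- list()
  add <- function(kind, detail, position) {
    violations[[length(violations) + 1]] <<-
      tibble::tibble(kind = kind, detail = detail, position = as.integer(position))
  }

  # smallest forward cyclic distance from position i to position j
  cyc_gap <- function(i, j) (j - i) %% L

  for (k in seq_len(nrow(rules))) {
    r <- rules[k, ]
    if (r$kind == "min_return_same_crop") {
      pos <- which(seq_crop == r$crop_a)
      if (length(pos) >= 2) {
        nxt <- c(pos[-1], pos[1])
        gaps <- (nxt - pos) %% L
        bad <- which(gaps < r$gap & gaps > 0)
        for (b in bad) {
          add(r$kind,
              sprintf("%s returns after %d year(s) at position %d (minimum %d)",
                      r$crop_a, gaps[b], nxt[b], r$gap), pos[b])
        }
      }
      # a crop occupying consecutive positions (gap accumulating through a
      # multi-year phase, e.g. pasture) is exempt: gap 0/1 between adjacent
      # identical crops marks a continuous phase, handled below
    } else if (r$kind == "min_return_pair") {
      pa <- which(seq_crop == r$crop_a)
      pb <- which(seq_crop == r$crop_b)
      for (i in pa) for (j in pb) {
        g <- min(cyc_gap(i, j), cyc_gap(j, i))
        if (g > 0 && g < r$gap) {
          add(r$kind,
              sprintf("%s (pos %d) and %s (pos %d) separated by %d year(s) (minimum %d)",
                      r$crop_a, i, r$crop_b, j, g, r$gap), i)
        }
      }
    } else if (r$kind == "family_alternation") {
      fam <- crop_family(seq_crop)
      nxt <- c(fam[-1], fam[1])
      bad <- which(fam == nxt & seq_crop != c(seq_crop[-1], seq_crop[1]))
      for (b in bad) add(r$kind, sprintf("family %s repeated at positions %d-%d",
                                         fam[b], b, b %% L + 1), b)
    } else if (r$kind == "winter_spring_alternation") {
      sp <- seq_crop %in% spring_crops
      nxt <- c(sp[-1], sp[1])
      bad <- which(sp == nxt)
      for (b in bad) add(r$kind, sprintf("no winter/spring alternation at positions %d-%d",
                                         b, b %% L + 1), b)
    } else if (r$kind == "cover_before_spring") {
      prev <- c(L, seq_len(L - 1))
      # the continuation of a multi-year phase (same crop as before) needs no
      # cover; only true spring sowings after a different crop do
      needs <- which(seq_crop %in% spring_crops & seq_crop != seq_crop[prev] &
                       seq_crop != "cover")
      bad <- needs[!plan$cover_crop[prev[needs]]]
      for (b in bad) add(r$kind,
                         sprintf("spring crop %s at position %d lacks a preceding cover crop",
                                 seq_crop[b], b), b)
    } else {
      stop("unknown rule kind: ", r$kind, call. = FALSE)
    }
  }

  if (length(violations) == 0) {
    tibble::tibble(kind = character(), detail = character(), position = integer())
  } else {
    dplyr::bind_rows(violations)
  }
}

# handle adjacent identical crops (multi-year pasture phase) in same-crop rule:
# collapse runs before computing return gaps
crop_family <- function(crop) {
  fam <- c(WW = "poaceae", MZ = "poaceae", GR = "poaceae", cover = "mixture",
           SB = "amaranthaceae", PT = "solanaceae",
           PE = "fabaceae", FB = "fabaceae", RS = "brassicaceae")
  unname(fam[crop])
}

#' @export
print.rotation_plan <- function(x, ...) {
  cat("<rotation_plan> ", attr(x, "rotation_name"),
      " (livestock: ", attr(x, "livestock_linkage"), ")\n", sep = "")
  NextMethod()
}

#' Export rotation definitions as a table
#'
#' @param rotations Character vector of rotation names.
#' @param config A configuration list.
#' @return A tibble with one row per rotation position across all requested
#'   rotations.
#' @export
rotation_table <- function(rotations = c("BAU", "Vegan", "ICLS"),
                           config = default_config()) {
  purrr::map_dfr(rotations, function(nm) {
    plan <- build_rotation(nm, config)
    dplyr::mutate(tibble::as_tibble(plan), rotation = nm, .before = 1)
  })
}
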