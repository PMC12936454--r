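#' Flag outliers by the interquartile-range rule
#'
#' A value is an outlier when it falls below Q1 - k x IQR or above
#' Q3 + k x IQR (quartiles by linear interpolation, quantile type 7; the
#' interval is closed, so with IQR = 0 identical values are never flagged).
#'
#' @param x Numeric vector (length >= 4).
#' @param k IQR multiplier (default 1.5).
#' @return Logical vector, `TRUE` where `x` is an outlier.
#' @export
#' @examples
#' iqr_outliers(c(1:9, 100))
iqr_outliers <- function(x, k = 1.5) {
  stopifnot(length(x) >= 4, k > 0)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' Dunn's rank-based pairwise comparisons
#'
#' Post-hoc pairwise z tests on the joint ranking after a Kruskal-Wallis
#' analysis, with tie correction:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)) where
#' T = sum(t^3 - t) / (12 (N - 1)) over tie groups.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (coerced to factor).
#' @param p_adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return A tibble with one row per pair: `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  n <- tabulate(groups)
  if (any(n == 0)) stop("empty group", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(seq_along(lv), 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  tibble::tibble(
    group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
    z = res["z", ], p = res["p", ],
    p_adj = stats::p.adjust(res["p", ], method = p_adjust)
  )
}

# compact letter display by insert-and-absorb on the non-significance graph
letter_display <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group1[k]; b <- sig_pairs$group2[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[i] && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            !(all(new_sets[[j]] %in% new_sets[[i]]) && i < j)) {
          keep[i] <- FALSE
        }
      }
    }
    sets <- unique(new_sets[keep])
    sets <- sets[lengths(sets) > 0]
  }
  letters_vec <- rlang::set_names(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) letters_vec[g] <- paste0(letters_vec[g], letters[i])
  }
  letters_vec
}

#' Compare scenario groups with subsampled rank tests
#'
#' The study-scale comparison: values are subsampled at a configured fraction
#' (the same record indices in every group when group sizes match, emulating
#' paired site subsampling), a Kruskal-Wallis test is run across groups, and
#' Dunn's pairwise comparisons are summarised as grouping letters (groups
#' sharing a letter are not significantly different at `p_threshold`).
#'
#' @param data A tibble.
#' @param value Column with the response (tidy-eval).
#' @param group Column with the grouping (tidy-eval).
#' @param subsample_fraction Fraction of records kept (default from config,
#'   1/100; 1 reproduces the full-data test).
#' @param seed Integer seed for the subsample.
#' @param config A configuration list (p threshold, adjustment).
#' @return An object of class `group_comparison`: list with `kruskal`
#'   (htest), `pairs` (Dunn tibble), `letters` (tibble `group`, `letter`,
#'   `median`), `n_used`. Supports [generics::tidy()] / [generics::glance()].
#' @export
compare_groups <- function(data, value, group,
                           subsample_fraction = config$stats$subsample_fraction,
                           seed = 1, config = default_config()) {
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1)
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  df <- tibble::tibble(
    value = dplyr::pull(data, !!value),
    group = factor(dplyr::pull(data, !!group))
  )
  df <- df[!is.na(df$value), ]
  if (nlevels(droplevels(df$group)) < 2) {
    stop("need at least two groups", call. = FALSE)
  }

  if (subsample_fraction < 1) {
    sizes <- table(df$group)
    if (length(unique(sizes)) == 1) {
      # matched subsampling: same indices within each group
      n_g <- unique(sizes)
      n_keep <- max(1, round(n_g * subsample_fraction))
      idx <- with_seed_(derive_seed(seed, "subsample"),
                        sample.int(n_g, n_keep))
      df <- df |>
        dplyr::group_by(.data$group) |>
        dplyr::slice(idx) |>
        dplyr::ungroup()
    } else {
      df <- with_seed_(derive_seed(seed, "subsample"), {
        df |>
          dplyr::group_by(.data$group) |>
          dplyr::slice_sample(prop = subsample_fraction) |>
          dplyr::ungroup()
      })
    }
    if (any(table(droplevels(df$group)) == 0)) {
      stop("a group is empty after subsampling", call. = FALSE)
    }
  }

  kw <- stats::kruskal.test(df$value, df$group)
  pairs <- dunn_test(df$value, df$group, p_adjust = config$stats$p_adjust)
  sig <- pairs[pairs$p_adj < config$stats$p_threshold, ]
  lets <- letter_display(levels(droplevels(df$group)), sig)
  med <- tapply(df$value, droplevels(df$group), stats::median)
  structure(
    list(
      kruskal = kw,
      pairs = pairs,
      letters = tibble::tibble(group = names(lets), letter = unname(lets),
                               median = as.numeric(med[names(lets)])),
      n_used = nrow(df)
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> Kruskal-Wallis chi-sq =",
      format(unname(x$kruskal$statistic), digits = 4),
      ", p =", format(x$kruskal$p.value, digits = 3),
      ", n =", x$n_used, "\n")
  print(x$letters)
  invisible(x)
}

#' Tidy the pairwise comparisons of a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return The Dunn pairwise tibble.
#' @export
tidy.group_comparison <- function(x, ...) x$pairs

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble with the Kruskal-Wallis statistic, df, p-value
#'   and sample size used.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$kruskal$statistic),
    df = unname(x$kruskal$parameter),
    p.value = x$kruskal$p.value,
    n = x$n_used
  )
}
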