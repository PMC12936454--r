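#' Monthly climatic water balance
#'
#' Aggregates a daily weather series into calendar-month sums of precipitation
#' minus reference evapotranspiration (D = P - PET, mm), the quantity the
#' standardized drought index is built on.
#'
#' @param weather A daily weather tibble from [generate_weather()] (columns
#'   `year`, `month`, `precip`, `pet`; `uid`/`scenario` carried through when
#'   present).
#' @return A tibble with one row per year x month and column `d` (mm).
#' @export
monthly_balance <- function(weather) {
  counts <- weather |>
    dplyr::count(.data$year, .data$month)
  expected <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  if (any(counts$n != expected[counts$month])) {
    stop("daily series has incomplete months", call. = FALSE)
  }
  keys <- intersect(c("uid", "scenario"), names(weather))
  weather |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "year", "month")))) |>
    dplyr::summarise(d = sum(.data$precip - .data$pet), .groups = "drop") |>
    dplyr::arrange(.data$year, .data$month)
}

#' Fit and apply the 3-month standardized water-balance index (SPEI-3)
#'
#' Computes the rolling `window`-month sum of the monthly balance and
#' standardizes it per calendar month through a three-parameter log-logistic
#' distribution fitted by unbiased probability-weighted moments on a
#' calibration window, mapped through the standard normal quantile function.
#' A future-scenario series is standardized with the *same* coefficients
#' (pass them via `coefficients`), so the index measures change relative to
#' the historical climate rather than re-centering on the new one.
#'
#' @param d_monthly A tibble from [monthly_balance()] for a single site and
#'   scenario (columns `year`, `month`, `d`).
#' @param window Aggregation window in months (default 3).
#' @param calibration_years Years (values of `d_monthly$year`) defining the
#'   calibration window; default all years. Ignored when `coefficients` is
#'   supplied.
#' @param coefficients Optional coefficient tibble from a previous fit
#'   (attribute `"coefficients"` of a fitted series), used to standardize a
#'   new series without recalibration.
#' @param config A configuration list (minimum calibration length).
#' @return A tibble with columns `year`, `month`, `d_roll`, `spei`, carrying
#'   the per-calendar-month log-logistic coefficients in attribute
#'   `"coefficients"`. The first `window - 1` months have `NA` index values.
#' @export
fit_spei <- function(d_monthly, window = 3, calibration_years = NULL,
                     coefficients = NULL, config = default_config()) {
  d_monthly <- dplyr::arrange(d_monthly, .data$year, .data$month)
  n <- nrow(d_monthly)
  if (n < window) stop("series shorter than the aggregation window", call. = FALSE)
  droll <- stats::filter(d_monthly$d, rep(1, window), sides = 1)
  droll <- as.numeric(droll)

  out <- tibble::tibble(
    year = d_monthly$year, month = d_monthly$month,
    d_roll = droll, spei = NA_real_
  )

  if (is.null(coefficients)) {
    cal_years <- calibration_years %||% unique(d_monthly$year)
    min_years <- config$spei$min_calibration_years %||% 20
    if (length(unique(cal_years)) < min_years) {
      stop("calibration window must span at least ", min_years, " years",
           call. = FALSE)
    }
    coefficients <- purrr::map_dfr(1:12, function(m) {
      idx <- which(out$month == m & out$year %in% cal_years & !is.na(droll))
      x <- droll[idx]
      if (length(x) < 4) {
        return(tibble::tibble(month = m, xi = NA_real_, alpha = NA_real_,
                              k = NA_real_))
      }
      if (stats::sd(x) == 0) {
        stop("degenerate (constant) water balance in calendar month ", m,
             call. = FALSE)
      }
      fit <- loglogistic_lmom(x)
      tibble::tibble(month = m, xi = fit$xi, alpha = fit$alpha, k = fit$k)
    })
  }

  for (m in 1:12) {
    cf <- coefficients[coefficients$month == m, ]
    if (nrow(cf) == 0 || is.na(cf$alpha)) next
    idx <- which(out$month == m & !is.na(droll))
    p <- loglogistic_cdf(droll[idx], cf$xi, cf$alpha, cf$k)
    out$spei[idx] <- stats::qnorm(p)
  }
  attr(out, "coefficients") <- coefficients
  out
}

# Unbiased probability-weighted moments b0, b1, b2 (estimating
# E[X (1 - F)^s]) of an ascending sample.
pwm_ub <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  c(b0 = mean(x),
    b1 = sum(x * (n - i)) / (n * (n - 1)),
    b2 = sum(x * (n - i) * (n - i - 1)) / (n * (n - 1) * (n - 2)))
}

# Log-logistic (generalized-logistic parameterization) fitted by L-moments
# from unbiased PWMs, the convention of the reference SPEI implementation.
# The shape k = -tau3 covers both skew directions, which matters because an
# aggregated water balance can be nearly symmetric; k > 0 mirrors the
# classical right-skewed log-logistic (beta = -1/k), k ~ 0 is the logistic
# limit. Location xi, scale alpha, shape k.
loglogistic_lmom <- function(x) {
  b <- pwm_ub(x)
  l1 <- b[["b0"]]
  l2 <- b[["b0"]] - 2 * b[["b1"]]        # lambda2 from E[X(1-F)^s] moments
  l3 <- b[["b0"]] - 6 * b[["b1"]] + 6 * b[["b2"]]
  if (l2 <= 0) stop("degenerate sample: zero or negative L-scale", call. = FALSE)
  t3 <- l3 / l2
  k <- -t3
  if (abs(k) < 1e-8) {
    list(xi = l1, alpha = l2, k = 0)
  } else {
    lam <- k * pi / sin(k * pi)          # Gamma(1+k) Gamma(1-k)
    alpha <- l2 / lam
    xi <- l1 - alpha * (1 - lam) / k
    list(xi = xi, alpha = alpha, k = k)
  }
}

loglogistic_cdf <- function(x, xi, alpha, k) {
  if (abs(k) < 1e-8) {
    y <- (x - xi) / alpha
  } else {
    arg <- 1 - k * (x - xi) / alpha
    # outside the support: probability saturates at the corresponding tail
    y <- rep(if (k > 0) Inf else -Inf, length(x))
    inside <- arg > 0
    y[inside] <- -log(arg[inside]) / k
  }
  p <- 1 / (1 + exp(-y))
  pmin(pmax(p, 1e-7), 1 - 1e-7)
}

# quantile via the inverse CDF (used in tests and simulation)
loglogistic_quantile <- function(p, xi, alpha, k) {
  y <- log(p / (1 - p))
  if (abs(k) < 1e-8) xi + alpha * y
  else xi + alpha * (1 - exp(-k * y)) / k
}

#' Event-class thresholds from a historical index series
#'
#' Empirical quantiles (type 7) of the historical-period index values used to
#' label seasons: below q0.10 extreme dry, q0.10-q0.25 moderately dry,
#' q0.25-q0.75 normal, q0.75-q0.90 moderately wet, above q0.90 extreme wet.
#'
#' @param x Numeric vector of historical index values (e.g. the May-dated
#'   SPEI-3 of each historical year for one site).
#' @return A named numeric vector `q10`, `q25`, `q75`, `q90`.
#' @export
spei_thresholds <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  if (any(diff(q) <= 0)) {
    stop("degenerate index distribution: thresholds are not strictly increasing",
         call. = FALSE)
  }
  c(q10 = q[1], q25 = q[2], q75 = q[3], q90 = q[4])
}

#' Classify seasons by their March-May drought index
#'
#' Labels each season by the SPEI-3 value dated May (the aggregation window
#' covering March to May, the period preceding wheat flowering) against
#' historical-period thresholds. Values falling exactly on a threshold go to
#' the more extreme class.
#'
#' @param spei A fitted index tibble from [fit_spei()].
#' @param seasons Integer vector of years (values of `spei$year`) to classify,
#'   default all years present.
#' @param thresholds Named vector from [spei_thresholds()]. When `NULL`,
#'   thresholds are computed from the May values of `spei` itself (appropriate
#'   only for the historical series).
#' @param month Index month defining the season window (default 5 = May,
#'   closing the March-May window).
#' @return A tibble with columns `year`, `spei`, `label`; `label` is a factor
#'   with levels `extreme_dry`, `moderate_dry`, `normal`, `moderate_wet`,
#'   `extreme_wet`.
#' @export
classify_seasons <- function(spei, seasons = NULL, thresholds = NULL, month = 5) {
  may <- spei[spei$month == month & !is.na(spei$spei), c("year", "spei")]
  if (is.null(thresholds)) thresholds <- spei_thresholds(may$spei)
  seasons <- seasons %||% may$year
  missing <- setdiff(seasons, may$year)
  if (length(missing) > 0) {
    stop("seasons outside the index series: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sel <- may[match(seasons, may$year), ]
  lab <- event_label(sel$spei, thresholds)
  tibble::tibble(year = sel$year, spei = sel$spei, label = lab)
}

event_label <- function(x, thresholds) {
  lv <- c("extreme_dry", "moderate_dry", "normal", "moderate_wet", "extreme_wet")
  lab <- dplyr::case_when(
    x <= thresholds[["q10"]] ~ "extreme_dry",
    x <= thresholds[["q25"]] ~ "moderate_dry",
    x >= thresholds[["q90"]] ~ "extreme_wet",
    x >= thresholds[["q75"]] ~ "moderate_wet",
    TRUE ~ "normal"
  )
  factor(lab, levels = lv)
}
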