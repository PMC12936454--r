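# small weather builder: given per-month daily precip/pet constants
month_weather <- function(n_years, precip_daily, pet_daily) {
  mlen <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  month <- rep(rep(1:12, mlen), n_years)
  tibble::tibble(
    year = rep(seq_len(n_years), each = 365),
    month = month,
    precip = precip_daily[month],
    pet = pet_daily[month]
  )
}

test_that("monthly balance sums P - PET per calendar month", {
  w <- month_weather(2, rep(2, 12), rep(2, 12))
  d <- monthly_balance(w)
  expect_equal(nrow(d), 24)
  expect_true(all(d$d == 0))

  # one month with P = 60, PET = 100 -> D = -40
  w2 <- month_weather(1, c(60 / 31, rep(2, 11)), c(100 / 31, rep(2, 11)))
  d2 <- monthly_balance(w2)
  expect_equal(d2$d[d2$month == 1], -40)

  # incomplete months are rejected
  expect_error(monthly_balance(w[-1, ]), "incomplete months")
})

test_that("the rolling 3-month aggregation equals direct window sums", {
  cfg <- default_config()
  site <- generate_sites(1, seed = 4)
  w <- generate_weather(site, cfg$scenarios$historical, 3, seed = 4)
  d <- monthly_balance(w)
  sp <- fit_spei(d, window = 3,
                 config = modifyList(cfg, list(spei = list(min_calibration_years = 3))))
  for (i in c(3, 10, 25, 36)) {
    expect_equal(sp$d_roll[i], sum(d$d[(i - 2):i]))
  }
  expect_true(all(is.na(sp$spei[1:2])))
})

test_that("the log-logistic L-moment fit recovers known parameters (both skews)", {
  cases <- list(
    list(xi = 5, alpha = 10, k = -0.25),   # right-skewed (classic log-logistic)
    list(xi = -40, alpha = 25, k = 0.2),   # left-skewed
    list(xi = 0, alpha = 1, k = 0)         # symmetric logistic limit
  )
  withr::with_seed(17, {
    for (cs in cases) {
      x <- rglo(4000, cs$xi, cs$alpha, cs$k)
      fit <- agrocycle:::loglogistic_lmom(x)
      expect_equal(fit$xi, cs$xi, tolerance = 0.1 * cs$alpha)
      expect_equal(fit$alpha, cs$alpha, tolerance = 0.1 * cs$alpha)
      expect_equal(fit$k, cs$k, tolerance = 0.06)
      # CDF round-trip through the quantile function
      p <- c(0.05, 0.25, 0.5, 0.9)
      q <- agrocycle:::loglogistic_quantile(p, cs$xi, cs$alpha, cs$k)
      expect_equal(agrocycle:::loglogistic_cdf(q, cs$xi, cs$alpha, cs$k), p,
                   tolerance = 1e-6)
    }
  })
})

test_that("the calibrated index is approximately standard normal", {
  cfg <- default_config()
  site <- generate_sites(1, seed = 3)
  w <- generate_weather(site, cfg$scenarios$historical, 30, seed = 3)
  sp <- fit_spei(monthly_balance(w))
  expect_lt(abs(mean(sp$spei, na.rm = TRUE)), 0.1)
  expect_gt(stats::sd(sp$spei, na.rm = TRUE), 0.85)
  expect_lt(stats::sd(sp$spei, na.rm = TRUE), 1.15)
  # the fitted median of a calendar month maps to index 0
  cf <- attr(sp, "coefficients")
  cf5 <- cf[cf$month == 5, ]
  med <- agrocycle:::loglogistic_quantile(0.5, cf5$xi, cf5$alpha, cf5$k)
  p <- agrocycle:::loglogistic_cdf(med, cf5$xi, cf5$alpha, cf5$k)
  expect_equal(stats::qnorm(p), 0, tolerance = 1e-6)
})

test_that("a uniformly drier series standardized with frozen coefficients shifts negative", {
  cfg <- default_config()
  site <- generate_sites(1, seed = 6)
  w <- generate_weather(site, cfg$scenarios$historical, 25, seed = 6)
  d <- monthly_balance(w)
  sp_hist <- fit_spei(d)
  d_dry <- dplyr::mutate(d, d = d - 60)
  sp_dry <- fit_spei(d_dry, coefficients = attr(sp_hist, "coefficients"))
  ok <- !is.na(sp_hist$spei)
  expect_true(all(sp_dry$spei[ok] < sp_hist$spei[ok]))
  expect_lt(mean(sp_dry$spei, na.rm = TRUE), -0.5)
})

test_that("season classification respects thresholds and boundary-to-extreme ties", {
  thr <- c(q10 = -1.28, q25 = -0.67, q75 = 0.67, q90 = 1.28)
  lab <- agrocycle:::event_label(c(-2, -1.28, -1, -0.67, 0, 0.67, 1, 1.28, 2), thr)
  expect_equal(as.character(lab),
               c("extreme_dry", "extreme_dry", "moderate_dry", "moderate_dry",
                 "normal", "moderate_wet", "moderate_wet", "extreme_wet",
                 "extreme_wet"))
})

test_that("class frequencies on the calibration window match the quantile construction", {
  cfg <- default_config()
  site <- generate_sites(1, seed = 12)
  w <- generate_weather(site, cfg$scenarios$historical, 30, seed = 12)
  sp <- fit_spei(monthly_balance(w))
  cl <- classify_seasons(sp)
  freq <- table(cl$label) / nrow(cl)
  target <- c(extreme_dry = 0.10, moderate_dry = 0.15, normal = 0.50,
              moderate_wet = 0.15, extreme_wet = 0.10)
  # finite-sample tolerance: within 2/30 of the construction targets
  expect_true(all(abs(freq[names(target)] - target) <= 2 / 30 + 1e-9))
})

test_that("classification is leakage-free: future data never moves historical labels", {
  cfg <- default_config()
  site <- generate_sites(1, seed = 8)
  w <- generate_weather(site, cfg$scenarios$historical, 24, seed = 8)
  d <- monthly_balance(w)
  sp <- fit_spei(d)
  thr <- spei_thresholds(sp$spei[sp$month == 5 & !is.na(sp$spei)])
  base_labels <- classify_seasons(sp, thresholds = thr)

  # future decades appended: same coefficients, same thresholds
  plus4 <- cfg$scenarios$plus4
  plus4$esm_label <- cfg$scenarios$historical$esm_label
  w_fut <- generate_weather(site, plus4, 24, seed = 8)
  d_fut <- monthly_balance(w_fut)
  sp_fut <- fit_spei(d_fut, coefficients = attr(sp, "coefficients"))
  fut_labels <- classify_seasons(sp_fut, thresholds = thr)
  # historical labels recomputed after seeing the future: identical
  relabeled <- classify_seasons(sp, thresholds = thr)
  expect_identical(base_labels, relabeled)
  # and the drier/wetter future uses historical yardsticks (labels exist)
  expect_equal(nrow(fut_labels), 24)

  # asking for seasons outside coverage errors
  expect_error(classify_seasons(sp, seasons = 99), "outside")
})

test_that("calibration shorter than the configured minimum is rejected", {
  cfg <- default_config()
  site <- generate_sites(1, seed = 4)
  w <- generate_weather(site, cfg$scenarios$historical, 10, seed = 4)
  expect_error(fit_spei(monthly_balance(w)), "at least 20 years")
})
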