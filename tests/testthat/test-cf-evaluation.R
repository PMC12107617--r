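test_that("records land in the printed bins, gaps stay unbinned", {
  recs <- data.frame(
    subject_id = "X", study = "C208", arm = "active",
    t_weeks = c(-1 / 7, 0, 1, 1.5, 2, 3, 3.5, 4, 8, 12, 16, 20, 24),
    ctime_h = 10, occasion_id = paste0("o", 1:13), replicate = 1L,
    hr_bpm = 75, qt_ms = 380, conc_m2 = 0, stringsAsFactors = FALSE)
  out <- assign_bins(recs)
  expect_equal(as.character(out$bin),
               c("pretreatment", "wk0-1", "wk0-1", NA, "wk2-3", "wk2-3",
                 "wk3-4", "wk3-4", "wk5-8", "wk9-12", "wk13-20", "wk13-20",
                 "wk20-24"))
})

make_bin_data <- function(n, slope, intercept = 400, noise = 0, seed = 1) {
  set.seed(seed)
  hr <- rnorm(n, 78, 9)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)), study = "C208",
    arm = "active", t_weeks = 0.5, ctime_h = 10,
    occasion_id = sprintf("o%03d", seq_len(n)), replicate = 1L,
    hr_bpm = hr, qt_ms = 380, conc_m2 = 0,
    qtc = intercept + slope * hr + rnorm(n, 0, noise),
    stringsAsFactors = FALSE)
}

test_that("bin regression recovers exact lines and flags degenerate bins", {
  dat <- make_bin_data(50, slope = -0.5)
  res <- suppressWarnings(bin_regression(dat, "qtc"))
  expect_equal(nrow(res), 1L)
  expect_equal(res$slope, -0.5, tolerance = 1e-10)
  expect_equal(res$r2, 1)
  # constant QTc: slope and r2 are 0
  dat$qtc <- 411
  res0 <- suppressWarnings(bin_regression(dat, "qtc"))
  expect_equal(res0$slope, 0)
  expect_equal(res0$r2, 0)
  # no HR spread: bin skipped with a warning
  dat$hr_bpm <- 70
  expect_warning(bin_regression(dat, "qtc"), "no HR spread")
  # < 3 records: skipped
  expect_warning(bin_regression(make_bin_data(2, 0), "qtc"), "fewer than 3")
})

test_that("bin regression equals the normal-equations oracle", {
  dat <- make_bin_data(40, slope = -0.3, noise = 5, seed = 9)
  res <- suppressWarnings(bin_regression(dat, "qtc", se_type = "ols"))
  # hand-rolled normal equations
  x <- dat$hr_bpm; y <- dat$qtc; n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  e <- y - a - b * x
  se <- sqrt(sum(e^2) / (n - 2) / sxx)
  expect_equal(res$slope, b, tolerance = 1e-10)
  expect_equal(res$intercept, a, tolerance = 1e-10)
  expect_equal(res$se, se, tolerance = 1e-10)
  # point estimates are identical under cluster-robust standard errors
  res_cl <- suppressWarnings(bin_regression(dat, "qtc", se_type = "cluster"))
  expect_equal(res_cl$slope, b, tolerance = 1e-10)
  # with one record per subject, CR0 SE times (g-1)/g equals HC0-type SE
  u <- (x - mean(x)) * e / sxx
  expect_equal(res_cl$se, sqrt(sum(u^2) * n / (n - 1)), tolerance = 1e-10)
})

test_that("a mismatched constant exponent shows up as a significant slope", {
  # QT generated with the pretreatment exponent, corrected with 0.33:
  # undercorrection leaves a negative QTc-HR slope at treatment start
  set.seed(4)
  n <- 500
  hr <- rnorm(n, 80, 10)
  dat <- make_bin_data(n, 0)
  dat$hr_bpm <- hr
  dat$qt_ms <- 400 * rr_from_hr(hr)^0.4081 * exp(rnorm(n, 0, 0.02))
  dat$qtc <- correct_qt(dat$qt_ms, hr, spec = "fridericia")
  res <- suppressWarnings(bin_regression(dat, "qtc"))
  expect_lt(res$hi95, 0)
  # corrected with the generating exponent the slope CI covers 0
  dat$qtc <- correct_qt(dat$qt_ms, hr, spec = "olliaro")
  res0 <- suppressWarnings(bin_regression(dat, "qtc"))
  expect_true(res0$lo95 < 0 && res0$hi95 > 0)
})

fake_bins <- function(slopes, ses, mids = NULL) {
  k <- length(slopes)
  data.frame(bin = paste0("b", seq_len(k)),
             midpoint = if (is.null(mids)) seq(0, 24, length.out = k)
                        else mids,
             n = 100, slope = slopes, intercept = 0, se = ses,
             lo95 = slopes - 2 * ses, hi95 = slopes + 2 * ses, r2 = 0.1,
             stringsAsFactors = FALSE)
}

test_that("slope trend handles flat, equal-weight and rescaled-weight cases", {
  bins <- fake_bins(rep(0.25, 5), rep(0.05, 5))
  tr <- slope_trend(bins)
  expect_equal(tr$intercept, 0.25, tolerance = 1e-12)
  expect_equal(tr$trend, 0, tolerance = 1e-12)
  # equal SEs reduce WLS to OLS
  bins2 <- fake_bins(c(0.1, 0.3, 0.2, 0.5, 0.4), rep(0.07, 5))
  tr2 <- slope_trend(bins2)
  ols <- lm(slope ~ midpoint, data = bins2)
  expect_equal(tr2$trend, unname(coef(ols)[2]), tolerance = 1e-12)
  # rescaling all SEs by a constant changes nothing
  bins3 <- bins2; bins3$se <- bins3$se * 7
  tr3 <- slope_trend(bins3)
  expect_equal(tr3$trend, tr2$trend, tolerance = 1e-12)
  expect_equal(tr3$trend_ci, tr2$trend_ci, tolerance = 1e-12)
  expect_error(slope_trend(fake_bins(c(0, 0.1), c(1, 1))), "3 usable bins")
})

test_that("matched-CF simulation nulls both steps of the evaluation", {
  trial <- simulate_trial(cohort_design(n_subjects = 200), hr_model_spec(),
                          seed = 55)
  ev <- evaluate_corrections(trial, methods = c("tbt", "fridericia",
                                                "bazett"))
  m <- ev$methods$tbt
  expect_equal(m$n_bins, 8L)
  expect_gte(m$n_cover_zero, 7L)
  expect_true(m$trend$trend_ci[1] <= 0 && m$trend$trend_ci[2] >= 0)
  # the mismatched constant corrections show their published signatures
  expect_lt(ev$methods$fridericia$trend$intercept_ci[2], 0)
  expect_gt(ev$methods$bazett$trend$intercept_ci[1], 0)
  # r2 near zero for the matched correction in every bin
  expect_true(all(m$bins$r2 < 0.1))
})
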