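test_that("cohort covariates match the published medians, and seeds reproduce", {
  d <- cohort_design(n_subjects = 440)
  cohort <- make_cohort(d, seed = 21)
  expect_equal(median(cohort$age_y), 33, tolerance = 0.1)       # ~10%
  expect_equal(median(cohort$weight_kg), 55, tolerance = 0.1)
  expect_equal(median(cohort$albumin_gL), 35, tolerance = 0.1)
  expect_equal(median(cohort$ttp_mgit_h), 230.5, tolerance = 0.15)
  expect_true(all(cohort$age_y >= 18 & cohort$age_y <= 68))
  expect_true(all(cohort$ttp_mgit_h >= 56 & cohort$ttp_mgit_h <= 1008))
  expect_true(all(cohort$arm[cohort$study == "C209"] == "active"))
  expect_identical(make_cohort(d, seed = 21), cohort)
  # degenerate design collapses to the medians exactly
  d0 <- qtctbt:::reference_covariate_design(3, placebo_fraction = 1)
  c0 <- make_cohort(d0, seed = 1)
  expect_equal(c0$weight_kg, rep(56, 3))
})

test_that("M2 exposure follows the accumulation curve anchored at 300 ng/mL", {
  d <- cohort_design(n_subjects = 1,
                     exposure = list(css_mean = 600, css_cv = 0,
                                     t_acc_weeks = 2, dist = "lognormal",
                                     css_range = c(0, 8000)))
  subj <- list(arm = "active")
  expect_equal(simulate_m2_profile(subj, 0, d), 0)
  expect_equal(simulate_m2_profile(subj, 2, d), 300)  # week-2 mean anchor
  expect_equal(simulate_m2_profile(subj, 1e6, d), 600)
  expect_equal(simulate_m2_profile(subj, -0.5, d), 0)
  expect_equal(simulate_m2_profile(list(arm = "placebo"), c(2, 8), d),
               c(0, 0))
  # lognormal subject scale preserves the population mean
  set.seed(2)
  d$exposure$css_cv <- 0.45
  css <- qtctbt:::draw_css(d$exposure, 2e4)
  expect_equal(mean(css), 600, tolerance = 0.02)
})

test_that("with all variances zero the simulator reproduces predict_hr exactly", {
  truth <- reduced_iiv_spec(keep = character(0))
  truth$sigma_prop <- 0; truth$sigma_add <- 0
  design <- qtctbt:::reference_covariate_design(4, placebo_fraction = 1)
  cohort <- make_cohort(design, seed = 3)
  recs <- simulate_hr_observations(cohort, truth, design, seed = 4)
  pred <- predict_hr(cohort[1, ], truth, recs$t_weeks[recs$subject_id ==
                       cohort$subject_id[1]],
                     recs$ctime_h[recs$subject_id == cohort$subject_id[1]],
                     recs$conc_m2[recs$subject_id == cohort$subject_id[1]])
  expect_equal(recs$hr_bpm[recs$subject_id == cohort$subject_id[1]], pred)
})

test_that("degenerate model at the references gives the typical values", {
  truth <- reduced_iiv_spec(keep = character(0), amp24 = 0, amp12 = 0)
  truth$sigma_prop <- 0; truth$sigma_add <- 0
  base_design <- qtctbt:::reference_covariate_design(2, placebo_fraction = 1)
  at_t <- function(t) {
    d <- base_design
    d$visits <- data.frame(t_weeks = t, assessment = "predose",
                           n_replicates = 1L)
    cohort <- make_cohort(d, seed = 1)
    simulate_hr_observations(cohort, truth, d, seed = 2)$hr_bpm
  }
  expect_equal(at_t(0), rep(78.2, 2))
  expect_equal(at_t(1e7), rep(73.1, 2))
})

test_that("simulated IIV magnitudes satisfy the log-normal CV identity", {
  spec <- hr_model_spec()
  set.seed(31)
  E <- qtctbt:::draw_etas(spec, 1e4)
  cv_emp <- sd(exp(E[, "hr_base"])) / mean(exp(E[, "hr_base"]))
  expect_equal(cv_emp, 0.15, tolerance = 0.05)
  expect_equal(cor(E[, "hr_base"], E[, "hr_rec"]), 0.41, tolerance = 0.08)
  expect_equal(cor(E[, "prop"], E[, "add"]), 0.38, tolerance = 0.08)
})

test_that("QT simulation embodies the true QT-RR power law", {
  d <- cohort_design(n_subjects = 1,
                     qt_truth = list(qtc0_ms = 400, qtc0_cv = 0,
                                     sigma_qt = 0, cf = correction_spec("tbt")))
  recs <- data.frame(subject_id = "X", study = "C208", arm = "active",
                     t_weeks = c(0, 0, 12), ctime_h = 10,
                     occasion_id = c("o1", "o2", "o3"), replicate = 1L,
                     hr_bpm = c(60, 90, 90), qt_ms = NA_real_, conc_m2 = 0,
                     stringsAsFactors = FALSE)
  out <- simulate_qt_observations(recs, d, seed = 1)
  expect_equal(out$qt_ms[1], 400)                      # RR = 1 s
  expect_equal(out$qt_ms[2], 400 * (2 / 3)^0.4081)     # ~339.0 ms
  # correcting with the generating CF recovers QTc0 exactly
  back <- correct_qt(out$qt_ms, out$hr_bpm, out$t_weeks, "tbt")
  expect_equal(back, rep(400, 3), tolerance = 1e-12)
})

test_that("trial simulation is reproducible end-to-end", {
  d <- cohort_design(n_subjects = 8)
  a <- simulate_trial(d, hr_model_spec(), seed = 77)
  b <- simulate_trial(d, hr_model_spec(), seed = 77)
  expect_identical(a$records, b$records)
  expect_true(all(a$records$hr_bpm > 0))
  expect_true(all(table(a$records$occasion_id) == 3))
})
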