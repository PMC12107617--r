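spec <- hr_model_spec()

test_that("asymptotic time effect hits its anchor points", {
  expect_equal(time_effect(spec, 0), 0)
  # half the total change after one half-life
  expect_equal(time_effect(spec, 7.74), (73.1 - 78.2) / 2)
  expect_equal(time_effect(spec, 1e9), 73.1 - 78.2)
  # pretreatment clamps to the start-of-treatment state
  expect_equal(time_effect(spec, -1 / 7), 0)
  lin <- hr_model_spec(time_effect_form = "linear", alpha = -0.3)
  expect_equal(time_effect(lin, c(0, 10)), c(0, -3))
  bad <- spec; bad$t_prog <- -1
  expect_error(time_effect(bad, 1), "t_prog")
})

test_that("circadian harmonics peak at the acrophases", {
  one <- hr_model_spec(amp12 = 0)
  expect_equal(circadian(one, one$phi24), one$amp24)
  expect_equal(circadian(one, one$phi24 + 12), -one$amp24)
  # published harmonics give ~4.8 bpm in the early afternoon
  expect_equal(circadian(spec, 14.25), 4.8, tolerance = 0.1 / 4.8)
})

test_that("Emax model reproduces its closed-form anchors", {
  expect_equal(m2_effect(spec, 0), 0)
  expect_equal(m2_effect(spec, spec$ec50_m2), spec$emax_m2 / 2)
  # ~2% decrease at the week-2 mean concentration
  expect_equal(round(100 * m2_effect(spec, 300)), 2)
  expect_equal(m2_effect(spec, 300), 0.179 * 300 / 2900)
  expect_error(m2_effect(spec, -1), "conc")
})

test_that("covariate factors follow the power and conditional forms", {
  expect_equal(covariate_factor(56, 56, -0.2), 1)
  expect_equal(covariate_factor(15, 35, -0.22), (15 / 35)^-0.22)
  expect_gt(covariate_factor(15, 35, -0.22), 1)  # low albumin raises HR
  expect_equal(conditional_factor(FALSE, 0.5), 1)
  expect_equal(conditional_factor(TRUE, 0), 1)
  expect_equal(conditional_factor(TRUE, -0.047), 0.953)
  expect_error(covariate_factor(-1, 35, -0.22), "positive")
})

test_that("individual parameters apply exponential and Box-Cox IIV", {
  ip0 <- individual_params(spec, c(hr_base = 0, amp = 0, ec50 = 0))
  expect_equal(ip0$hr_base, spec$hr_base)
  expect_equal(ip0$amp24, spec$amp24)       # Box-Cox of 0 is 0
  expect_equal(ip0$ec50, spec$ec50_m2)
  ip1 <- individual_params(spec, c(ec50 = 1))
  expect_equal(ip1$ec50, 2600 * exp(1))
  # lambda -> 0 limit recovers plain exponential IIV
  lam0 <- hr_model_spec(boxcox_lambda = 0)
  expect_equal(individual_params(lam0, c(amp = 0.5))$amp24,
               spec$amp24 * exp(0.5))
  lam_small <- hr_model_spec(boxcox_lambda = 1e-9)
  expect_equal(individual_params(lam_small, c(amp = 0.5))$amp24,
               spec$amp24 * exp(0.5), tolerance = 1e-6)
  # one shared eta scales both amplitudes
  ip <- individual_params(spec, c(amp = 0.8))
  expect_equal(ip$amp24 / spec$amp24, ip$amp12 / spec$amp12)
})

test_that("composite prediction reproduces the typical values", {
  expect_equal(predict_hr(spec = spec, t_weeks = 0, ctime_h = NULL,
                          conc_m2 = 0), 78.2)
  expect_equal(predict_hr(spec = spec, t_weeks = 1e7, ctime_h = NULL,
                          conc_m2 = 0), 73.1)
  expect_equal(predict_hr(spec = spec, t_weeks = 0, ctime_h = NULL,
                          conc_m2 = 300), 78.2 * (1 - 0.179 * 300 / 2900))
  # C209 membership lowers HR by the study factor under the default sign
  s209 <- predict_hr(list(study = "C209"), spec, 0, NULL, 0)
  expect_equal(s209, 78.2 * 0.953)
})

test_that("composite prediction is monotone in concentration and time", {
  conc <- seq(0, 5000, length.out = 40)
  hr_conc <- predict_hr(spec = spec, t_weeks = 2, ctime_h = NULL,
                        conc_m2 = conc)
  expect_true(all(diff(hr_conc) <= 0))
  tt <- seq(0, 60, length.out = 60)
  hr_t <- predict_hr(spec = spec, t_weeks = tt, ctime_h = 12, conc_m2 = 0)
  expect_true(all(diff(hr_t) <= 1e-12))
})

test_that("covariates act on their designated model quantities", {
  # TTP acts on baseline HR only: at t -> Inf its effect vanishes
  subj <- list(ttp_mgit_h = 100)
  expect_equal(predict_hr(subj, spec, 0, NULL, 0),
               78.2 * (100 / 230.5)^-0.05)
  expect_equal(predict_hr(subj, spec, 1e7, NULL, 0), 73.1)
  # age acts on recovered HR only: no effect at baseline
  subj <- list(age_y = 60)
  expect_equal(predict_hr(subj, spec, 0, NULL, 0), 78.2)
  expect_equal(predict_hr(subj, spec, 1e7, NULL, 0),
               73.1 * (60 / 33)^0.08)
  # albumin multiplies the composite at every time
  subj <- list(albumin_gL = 15)
  f <- (15 / 35)^-0.22
  expect_equal(predict_hr(subj, spec, 0, NULL, 0), 78.2 * f)
  expect_equal(predict_hr(subj, spec, 1e7, NULL, 0), 73.1 * f)
})

test_that("IIV covariance honours the published correlations and CVs", {
  Om <- iiv_covariance(spec)
  expect_equal(Om["hr_base", "hr_rec"] /
                 sqrt(Om["hr_base", "hr_base"] * Om["hr_rec", "hr_rec"]),
               0.41)
  expect_equal(cv_from_omega2(Om["hr_base", "hr_base"]), 0.15)
  expect_equal(omega2_from_cv(cv_from_omega2(0.3)), 0.3)
  bad <- spec
  bad$corr[] <- c(0.99, -0.99, 0.99, 0)
  expect_error(iiv_covariance(bad), "positive definite")
})
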