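# Covariate selection and VPC diagnostics. Fits here run with IIV switched
# off (closed-form OFV) to keep the stepwise loops cheap; the marginal-ML
# machinery itself is exercised in the likelihood and acceptance tests.

null_truth <- function() {
  spec <- reduced_iiv_spec(keep = character(0))
  spec$cov_albumin_exp <- 0
  spec$cov_weight_exp <- 0
  spec$sigma_prop <- 0.05
  spec
}

sim_cov_cohort <- function(truth, n = 30, seed = 1) {
  design <- cohort_design(
    n_subjects = n, placebo_fraction = 1,
    covariates = list(
      age_y = list(median = 33, cv = 0.3, range = c(18, 68)),
      weight_kg = list(median = 55, cv = 0.2, range = c(30, 113)),
      albumin_gL = list(median = 35, cv = 0.2, range = c(15, 49)),
      ttp_mgit_h = list(median = 230.5, cv = 0.9, range = c(56, 1008))))
  cohort <- make_cohort(design, seed = seed)
  records <- simulate_hr_observations(cohort, truth, design, seed = seed + 1L)
  list(records = records, cohort = cohort)
}

test_that("an empty candidate set returns the base model", {
  truth <- null_truth()
  dat <- sim_cov_cohort(truth, n = 10, seed = 3)
  out <- scm_step(dat$records, dat$cohort, base_spec = truth,
                  candidates = character(0))
  expect_length(out$included, 0)
})

test_that("forward selection finds a covariate effect that is really there", {
  truth <- null_truth()
  truth$cov_albumin_exp <- -0.5    # strong effect by construction
  dat <- sim_cov_cohort(truth, n = 40, seed = 11)
  base <- null_truth()
  out <- scm_step(dat$records, dat$cohort, base_spec = base,
                  candidates = c("cov_albumin_exp", "cov_weight_exp"))
  expect_true("cov_albumin_exp" %in% out$included)
  # and backward elimination keeps it
  back <- scm_step(dat$records, dat$cohort, base_spec = out$spec,
                   candidates = out$included, direction = "backward",
                   included = out$included)
  expect_true("cov_albumin_exp" %in% back$included)
})

test_that("under the null the forward step selects at about the 3.84-threshold rate", {
  hits <- vapply(1:20, function(k) {
    truth <- null_truth()
    dat <- sim_cov_cohort(truth, n = 15, seed = 100 + k)
    out <- scm_step(dat$records, dat$cohort, base_spec = null_truth(),
                    candidates = "cov_albumin_exp")
    length(out$included) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.2)   # ~5% expected; allow binomial noise at 20 reps
})

test_that("VPC bands are reproducible, calibrated, and collapse without noise", {
  spec <- reduced_iiv_spec(keep = c("hr_base", "hr_rec"))
  design <- qtctbt:::reference_covariate_design(30, placebo_fraction = 1)
  cohort <- make_cohort(design, seed = 41)
  records <- simulate_hr_observations(cohort, spec, design, seed = 42)
  v1 <- vpc(records, cohort, spec, n_sim = 100, seed = 43)
  v2 <- vpc(records, cohort, spec, n_sim = 100, seed = 43)
  expect_identical(v1$summary, v2$summary)
  # observed data are one draw from the model: percentiles sit in the bands
  inside <- with(v1$summary, observed >= lo & observed <= hi)
  expect_gte(mean(inside), 0.8)
  # no IIV, no residual noise: bands collapse onto the prediction curve
  det <- reduced_iiv_spec(keep = character(0))
  det$sigma_prop <- 1e-12; det$sigma_add <- 0
  rec_det <- simulate_hr_observations(cohort, det, design, seed = 44)
  v0 <- vpc(rec_det, cohort, det, n_sim = 100, seed = 45)
  expect_lt(max(v0$summary$hi - v0$summary$lo), 1e-6)
})

test_that("an empty time bin is dropped from the VPC with a warning", {
  spec <- reduced_iiv_spec(keep = character(0))
  design <- qtctbt:::reference_covariate_design(5, placebo_fraction = 1)
  design$visits <- data.frame(t_weeks = c(-1 / 7, 24),
                              assessment = "predose", n_replicates = 2L)
  cohort <- make_cohort(design, seed = 51)
  records <- simulate_hr_observations(cohort, spec, design, seed = 52)
  expect_warning(v <- vpc(records, cohort, spec, n_sim = 100, seed = 53),
                 "empty bin")
  expect_setequal(unique(v$summary$bin), c("pretreatment", "wk20-24"))
})
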