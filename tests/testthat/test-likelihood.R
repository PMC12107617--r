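# spec with no IIV at all: the OFV has a closed form
no_iiv <- reduced_iiv_spec(keep = character(0))

test_that("with all IIV off the OFV equals the closed-form Gaussian value", {
  toy <- toy_subject_data(n_obs = 10)
  ctx <- qtctbt:::hr_likelihood_context(toy$records, toy$subjects)
  cond <- qtctbt:::make_cond_loglik(ctx, no_iiv)
  pred <- predict_hr(toy$subjects, no_iiv, toy$records$t_weeks,
                     toy$records$ctime_h, toy$records$conc_m2)
  # singleton occasions: independent obs with variance (pred*sp)^2 + sa^2
  sd_obs <- sqrt((pred * no_iiv$sigma_prop)^2 + no_iiv$sigma_add^2)
  closed <- -2 * sum(dnorm(toy$records$hr_bpm, pred, sd_obs, log = TRUE))
  expect_equal(hr_ofv(toy$records, toy$subjects, no_iiv), closed,
               tolerance = 1e-10)
})

test_that("the two-level residual model correlates replicates within occasions", {
  # same six observations, grouped as two triplicates vs six singletons:
  # the shared additive component makes the joint density differ
  recs <- toy_subject_data(n_obs = 6)$records
  subj <- toy_subject_data()$subjects
  recs$t_weeks <- rep(c(0, 4), each = 3)
  recs$ctime_h <- rep(c(10, 14), each = 3)
  grouped <- recs
  grouped$occasion_id <- rep(c("o1", "o2"), each = 3)
  grouped$replicate <- rep(1:3, 2)
  ofv_grouped <- hr_ofv(grouped, subj, no_iiv)
  ofv_single <- hr_ofv(recs, subj, no_iiv)
  expect_false(isTRUE(all.equal(ofv_grouped, ofv_single)))
  # with no additive component the grouping is irrelevant
  pure_prop <- no_iiv
  pure_prop$sigma_add <- 0
  expect_equal(hr_ofv(grouped, subj, pure_prop),
               hr_ofv(recs, subj, pure_prop), tolerance = 1e-10)
})

test_that("likelihood factorises over subjects: a duplicated subject doubles its contribution", {
  toy <- toy_subject_data(n_obs = 8)
  spec <- reduced_iiv_spec(keep = "hr_base")
  r2 <- toy$records
  r2$subject_id <- "T2"
  r2$occasion_id <- sub("T1", "T2", r2$occasion_id)
  s2 <- toy$subjects; s2$subject_id <- "T2"
  both <- rbind(toy$records, r2)
  subs <- rbind(toy$subjects, s2)
  expect_equal(hr_ofv(both, subs, spec),
               2 * hr_ofv(toy$records, toy$subjects, spec),
               tolerance = 1e-8)
})

test_that("Laplace matches adaptive quadrature on one-random-effect instances", {
  toy <- toy_subject_data(n_obs = 12, seed = 7)
  # near-linear regime: exp(eta) is linear to first order, Laplace ~ exact
  tiny <- reduced_iiv_spec(keep = "hr_base")
  tiny$omega2[["hr_base"]] <- 1e-4
  ofv_lap <- hr_ofv(toy$records, toy$subjects, tiny)
  ofv_quad <- quadrature_ofv(toy$records, toy$subjects, tiny)
  expect_equal(ofv_lap, ofv_quad, tolerance = 1e-6)
  # published IIV magnitude
  full <- reduced_iiv_spec(keep = "hr_base")
  ofv_lap <- hr_ofv(toy$records, toy$subjects, full)
  ofv_quad <- quadrature_ofv(toy$records, toy$subjects, full)
  expect_equal(ofv_lap, ofv_quad, tolerance = 1e-4)
})

test_that("Laplace matches adaptive quadrature with two correlated random effects", {
  skip_if_not_installed("pracma")
  toy <- toy_subject_data(n_obs = 12, seed = 13)
  spec <- reduced_iiv_spec(keep = c("hr_base", "hr_rec"))
  ofv_lap <- hr_ofv(toy$records, toy$subjects, spec)
  ofv_quad <- quadrature_ofv(toy$records, toy$subjects, spec)
  expect_equal(ofv_lap, ofv_quad, tolerance = 1e-4)
})

test_that("fitting with IIV off recovers the generating parameters within 3 SEs", {
  truth <- reduced_iiv_spec(keep = character(0))
  truth$sigma_prop <- 0.02; truth$sigma_add <- 0.5
  design <- qtctbt:::reference_covariate_design(25, placebo_fraction = 1)
  cohort <- make_cohort(design, seed = 5)
  records <- simulate_hr_observations(cohort, truth, design, seed = 6)
  init <- truth
  init$hr_base <- 85; init$hr_rec <- 70; init$t_prog <- 4
  fit <- hr_fit(records, cohort, init = init,
                mask = c("hr_base", "hr_rec", "t_prog"), se = TRUE)
  expect_true(fit$convergence)
  expect_lt(abs(fit$spec$hr_base - truth$hr_base), 3 * fit$se[["hr_base"]])
  expect_lt(abs(fit$spec$hr_rec - truth$hr_rec), 3 * fit$se[["hr_rec"]])
  expect_lt(abs(fit$spec$t_prog - truth$t_prog),
            3 * fit$se[["t_prog"]] + 0.05 * truth$t_prog)
  # refitting from the optimum is a fixed point
  refit <- hr_fit(records, cohort, init = fit$spec,
                  mask = c("hr_base", "hr_rec", "t_prog"), se = FALSE)
  expect_lt(abs(refit$ofv - fit$ofv), 1e-2)
  tab <- fit_table(fit)
  expect_true(all(tab$lo95 <= tab$estimate & tab$estimate <= tab$hi95))
})
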