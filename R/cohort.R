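#' Virtual trial design
#'
#' Describes the cohort a synthetic trial emulates: the two phase IIb MDR-TB
#' studies pooled for model development (~440 adults, a placebo arm in the
#' controlled study, ECGs in triplicate from Day −1 through Week 24).
#' Covariates are drawn from independent log-normals matched to the published
#' medians and truncated to the published ranges; M2 exposure follows a
#' phenomenological accumulation curve whose population mean reaches
#' 300 ng/mL at Week 2 (the observed mean); QT "truth" is a subject-level
#' corrected QT (QTc0) mapped to QT through a chosen true correction factor.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param placebo_fraction Fraction randomised to placebo (placebo subjects
#'   belong to study C208, mirroring the controlled trial).
#' @param visits Data frame of occasions: columns `t_weeks`, `assessment`
#'   (`"predose"` or `"5h"`), `n_replicates`. Default:
#'   [default_visit_schedule()].
#' @param covariates Named list of `list(median, cv, range)` for `age_y`,
#'   `weight_kg`, `albumin_gL`, `ttp_mgit_h`.
#' @param exposure List: `css_mean` (ng/mL), `css_cv`, `t_acc_weeks`
#'   (accumulation half-life), `dist` (`"lognormal"` or `"uniform"`),
#'   `css_range` (for the uniform option). Defaults give a population mean
#'   concentration of exactly 300 ng/mL at Week 2.
#' @param qt_truth List: `qtc0_ms` (median subject-level corrected QT),
#'   `qtc0_cv`, `sigma_qt` (log-scale residual), `cf` ([correction_spec()]
#'   used as the true QT--RR relationship; default the time-varying TBT
#'   factor).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 440,
                          placebo_fraction = 105 / 440,
                          visits = default_visit_schedule(),
                          covariates = list(
                            age_y = list(median = 33, cv = 0.30,
                                         range = c(18, 68)),
                            weight_kg = list(median = 55, cv = 0.20,
                                             range = c(30, 113)),
                            albumin_gL = list(median = 35, cv = 0.20,
                                              range = c(15, 49)),
                            ttp_mgit_h = list(median = 230.5, cv = 0.90,
                                              range = c(56, 1008))),
                          exposure = list(css_mean = 600, css_cv = 0.45,
                                          t_acc_weeks = 2,
                                          dist = "lognormal",
                                          css_range = c(0, 8000)),
                          qt_truth = list(qtc0_ms = 400, qtc0_cv = 0.05,
                                          sigma_qt = 0.02,
                                          cf = correction_spec("tbt"))) {
  stopifnot(n_subjects >= 1,
            placebo_fraction >= 0, placebo_fraction <= 1,
            all(vapply(covariates, function(x) x$cv >= 0, logical(1))),
            exposure$css_cv >= 0, qt_truth$qtc0_cv >= 0,
            qt_truth$sigma_qt >= 0)
  if (is.data.frame(visits)) visits <- as.data.frame(visits)
  structure(list(n_subjects = as.integer(n_subjects),
                 placebo_fraction = placebo_fraction, visits = visits,
                 covariates = covariates, exposure = exposure,
                 qt_truth = qt_truth),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @export
default_visit_schedule <- function() {
  data.frame(
    t_weeks = c(-1 / 7, -1 / 7, 1, 2, 4, 8, 12, 16, 20, 24),
    assessment = c("predose", "5h", rep("predose", 8)),
    n_replicates = 3L)
}

# truncated log-normal sampler keyed to median/cv/range; cv = 0 collapses to
# the median exactly
rlnorm_trunc <- function(n, median, cv, range) {
  if (cv == 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  plo <- pnorm(log(range[1] / median) / sdlog)
  phi <- pnorm(log(range[2] / median) / sdlog)
  qlnorm(runif(n, plo, phi), meanlog = log(median), sdlog = sdlog)
}

#' Generate a virtual cohort of subject profiles
#'
#' Draws covariates from independent truncated log-normals matched to the
#' published medians/ranges, assigns arms by the design's placebo fraction
#' (placebo subjects to study C208; active subjects split C208/C209 in the
#' published proportion).
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Subject profile data frame (one row per subject).
#' @export
make_cohort <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects
  arm <- ifelse(runif(n) < design$placebo_fraction, "placebo", "active")
  # active arm split between the controlled (102/335) and single-arm study
  study <- ifelse(arm == "placebo", "C208",
                  ifelse(runif(n) < 102 / 335, "C208", "C209"))
  cv <- design$covariates
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    study = study, arm = arm,
    age_y = rlnorm_trunc(n, cv$age_y$median, cv$age_y$cv, cv$age_y$range),
    weight_kg = rlnorm_trunc(n, cv$weight_kg$median, cv$weight_kg$cv,
                             cv$weight_kg$range),
    albumin_gL = rlnorm_trunc(n, cv$albumin_gL$median, cv$albumin_gL$cv,
                              cv$albumin_gL$range),
    ttp_mgit_h = rlnorm_trunc(n, cv$ttp_mgit_h$median, cv$ttp_mgit_h$cv,
                              cv$ttp_mgit_h$range),
    stringsAsFactors = FALSE)
}

# Draw one subject's steady-state concentration scale.
draw_css <- function(exposure, n = 1L) {
  if (identical(exposure$dist, "uniform")) {
    runif(n, exposure$css_range[1], exposure$css_range[2])
  } else if (exposure$css_cv == 0) {
    rep(exposure$css_mean, n)
  } else {
    sdlog <- sqrt(log(1 + exposure$css_cv^2))
    rlnorm(n, meanlog = log(exposure$css_mean) - sdlog^2 / 2, sdlog = sdlog)
  }
}

#' Simulate an M2 concentration profile
#'
#' Phenomenological accumulation curve standing in for the population PK
#' model the trials used:
#' \eqn{C(t) = C_{ss,i} (1 - e^{-\ln 2 \, t / t_{acc}})}, with subject scale
#' \eqn{C_{ss,i}} log-normal around the design mean (so the population mean
#' is `css_mean` at steady state). Placebo subjects and pre-dose times
#' return 0.
#'
#' @param subject One-row subject profile (the `arm` field is honoured).
#' @param times Treatment times (weeks).
#' @param design A [cohort_design()].
#' @param seed Optional integer seed.
#' @param css Optional pre-drawn subject concentration scale (ng/mL).
#' @return Concentrations (ng/mL), same length as `times`.
#' @export
simulate_m2_profile <- function(subject, times, design, seed = NULL,
                                css = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(subject$arm) && subject$arm == "placebo")
    return(rep(0, length(times)))
  if (is.null(css)) css <- draw_css(design$exposure)
  ifelse(times <= 0, 0,
         css * (1 - exp(-log(2) * times / design$exposure$t_acc_weeks)))
}

# Draw the full 6-dim random-effect matrix for a cohort (inactive columns 0).
draw_etas <- function(spec, n) {
  act <- active_etas(spec)
  E <- matrix(0, n, 6,
              dimnames = list(NULL, c("hr_base", "hr_rec", "amp", "ec50",
                                      "prop", "add")))
  if (length(act) > 0L) {
    Omega <- iiv_covariance(spec)
    E[, act] <- MASS::mvrnorm(n, mu = rep(0, length(act)), Sigma = Omega)
  }
  E
}

#' Simulate heart-rate observations for a cohort
#'
#' Builds the ECG record table for the design's visit schedule (clock times
#' drawn uniformly on \[8, 17) h per occasion), draws correlated random
#' effects per subject, computes the composite model prediction, and applies
#' the two-level residual model:
#' \deqn{HR_{obs} = pred (1 + \sigma_{prop} e^{\eta_{prop}} \epsilon_1) +
#'   \sigma_{add} e^{\eta_{add}} \epsilon_2}
#' with \eqn{\epsilon_1} drawn per replicate and \eqn{\epsilon_2} shared by
#' the replicates of one occasion. Non-positive draws are resampled (at most
#' 100 attempts).
#'
#' @param cohort Subject profile data frame from [make_cohort()].
#' @param spec An [hr_model_spec()] used as simulation truth.
#' @param design A [cohort_design()].
#' @param seed Optional integer seed.
#' @return ECG record data frame with `hr_bpm` filled and `qt_ms = NA`.
#' @export
simulate_hr_observations <- function(cohort, spec = hr_model_spec(),
                                     design = cohort_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_hr_model_spec(spec)
  n <- nrow(cohort)
  visits <- design$visits
  n_occ_per_subj <- nrow(visits)
  reps <- rep(visits$n_replicates, n)
  occ_subj <- rep(seq_len(n), each = n_occ_per_subj)
  occ_visit <- rep(seq_len(n_occ_per_subj), n)
  ct_occ <- runif(length(occ_subj), 8, 17)
  E <- draw_etas(spec, n)
  css <- draw_css(design$exposure, n)
  css[cohort$arm == "placebo"] <- 0
  rec_idx <- rep(seq_along(occ_subj), reps)
  records <- data.frame(
    subject_id = cohort$subject_id[occ_subj[rec_idx]],
    study = cohort$study[occ_subj[rec_idx]],
    arm = cohort$arm[occ_subj[rec_idx]],
    t_weeks = visits$t_weeks[occ_visit[rec_idx]],
    ctime_h = ct_occ[rec_idx],
    occasion_id = sprintf("%s-o%02d", cohort$subject_id[occ_subj[rec_idx]],
                          occ_visit[rec_idx]),
    replicate = unlist(lapply(reps, seq_len)),
    assessment = visits$assessment[occ_visit[rec_idx]],
    stringsAsFactors = FALSE)
  si <- occ_subj[rec_idx]
  tt <- pmax(records$t_weeks, 0)
  records$conc_m2 <- ifelse(records$t_weeks <= 0, 0,
                            css[si] * (1 - exp(-log(2) * tt /
                                               design$exposure$t_acc_weeks)))
  records$hr_bpm <- sim_hr_draw(records, cohort, spec, si, E)
  records$qt_ms <- NA_real_
  records[, c(.ecg_record_cols, "assessment")]
}

# Composite model prediction for a record table, given the per-subject
# random-effect matrix E (columns hr_base, hr_rec, amp, ec50, prop, add) and
# the subject index si per record.
predict_cohort_hr <- function(records, cohort, spec, si, E) {
  ref <- spec$reference
  cf <- function(v, r, e) ifelse(is.na(v), 1, covariate_factor(ifelse(is.na(v), r, v), r, e))
  tt <- pmax(records$t_weeks, 0)
  f_ttp <- cf(cohort$ttp_mgit_h, ref$ttp_mgit_h, spec$cov_ttp_exp)[si]
  f_age <- cf(cohort$age_y, ref$age_y, spec$cov_age_exp)[si]
  f_comp <- (cf(cohort$weight_kg, ref$weight_kg, spec$cov_weight_exp) *
             cf(cohort$albumin_gL, ref$albumin_gL, spec$cov_albumin_exp) *
             conditional_factor(cohort$study == "C209",
                                spec$study_effect_direction *
                                  spec$cov_study))[si]
  base_i <- spec$hr_base * exp(E[si, "hr_base"]) * f_ttp
  rec_i <- spec$hr_rec * exp(E[si, "hr_rec"]) * f_age
  te <- if (spec$time_effect_form == "linear") spec$alpha * tt
        else (rec_i - base_i) * (1 - exp(-log(2) * tt / spec$t_prog))
  amp_scale <- exp(boxcox_eta(E[si, "amp"], spec$boxcox_lambda))
  diur <- (spec$amp24 * cos(2 * pi * (records$ctime_h - spec$phi24) / 24) +
           spec$amp12 * cos(2 * pi * (records$ctime_h - spec$phi12) / 12)) *
    amp_scale
  ec50_i <- spec$ec50_m2 * exp(E[si, "ec50"])
  m2 <- spec$emax_m2 * records$conc_m2 / (ec50_i + records$conc_m2)
  (base_i + te + diur) * (1 - m2) * f_comp
}

# Draw observed HR for a record table: new random effects (if E not given)
# plus the two-level residual noise; positivity enforced by resampling the
# residual draws of offending occasions.
sim_hr_draw <- function(records, cohort, spec, si = NULL, E = NULL) {
  if (is.null(si)) si <- match(records$subject_id, cohort$subject_id)
  if (is.null(E)) E <- draw_etas(spec, nrow(cohort))
  occ_key <- paste(records$subject_id, records$occasion_id, sep = "\r")
  occ_idx <- match(occ_key, unique(occ_key))
  n_occ <- max(occ_idx)
  pred <- predict_cohort_hr(records, cohort, spec, si, E)
  sp <- spec$sigma_prop * exp(E[si, "prop"])
  sa <- spec$sigma_add * exp(E[si, "add"])
  eps2 <- rnorm(n_occ)[occ_idx]   # shared within occasion
  hr <- pred * (1 + sp * rnorm(nrow(records))) + sa * eps2
  for (attempt in seq_len(100L)) {
    bad <- hr <= 0
    if (!any(bad)) break
    occ_bad <- unique(occ_idx[bad])
    redraw <- occ_idx %in% occ_bad
    eps2_new <- rnorm(n_occ)[occ_idx]
    hr[redraw] <- pred[redraw] * (1 + sp[redraw] * rnorm(sum(redraw))) +
      sa[redraw] * eps2_new[redraw]
  }
  if (any(hr <= 0))
    stop("could not obtain positive HR after 100 resampling attempts")
  hr
}

#' Simulate QT observations on top of simulated heart rates
#'
#' Embodies the assumption that a subject-level corrected QT (QTc0) maps to
#' the observed QT through the true correction factor:
#' \deqn{QT = QTc0_i \cdot RR^{CF_{true}(t)} \cdot e^{\sigma_{qt}\epsilon}}
#' with RR in seconds. Correcting the simulated QT with the identical CF
#' recovers \eqn{QTc0_i e^{\sigma_{qt}\epsilon}}, independent of HR.
#'
#' @param records ECG record data frame with `hr_bpm` filled.
#' @param design A [cohort_design()] (uses `qt_truth`).
#' @param seed Optional integer seed.
#' @return The records with `qt_ms` filled.
#' @export
simulate_qt_observations <- function(records, design = cohort_design(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qt <- design$qt_truth
  ids <- unique(records$subject_id)
  qtc0 <- if (qt$qtc0_cv == 0) rep(qt$qtc0_ms, length(ids))
          else rlnorm(length(ids), meanlog = log(qt$qtc0_ms),
                      sdlog = sqrt(log(1 + qt$qtc0_cv^2)))
  names(qtc0) <- ids
  rr <- rr_from_hr(records$hr_bpm)
  cf <- correction_exponent(qt$cf, records$t_weeks)
  eps <- if (qt$sigma_qt == 0) 0 else rnorm(nrow(records), 0, qt$sigma_qt)
  records$qt_ms <- qtc0[records$subject_id] * rr^cf * exp(eps)
  records
}

#' Simulate a complete virtual trial
#'
#' Convenience wrapper chaining [make_cohort()],
#' [simulate_hr_observations()] and [simulate_qt_observations()] with
#' sub-seeds derived from one master seed.
#'
#' @param design A [cohort_design()].
#' @param spec An [hr_model_spec()] used as simulation truth.
#' @param seed Integer master seed.
#' @return An [ecg_data] object.
#' @export
simulate_trial <- function(design = cohort_design(), spec = hr_model_spec(),
                           seed = 1L) {
  cohort <- make_cohort(design, seed = seed)
  records <- simulate_hr_observations(cohort, spec, design, seed = seed + 1L)
  records <- simulate_qt_observations(records, design, seed = seed + 2L)
  ecg_data(records, cohort)
}
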