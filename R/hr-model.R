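#' Time-on-treatment effect on heart rate
#'
#' Change in HR (bpm) attributable to recovery from active TB after `t` weeks
#' of treatment. The asymptotic (final-model) form is
#' \deqn{TE(t) = (HR_{rec} - HR_{base}) (1 - e^{-\ln 2 \, t / T_{prog}})}
#' and the alternative linear form is \eqn{TE(t) = \alpha t}. Pretreatment
#' times (`t < 0`) are clamped to 0: the recovery process starts at
#' treatment start.
#'
#' @param spec An [hr_model_spec()].
#' @param t Time after start of treatment (weeks); vectorised.
#' @param hr_base,hr_rec Optional individualised endpoints overriding the
#'   typical values in `spec` (used by [predict_hr()] to apply covariate and
#'   IIV scaling to the asymptotes).
#' @return HR change (bpm), same length as `t`.
#' @export
#' @examples
#' time_effect(hr_model_spec(), c(0, 7.74, Inf))   # 0, -2.55, -5.1
time_effect <- function(spec, t, hr_base = spec$hr_base, hr_rec = spec$hr_rec) {
  if (spec$t_prog <= 0) stop("t_prog must be > 0")
  t <- pmax(t, 0)
  switch(spec$time_effect_form,
         linear = spec$alpha * t,
         asymptotic = (hr_rec - hr_base) * (1 - exp(-log(2) * t / spec$t_prog)))
}

#' Circadian heart-rate deviation
#'
#' Two-harmonic cosinor: \eqn{\sum_l A_l \cos(2\pi (CTIME - \phi_l)/l)} for
#' periods \eqn{l \in \{24, 12\}} h, peaking at the acrophases.
#'
#' @param spec An [hr_model_spec()].
#' @param ctime_h Clock time in hours, in \[0, 24); vectorised.
#' @param amp24,amp12 Optional individualised amplitudes (bpm).
#' @return HR deviation (bpm).
#' @export
circadian <- function(spec, ctime_h, amp24 = spec$amp24, amp12 = spec$amp12) {
  amp24 * cos(2 * pi * (ctime_h - spec$phi24) / 24) +
    amp12 * cos(2 * pi * (ctime_h - spec$phi12) / 12)
}

#' Fractional heart-rate decrease due to the M2 metabolite
#'
#' Emax exposure-response: \eqn{M2EF = E_{max} \, C / (EC_{50} + C)}.
#'
#' @param spec An [hr_model_spec()].
#' @param conc M2 concentration (ng/mL), non-negative; vectorised.
#' @param emax,ec50 Optional individualised parameters.
#' @return Fraction in \[0, `emax`).
#' @export
#' @examples
#' m2_effect(hr_model_spec(), 300)  # ~0.0185, the "2%" decrease at week 2
m2_effect <- function(spec, conc, emax = spec$emax_m2, ec50 = spec$ec50_m2) {
  if (any(conc < 0)) stop("conc must be >= 0")
  emax * conc / (ec50 + conc)
}

#' Covariate effect factors
#'
#' Power model for continuous covariates, \eqn{(x / x_{ref})^{\theta}}, and
#' conditional (categorical) model \eqn{1 + \theta \cdot 1[flag]} relative to
#' the most common category.
#'
#' @param value Covariate value(s), > 0.
#' @param reference Reference value, > 0.
#' @param exponent Power exponent.
#' @return Multiplicative factor(s).
#' @export
covariate_factor <- function(value, reference, exponent) {
  if (any(value <= 0) || reference <= 0)
    stop("power covariate model requires positive value and reference")
  (value / reference)^exponent
}

#' @rdname covariate_factor
#' @param flag Logical indicator of the non-reference category.
#' @param theta Fractional effect of the non-reference category.
#' @export
conditional_factor <- function(flag, theta) {
  1 + theta * as.numeric(flag)
}

#' Individualise model parameters from random effects
#'
#' Applies the exponential IIV model \eqn{p = \theta e^{\eta}} to baseline
#' HR, recovered HR, EC50 and the residual-error magnitudes, and the
#' Box--Cox-shaped model \eqn{p = \theta e^{\eta^*}},
#' \eqn{\eta^* = (e^{\lambda \eta} - 1)/\lambda}, to the circadian
#' amplitudes; one shared amplitude deviation scales both harmonics. The
#' \eqn{\lambda = 0} limit recovers the plain exponential model.
#'
#' @param spec An [hr_model_spec()].
#' @param eta Named numeric vector of random-effect values; recognised names
#'   are `hr_base`, `hr_rec`, `amp`, `ec50`, `prop`, `add`. Missing names
#'   default to 0.
#' @return Named list of individual parameters `hr_base`, `hr_rec`, `amp24`,
#'   `amp12`, `ec50`, `sigma_prop`, `sigma_add`.
#' @export
individual_params <- function(spec, eta = numeric(0)) {
  full <- c(hr_base = 0, hr_rec = 0, amp = 0, ec50 = 0, prop = 0, add = 0)
  if (length(eta)) full[names(eta)] <- eta
  eta_star <- boxcox_eta(full[["amp"]], spec$boxcox_lambda)
  list(hr_base = spec$hr_base * exp(full[["hr_base"]]),
       hr_rec = spec$hr_rec * exp(full[["hr_rec"]]),
       amp24 = spec$amp24 * exp(eta_star),
       amp12 = spec$amp12 * exp(eta_star),
       ec50 = spec$ec50_m2 * exp(full[["ec50"]]),
       sigma_prop = spec$sigma_prop * exp(full[["prop"]]),
       sigma_add = spec$sigma_add * exp(full[["add"]]))
}

# Box-Cox transform of a random effect; lambda -> 0 limit is the identity.
boxcox_eta <- function(eta, lambda) {
  if (abs(lambda) < 1e-12) eta else (exp(lambda * eta) - 1) / lambda
}

# Covariate factors for one subject (list/1-row data frame with age_y,
# weight_kg, albumin_gL, ttp_mgit_h, study); NA covariates fall back to the
# reference (factor 1).
subject_factors <- function(spec, subject) {
  ref <- spec$reference
  pf <- function(value, reference, exponent) {
    if (is.null(value) || all(is.na(value))) 1
    else covariate_factor(value, reference, exponent)
  }
  list(
    f_ttp = pf(subject$ttp_mgit_h, ref$ttp_mgit_h, spec$cov_ttp_exp),
    f_age = pf(subject$age_y, ref$age_y, spec$cov_age_exp),
    f_weight = pf(subject$weight_kg, ref$weight_kg, spec$cov_weight_exp),
    f_albumin = pf(subject$albumin_gL, ref$albumin_gL, spec$cov_albumin_exp),
    f_study = conditional_factor(!is.null(subject$study) &&
                                   !is.na(subject$study) &&
                                   subject$study == "C209",
                                 spec$study_effect_direction * spec$cov_study))
}

#' Composite heart-rate prediction
#'
#' Assembles the full model prediction for one subject:
#' \deqn{HR = [HR_{base,i} F_{ttp} + TE_i(t) + DIUR_i(CTIME)] \,
#'   (1 - M2EF_i(C)) \, F_{study} F_{weight} F_{albumin}}
#' where the asymptotic time effect runs from the covariate-adjusted
#' individual baseline \eqn{HR_{base,i} F_{ttp}} to the individual recovered
#' value \eqn{HR_{rec,i} F_{age}}. Baseline TTP MGIT acts on baseline HR,
#' age on recovered HR, and weight, albumin and study multiply the composite.
#' Pretreatment times evaluate at the `t = 0` structural state.
#'
#' @param subject Subject profile: list or 1-row data frame with covariates
#'   `age_y`, `weight_kg`, `albumin_gL`, `ttp_mgit_h`, `study` (missing or
#'   `NA` covariates count as reference). `NULL` means the reference subject.
#' @param spec An [hr_model_spec()].
#' @param t_weeks Treatment time (weeks); vectorised.
#' @param ctime_h Clock time (h); vectorised or `NULL` to omit the circadian
#'   component.
#' @param conc_m2 M2 concentration (ng/mL); vectorised.
#' @param eta Named random-effect vector (see [individual_params()]).
#' @return Predicted HR (bpm).
#' @export
#' @examples
#' spec <- hr_model_spec()
#' predict_hr(spec = spec, t_weeks = 0, ctime_h = NULL, conc_m2 = 0)    # 78.2
#' predict_hr(spec = spec, t_weeks = 1e6, ctime_h = NULL, conc_m2 = 0)  # 73.1
predict_hr <- function(subject = NULL, spec, t_weeks, ctime_h = NULL,
                       conc_m2 = 0, eta = numeric(0)) {
  ip <- individual_params(spec, eta)
  fac <- subject_factors(spec, subject %||% list())
  base_i <- ip$hr_base * fac$f_ttp
  rec_i <- ip$hr_rec * fac$f_age
  te <- time_effect(spec, t_weeks, hr_base = base_i, hr_rec = rec_i)
  diur <- if (is.null(ctime_h)) 0
          else circadian(spec, ctime_h, amp24 = ip$amp24, amp12 = ip$amp12)
  m2 <- m2_effect(spec, conc_m2, emax = spec$emax_m2, ec50 = ip$ec50)
  hr <- (base_i + te + diur) * (1 - m2) *
    fac$f_study * fac$f_weight * fac$f_albumin
  if (any(hr <= 0))
    stop("non-positive HR prediction; pathological parameter combination")
  hr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
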