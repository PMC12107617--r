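#' Specification of the composite heart-rate model
#'
#' Container for every fixed effect, variability term and covariate effect of
#' the heart-rate normalisation model. Defaults are the final published
#' estimates from the pooled phase IIb MDR-TB trials: baseline HR 78.2 bpm
#' recovering to 73.1 bpm with half-life 7.74 weeks, 24 h/12 h circadian
#' harmonics (6.2 bpm at 15.7 h; 1.65 bpm at 10.1 h) with a shared Box--Cox
#' inter-individual term (shape −0.77), an Emax effect of the bedaquiline
#' metabolite M2 (Emax 0.179, EC50 2600 ng/mL), power covariate effects
#' (weight −0.2 and albumin −0.22 on composite HR, MGIT time-to-positivity
#' −0.05 on baseline HR, age 0.08 on recovered HR), a study factor of 4.7%
#' lower HR in the single-arm study, and a two-level residual model
#' (proportional 8.4% per replicate, additive 2.7 bpm shared within a
#' triplicate occasion).
#'
#' Inter-individual variability is parameterised by variances `omega2` of
#' log-normal (exponential) random effects, except the shared amplitude term
#' which is Box--Cox transformed. Defaults convert the published %CV values
#' via the log-normal identity \eqn{CV = \sqrt{e^{\omega^2} - 1}}
#' ([omega2_from_cv()]).
#'
#' @param hr_base Typical baseline HR (bpm) of untreated active-TB patients.
#' @param hr_rec Typical recovered HR (bpm) after successful treatment.
#' @param t_prog Recovery half-life (weeks) of the asymptotic time effect.
#' @param amp24,phi24 Amplitude (bpm) and acrophase (clock h) of the 24 h
#'   harmonic.
#' @param amp12,phi12 Amplitude (bpm) and acrophase (clock h) of the 12 h
#'   harmonic.
#' @param boxcox_lambda Box--Cox shape of the shared amplitude IIV.
#' @param emax_m2 Maximal fractional HR decrease due to M2.
#' @param ec50_m2 M2 concentration (ng/mL) giving half the maximal decrease.
#' @param cov_study Fractional study effect (single-arm study vs controlled
#'   study); applied as `1 + study_effect_direction * cov_study` for study
#'   `"C209"`.
#' @param study_effect_direction `-1` (default) encodes typically *lower* HR
#'   in the C209 population; `+1` flips the sign convention.
#' @param cov_weight_exp,cov_albumin_exp Power exponents on composite HR.
#' @param cov_ttp_exp Power exponent of baseline TTP MGIT on baseline HR.
#' @param cov_age_exp Power exponent of age on recovered HR.
#' @param reference Reference covariates ([reference_covariates()]).
#' @param omega2 Named IIV variances for `hr_base`, `hr_rec`, `amp`, `ec50`,
#'   `prop`, `add` (zero switches a random effect off).
#' @param corr Named IIV correlations: `hr_base.hr_rec`, `hr_base.amp`,
#'   `hr_rec.amp`, `prop.add`.
#' @param sigma_prop Proportional residual magnitude (fraction, per
#'   replicate).
#' @param sigma_add Additive residual magnitude (bpm, shared within a
#'   triplicate occasion).
#' @param time_effect_form `"asymptotic"` (final model) or `"linear"`.
#' @param alpha Slope (bpm/week) of the linear time-effect form.
#' @return A list of class `hr_model_spec`.
#' @export
#' @examples
#' spec <- hr_model_spec()
#' predict_hr(spec = spec, t_weeks = 0, ctime_h = NULL, conc_m2 = 0)  # 78.2
hr_model_spec <- function(hr_base = 78.2, hr_rec = 73.1, t_prog = 7.74,
                          amp24 = 6.2, phi24 = 15.7,
                          amp12 = 1.65, phi12 = 10.1,
                          boxcox_lambda = -0.77,
                          emax_m2 = 0.179, ec50_m2 = 2600,
                          cov_study = 0.047, study_effect_direction = -1,
                          cov_weight_exp = -0.2, cov_albumin_exp = -0.22,
                          cov_ttp_exp = -0.05, cov_age_exp = 0.08,
                          reference = reference_covariates(),
                          omega2 = c(hr_base = omega2_from_cv(0.15),
                                     hr_rec = omega2_from_cv(0.154),
                                     amp = omega2_from_cv(0.953),
                                     ec50 = omega2_from_cv(8.834),
                                     prop = omega2_from_cv(0.236),
                                     add = omega2_from_cv(0.385)),
                          corr = c(hr_base.hr_rec = 0.41,
                                   hr_base.amp = -0.26,
                                   hr_rec.amp = -0.421,
                                   prop.add = 0.38),
                          sigma_prop = 0.084, sigma_add = 2.7,
                          time_effect_form = c("asymptotic", "linear"),
                          alpha = 0) {
  time_effect_form <- match.arg(time_effect_form)
  om <- c(hr_base = 0, hr_rec = 0, amp = 0, ec50 = 0, prop = 0, add = 0)
  om[names(omega2)] <- omega2
  cr <- c(hr_base.hr_rec = 0, hr_base.amp = 0, hr_rec.amp = 0, prop.add = 0)
  cr[names(corr)] <- corr
  spec <- structure(list(
    hr_base = hr_base, hr_rec = hr_rec, t_prog = t_prog,
    amp24 = amp24, phi24 = phi24, amp12 = amp12, phi12 = phi12,
    boxcox_lambda = boxcox_lambda,
    emax_m2 = emax_m2, ec50_m2 = ec50_m2,
    cov_study = cov_study, study_effect_direction = study_effect_direction,
    cov_weight_exp = cov_weight_exp, cov_albumin_exp = cov_albumin_exp,
    cov_ttp_exp = cov_ttp_exp, cov_age_exp = cov_age_exp,
    reference = reference,
    omega2 = om, corr = cr,
    sigma_prop = sigma_prop, sigma_add = sigma_add,
    time_effect_form = time_effect_form, alpha = alpha),
    class = "hr_model_spec")
  validate_hr_model_spec(spec)
}

#' @rdname hr_model_spec
#' @param spec An `hr_model_spec`.
#' @export
validate_hr_model_spec <- function(spec) {
  stopifnot(inherits(spec, "hr_model_spec"))
  if (!is.finite(spec$t_prog) || spec$t_prog <= 0)
    stop("t_prog must be > 0 (recovery half-life in weeks)")
  if (spec$emax_m2 < 0 || spec$emax_m2 >= 1)
    stop("emax_m2 must lie in [0, 1) (fractional maximal decrease)")
  if (spec$ec50_m2 <= 0) stop("ec50_m2 must be > 0")
  if (spec$amp24 < 0 || spec$amp12 < 0) stop("amplitudes must be >= 0")
  if (any(spec$omega2 < 0)) stop("omega2 variances must be >= 0")
  if (any(abs(spec$corr) >= 1)) stop("IIV correlations must lie in (-1, 1)")
  if (spec$sigma_prop < 0 || spec$sigma_add < 0)
    stop("residual magnitudes must be >= 0")
  # the implied correlation matrix of the active random effects must be PD
  iiv_covariance(spec)
  spec
}

#' @export
print.hr_model_spec <- function(x, ...) {
  cat("<hr_model_spec>\n")
  cat(sprintf("  time effect (%s): baseline %.1f -> recovered %.1f bpm, half-life %.2f wk\n",
              x$time_effect_form, x$hr_base, x$hr_rec, x$t_prog))
  cat(sprintf("  circadian: %.2f bpm @ %.1f h (24 h), %.2f bpm @ %.1f h (12 h)\n",
              x$amp24, x$phi24, x$amp12, x$phi12))
  cat(sprintf("  M2 effect: Emax %.3f, EC50 %.0f ng/mL\n", x$emax_m2, x$ec50_m2))
  act <- names(x$omega2)[x$omega2 > 0]
  cat(sprintf("  IIV on: %s\n", if (length(act)) paste(act, collapse = ", ") else "none"))
  cat(sprintf("  residual: %.1f%% proportional + %.1f bpm additive (per occasion)\n",
              100 * x$sigma_prop, x$sigma_add))
  invisible(x)
}

#' Convert between IIV variance and coefficient of variation
#'
#' Log-normal identity \eqn{CV = \sqrt{e^{\omega^2} - 1}} used to report
#' exponential inter-individual variability as a %CV.
#'
#' @param omega2 Variance of the log-scale random effect.
#' @param cv Coefficient of variation as a fraction (0.15 for 15%).
#' @return The converted quantity.
#' @export
cv_from_omega2 <- function(omega2) sqrt(exp(omega2) - 1)

#' @rdname cv_from_omega2
#' @export
omega2_from_cv <- function(cv) log(1 + cv^2)

# Names of random effects with non-zero variance, in canonical order.
active_etas <- function(spec) {
  names(spec$omega2)[spec$omega2 > 0]
}

#' Covariance matrix of the active random effects
#'
#' Builds the joint covariance implied by `omega2` and the named pairwise
#' correlations, restricted to random effects with positive variance, and
#' checks positive definiteness.
#'
#' @param spec An [hr_model_spec()].
#' @return Covariance matrix (possibly 0 x 0) with dimnames.
#' @export
iiv_covariance <- function(spec) {
  act <- active_etas(spec)
  d <- length(act)
  Omega <- matrix(0, d, d, dimnames = list(act, act))
  if (d == 0L) return(Omega)
  diag(Omega) <- spec$omega2[act]
  for (nm in names(spec$corr)) {
    pair <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (all(pair %in% act) && spec$corr[[nm]] != 0) {
      v <- spec$corr[[nm]] * sqrt(prod(spec$omega2[pair]))
      Omega[pair[1], pair[2]] <- Omega[pair[2], pair[1]] <- v
    }
  }
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("IIV covariance matrix is not positive definite; check corr/omega2")
  Omega
}
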