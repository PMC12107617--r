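# Marginal-likelihood machinery for the heart-rate model.
#
# The marginal likelihood per subject integrates the conditional data
# likelihood over the subject's random effects; the integral is approximated
# by Laplace's method at the per-subject conditional mode. The inner mode
# search is a damped Newton iteration with finite-difference derivatives,
# vectorised across subjects (every stencil evaluation is one full-data
# vectorised conditional log-likelihood call).

# Precompute data indexing shared by every likelihood evaluation.
hr_likelihood_context <- function(records, subjects) {
  records <- validate_ecg_records(records)
  subjects <- validate_subjects(subjects)
  records <- records[order(match(records$subject_id, subjects$subject_id)), ]
  subj_idx <- match(records$subject_id, subjects$subject_id)
  if (anyNA(subj_idx)) stop("records reference unknown subjects")
  occ_key <- paste(records$subject_id, records$occasion_id, sep = "\r")
  occ_idx <- match(occ_key, unique(occ_key))
  subj_of_occ <- subj_idx[!duplicated(occ_idx)]
  ref <- reference_covariates()
  lr <- function(v, r) ifelse(is.na(v), 0, log(v / r))
  list(
    y = records$hr_bpm,
    t = pmax(records$t_weeks, 0),
    ctime = records$ctime_h,
    conc = records$conc_m2,
    subj_idx = subj_idx,
    occ_idx = occ_idx,
    subj_of_occ = subj_of_occ,
    n_subj = nrow(subjects),
    n_occ = length(subj_of_occ),
    lr_ttp = lr(subjects$ttp_mgit_h, ref$ttp_mgit_h),
    lr_age = lr(subjects$age_y, ref$age_y),
    lr_weight = lr(subjects$weight_kg, ref$weight_kg),
    lr_albumin = lr(subjects$albumin_gL, ref$albumin_gL),
    is_c209 = as.numeric(subjects$study == "C209"),
    records = records, subjects = subjects)
}

# Conditional log-likelihood closure: given the current spec, returns
# f(E) -> per-subject log-likelihood vector, E an n_subj x d matrix of
# random-effect values with columns named after active etas (d may be 0).
make_cond_loglik <- function(ctx, spec) {
  if (spec$sigma_prop <= 0)
    stop("likelihood evaluation requires sigma_prop > 0")
  f_ttp <- exp(spec$cov_ttp_exp * ctx$lr_ttp)
  f_age <- exp(spec$cov_age_exp * ctx$lr_age)
  f_comp <- exp(spec$cov_weight_exp * ctx$lr_weight +
                spec$cov_albumin_exp * ctx$lr_albumin) *
    (1 + spec$study_effect_direction * spec$cov_study * ctx$is_c209)
  si <- ctx$subj_idx
  f_ttp_r <- f_ttp[si]; f_age_r <- f_age[si]; f_comp_r <- f_comp[si]
  cos24 <- cos(2 * pi * (ctx$ctime - spec$phi24) / 24)
  cos12 <- cos(2 * pi * (ctx$ctime - spec$phi12) / 12)
  decay <- switch(spec$time_effect_form,
                  asymptotic = 1 - exp(-log(2) * ctx$t / spec$t_prog),
                  linear = NULL)
  ln2pi <- log(2 * pi)
  function(E) {
    col <- function(nm) if (nm %in% colnames(E)) E[, nm] else
      rep(0, ctx$n_subj)
    base_i <- spec$hr_base * exp(col("hr_base")) * f_ttp
    rec_i <- spec$hr_rec * exp(col("hr_rec")) * f_age
    amp_i <- exp(boxcox_eta(col("amp"), spec$boxcox_lambda))
    base_r <- base_i[si]; rec_r <- rec_i[si]
    te <- if (spec$time_effect_form == "linear") spec$alpha * ctx$t
          else (rec_r - base_r) * decay
    diur <- (spec$amp24 * cos24 + spec$amp12 * cos12) * amp_i[si]
    m2 <- if ("ec50" %in% colnames(E)) {
      ec50_i <- spec$ec50_m2 * exp(E[, "ec50"])
      spec$emax_m2 * ctx$conc / (ec50_i[si] + ctx$conc)
    } else spec$emax_m2 * ctx$conc / (spec$ec50_m2 + ctx$conc)
    pred <- (base_r + te + diur) * (1 - m2) * f_comp_r
    sp_i <- spec$sigma_prop * exp(col("prop"))
    sa_i <- spec$sigma_add * exp(col("add"))
    r <- ctx$y - pred
    d <- (pmax(pred, 1e-6) * sp_i[si])^2
    parts <- rowsum(cbind(r * r / d, r / d, 1 / d, log(d)), ctx$occ_idx,
                    reorder = FALSE)
    a <- (sa_i[ctx$subj_of_occ])^2
    n_in_occ <- rowsum(rep(1, length(r)), ctx$occ_idx, reorder = FALSE)[, 1]
    denom <- 1 + a * parts[, 3]
    ll_occ <- -0.5 * (parts[, 4] + log(denom) +
                      parts[, 1] - a * parts[, 2]^2 / denom +
                      n_in_occ * ln2pi)
    # dense per-subject vector (subjects without records contribute 0)
    out <- rep(0, ctx$n_subj)
    agg <- rowsum(ll_occ, ctx$subj_of_occ)
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
  }
}

# Gaussian prior log-density per subject for an n x d matrix of etas.
make_prior_loglik <- function(Omega) {
  d <- ncol(Omega)
  R <- chol(Omega)
  Rinv <- backsolve(R, diag(d))
  logdet <- 2 * sum(log(diag(R)))
  function(E) {
    z <- E %*% Rinv
    -0.5 * (rowSums(z * z) + logdet + d * log(2 * pi))
  }
}

# Laplace approximation to -2 log marginal likelihood, vectorised damped
# Newton over all subjects simultaneously. `cache` (an environment) carries
# warm-start modes between calls during optimisation.
laplace_ofv_impl <- function(ctx, spec, cache = NULL,
                             inner_tol = 1e-6, max_inner = 100L,
                             trace = FALSE) {
  act <- active_etas(spec)
  d <- length(act)
  cond <- make_cond_loglik(ctx, spec)
  n <- ctx$n_subj
  if (d == 0L) {
    E0 <- matrix(numeric(0), nrow = n, ncol = 0)
    return(-2 * sum(cond(E0)))
  }
  Omega <- iiv_covariance(spec)
  prior <- make_prior_loglik(Omega)
  g <- function(E) {
    colnames(E) <- act
    val <- -(cond(E) + prior(E))
    val[!is.finite(val)] <- 1e30    # overflowed predictions: reject region
    val
  }
  E <- matrix(0, n, d, dimnames = list(NULL, act))
  if (!is.null(cache) && !is.null(cache$eta) &&
      identical(dim(cache$eta), dim(E)) &&
      identical(colnames(cache$eta), act)) E <- cache$eta
  h <- 1e-3
  f0 <- g(E)
  H <- array(0, c(n, d, d))
  grad <- matrix(0, n, d)
  for (iter in seq_len(max_inner)) {
    for (i in seq_len(d)) {
      Ei <- E; Ei[, i] <- E[, i] + h; fp <- g(Ei)
      Ei[, i] <- E[, i] - h; fm <- g(Ei)
      grad[, i] <- (fp - fm) / (2 * h)
      H[, i, i] <- (fp - 2 * f0 + fm) / h^2
      if (i < d) for (j in seq((i + 1L), d)) {
        Ei <- E
        Ei[, i] <- E[, i] + h; Ei[, j] <- E[, j] + h; fpp <- g(Ei)
        Ei[, j] <- E[, j] - h; fpm <- g(Ei)
        Ei[, i] <- E[, i] - h; fmm <- g(Ei)
        Ei[, j] <- E[, j] + h; fmp <- g(Ei)
        H[, i, j] <- H[, j, i] <- (fpp - fpm - fmp + fmm) / (4 * h^2)
      }
    }
    if (trace)
      cat(sprintf("inner iter %d: max|grad| %.3g, sum f %.6f\n",
                  iter, max(abs(grad)), sum(f0)))
    if (max(abs(grad)) < inner_tol * (1 + max(abs(f0)))) break
    # per-subject regularised Newton step
    step <- matrix(0, n, d)
    for (s in seq_len(n)) {
      Hs <- H[s, , , drop = TRUE]
      if (d == 1L) {
        Hs <- max(Hs, 1e-4)
        step[s, ] <- grad[s, ] / Hs
      } else {
        Hs <- matrix(Hs, d, d)
        ev <- eigen(Hs, symmetric = TRUE)
        lam <- pmax(ev$values, 1e-4)
        step[s, ] <- ev$vectors %*% ((t(ev$vectors) %*% grad[s, ]) / lam)
      }
    }
    # cap runaway steps (eta is a log-scale deviation; |step| > 3 is huge)
    too_big <- sqrt(rowSums(step^2)) > 3
    if (any(too_big))
      step[too_big, ] <- step[too_big, , drop = FALSE] * 3 /
        sqrt(rowSums(step[too_big, , drop = FALSE]^2))
    scal <- rep(1, n)
    repeat {
      Enew <- E - step * scal
      fnew <- g(Enew)
      worse <- !(fnew <= f0 + 1e-10)
      if (!any(worse)) break
      if (all(scal[worse] < 1e-6)) {    # no improvement possible: stay put
        scal[worse] <- 0
        Enew <- E - step * scal
        fnew <- g(Enew)
        break
      }
      scal[worse] <- scal[worse] / 2
    }
    moved <- max(abs(step * scal))
    E <- Enew
    f0 <- fnew
    if (moved < 1e-9) break
  }
  # log-determinants of the (regularised) conditional Hessians
  logdetH <- numeric(n)
  for (s in seq_len(n)) {
    Hs <- matrix(H[s, , ], d, d)
    ld <- tryCatch(2 * sum(log(diag(chol(Hs)))), error = function(e) NA_real_)
    if (is.na(ld)) {
      ev <- pmax(eigen(Hs, symmetric = TRUE, only.values = TRUE)$values, 1e-8)
      ld <- sum(log(ev))
    }
    logdetH[s] <- ld
  }
  if (!is.null(cache)) cache$eta <- E
  logL <- -f0 + 0.5 * d * log(2 * pi) - 0.5 * logdetH
  -2 * sum(logL)
}

#' Objective function value of the heart-rate model
#'
#' Computes OFV = \eqn{-2 \log} (total marginal likelihood of the data) under
#' an [hr_model_spec()]. Per subject the conditional likelihood (two-level
#' residual model: proportional per replicate, additive shared within a
#' triplicate occasion) is integrated over the active random effects by a
#' Laplace approximation at the conditional mode. With all IIV variances
#' zero the OFV is the exact closed-form Gaussian value.
#'
#' @param records ECG record data frame (HR observations used).
#' @param subjects Subject profile data frame.
#' @param spec An [hr_model_spec()].
#' @param inner_tol Convergence tolerance of the inner mode search.
#' @return The OFV (scalar).
#' @export
hr_ofv <- function(records, subjects, spec, inner_tol = 1e-6) {
  if (inherits(records, "ecg_data")) {
    subjects <- records$subjects; records <- records$records
  }
  ctx <- hr_likelihood_context(records, subjects)
  laplace_ofv_impl(ctx, spec, inner_tol = inner_tol)
}

# ---- parameter transforms for estimation ------------------------------------

.par_transforms <- local({
  logp <- c("hr_base", "hr_rec", "t_prog", "amp24", "amp12", "ec50_m2",
            "sigma_prop", "sigma_add",
            "omega2_hr_base", "omega2_hr_rec", "omega2_amp", "omega2_ec50",
            "omega2_prop", "omega2_add")
  logitp <- "emax_m2"
  list(log = logp, logit = logitp)
})

par_get <- function(spec, name) {
  if (startsWith(name, "omega2_")) spec$omega2[[sub("^omega2_", "", name)]]
  else spec[[name]]
}

par_set <- function(spec, name, value) {
  value <- unname(value)
  if (startsWith(name, "omega2_")) {
    spec$omega2[[sub("^omega2_", "", name)]] <- value
  } else spec[[name]] <- value
  spec
}

par_to_trans <- function(name, value) {
  if (name %in% .par_transforms$log) log(value)
  else if (name %in% .par_transforms$logit) stats::qlogis(value)
  else value
}

par_from_trans <- function(name, u) {
  if (name %in% .par_transforms$log) exp(u)
  else if (name %in% .par_transforms$logit) stats::plogis(u)
  else u
}

# d(natural)/d(transformed), for delta-method SEs
par_jacobian <- function(name, value) {
  if (name %in% .par_transforms$log) value
  else if (name %in% .par_transforms$logit) value * (1 - value)
  else 1
}

#' Fit the heart-rate model by maximum marginal likelihood
#'
#' Minimises the Laplace OFV over a chosen set of parameters, with positivity
#' enforced by log transforms (and a logit transform for `emax_m2`). Standard
#' errors come from the inverse numerical Hessian of OFV/2 at the optimum
#' (the observed Fisher information), mapped to the natural scale by the
#' delta method.
#'
#' @param records ECG record data frame, or an [ecg_data] object.
#' @param subjects Subject profile data frame (ignored when `records` is an
#'   `ecg_data`).
#' @param init An [hr_model_spec()] holding starting values and every fixed
#'   parameter.
#' @param mask Character vector of parameters to estimate. Structural and
#'   covariate parameters are addressed by name (`"hr_base"`, `"emax_m2"`,
#'   `"cov_albumin_exp"`, ...); IIV variances as `"omega2_hr_base"` etc.
#' @param se Compute standard errors (numerical Hessian; costs roughly as
#'   much as the fit itself for large masks).
#' @param control List: `inner_tol` (Laplace mode search, default `1e-6`),
#'   `outer_tol` (relative OFV tolerance, default `1e-4`), `max_iter`
#'   (default 500).
#' @return Object of class `hr_fit`: list with `spec` (estimates), `se`
#'   (named, natural scale), `ofv`, `convergence` (logical), `message`,
#'   `n_evals`, `mask`, and `vcov_trans` when `se = TRUE`.
#' @export
hr_fit <- function(records, subjects = NULL, init = hr_model_spec(),
                   mask = c("hr_base", "hr_rec", "t_prog"),
                   se = TRUE, control = list()) {
  if (inherits(records, "ecg_data")) {
    subjects <- records$subjects; records <- records$records
  }
  if (nrow(subjects) < 2L) stop("at least 2 subjects are required for fitting")
  ctrl <- utils::modifyList(list(inner_tol = 1e-6, outer_tol = 1e-4,
                                 max_iter = 500L), control)
  ctx <- hr_likelihood_context(records, subjects)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  u0 <- vapply(mask, function(nm) par_to_trans(nm, par_get(init, nm)),
               numeric(1))
  objective <- function(u) {
    spec <- init
    for (k in seq_along(mask))
      spec <- par_set(spec, mask[k], par_from_trans(mask[k], u[k]))
    n_evals <<- n_evals + 1L
    val <- tryCatch(
      laplace_ofv_impl(ctx, spec, cache = cache, inner_tol = ctrl$inner_tol),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  opt <- nlminb(u0, objective,
                control = list(iter.max = ctrl$max_iter,
                               eval.max = 20L * ctrl$max_iter,
                               rel.tol = ctrl$outer_tol / 2))
  est_spec <- init
  for (k in seq_along(mask))
    est_spec <- par_set(est_spec, mask[k], par_from_trans(mask[k], opt$par[k]))
  ses <- setNames(rep(NA_real_, length(mask)), mask)
  vcov_trans <- NULL
  if (se) {
    Hx <- tryCatch(optimHess(opt$par, function(u) objective(u) / 2),
                   error = function(e) NULL)
    if (!is.null(Hx)) {
      vcov_trans <- tryCatch(solve(Hx), error = function(e) NULL)
      if (!is.null(vcov_trans)) {
        sd_trans <- sqrt(pmax(diag(vcov_trans), 0))
        jac <- vapply(seq_along(mask), function(k)
          par_jacobian(mask[k], par_get(est_spec, mask[k])), numeric(1))
        ses <- setNames(sd_trans * abs(jac), mask)
      }
    }
  }
  structure(list(spec = est_spec, se = ses, ofv = opt$objective,
                 convergence = opt$convergence == 0L,
                 message = opt$message, n_evals = n_evals, mask = mask,
                 vcov_trans = vcov_trans),
            class = "hr_fit")
}

#' @export
print.hr_fit <- function(x, ...) {
  cat(sprintf("<hr_fit> OFV %.3f after %d evaluations (%s)\n", x$ofv,
              x$n_evals, if (x$convergence) "converged" else "NOT converged"))
  est <- vapply(x$mask, function(nm) par_get(x$spec, nm), numeric(1))
  tab <- data.frame(parameter = x$mask, estimate = est, se = x$se[x$mask],
                    row.names = NULL)
  print(tab, digits = 4)
  invisible(x)
}

#' Tabulate fit results in a report-style layout
#'
#' One row per estimated parameter: estimate, standard error and normal 95%
#' confidence interval on the natural scale.
#'
#' @param fit An [hr_fit()] result.
#' @return Data frame with columns `parameter`, `estimate`, `se`, `lo95`,
#'   `hi95`.
#' @export
fit_table <- function(fit) {
  est <- vapply(fit$mask, function(nm) par_get(fit$spec, nm), numeric(1))
  se <- fit$se[fit$mask]
  data.frame(parameter = fit$mask, estimate = est, se = se,
             lo95 = est - 1.96 * se, hi95 = est + 1.96 * se,
             row.names = NULL)
}
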