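options(qtctbt.quiet = TRUE)

# hand-written six-row fixture: one triplicate + singletons across 2 subjects
tiny_records <- function() {
  data.frame(
    subject_id = c("A", "A", "A", "A", "B", "B"),
    study = c(rep("C208", 4), rep("C209", 2)),
    arm = c(rep("placebo", 4), rep("active", 2)),
    t_weeks = c(-1 / 7, -1 / 7, -1 / 7, 2, -1 / 7, 24),
    ctime_h = c(9.5, 9.5, 9.5, 14, 10, 11.25),
    occasion_id = c("A1", "A1", "A1", "A2", "B1", "B2"),
    replicate = c(1L, 2L, 3L, 1L, 1L, 1L),
    hr_bpm = c(82.1, 80.4, 83.3, 75.2, 91.0, 72.5),
    qt_ms = c(361.2, 365.8, 358.9, 377.4, 340.1, 395.6),
    conc_m2 = c(0, 0, 0, 0, 0, 512.3),
    stringsAsFactors = FALSE)
}

tiny_subjects <- function() {
  data.frame(
    subject_id = c("A", "B"),
    study = c("C208", "C209"),
    arm = c("placebo", "active"),
    age_y = c(29, 41),
    weight_kg = c(52.5, 61),
    albumin_gL = c(33, 38),
    ttp_mgit_h = c(180, 412),
    stringsAsFactors = FALSE)
}

# single-replicate-per-occasion records for a one-subject likelihood toy
toy_subject_data <- function(n_obs = 12, hr = NULL, seed = 42) {
  set.seed(seed)
  t <- seq(0, 24, length.out = n_obs)
  recs <- data.frame(
    subject_id = "T1", study = "C208", arm = "placebo",
    t_weeks = t, ctime_h = rep(12, n_obs),
    occasion_id = sprintf("T1-%02d", seq_len(n_obs)),
    replicate = 1L,
    hr_bpm = if (is.null(hr)) 75 + rnorm(n_obs, 0, 4) else hr,
    qt_ms = NA_real_, conc_m2 = 0, stringsAsFactors = FALSE)
  subj <- data.frame(subject_id = "T1", study = "C208", arm = "placebo",
                     age_y = 33, weight_kg = 56, albumin_gL = 35,
                     ttp_mgit_h = 230.5, stringsAsFactors = FALSE)
  list(records = recs, subjects = subj)
}

# -2 log marginal likelihood by adaptive quadrature for 1-2 random effects
quadrature_ofv <- function(records, subjects, spec) {
  ctx <- qtctbt:::hr_likelihood_context(records, subjects)
  act <- qtctbt:::active_etas(spec)
  d <- length(act)
  cond <- qtctbt:::make_cond_loglik(ctx, spec)
  Omega <- iiv_covariance(spec)
  n <- nrow(subjects)
  stopifnot(n == 1L)
  if (d == 1L) {
    om <- sqrt(Omega[1, 1])
    integrand <- Vectorize(function(e) {
      E <- matrix(e, 1, 1, dimnames = list(NULL, act))
      exp(cond(E)) * stats::dnorm(e, 0, om)
    })
    L <- stats::integrate(integrand, -8 * om, 8 * om,
                          rel.tol = 1e-10)$value
  } else if (d == 2L) {
    # adaptive Gauss-Hermite centred at an independently located mode
    Oinv <- solve(Omega)
    ldet <- as.numeric(determinant(2 * pi * Omega, logarithm = TRUE)$modulus)
    logf <- function(e) {
      E <- matrix(e, 1, 2, dimnames = list(NULL, act))
      cond(E) - 0.5 * (drop(e %*% Oinv %*% e) + ldet)
    }
    opt <- stats::nlminb(c(0, 0), function(e) -logf(e))
    H <- stats::optimHess(opt$par, function(e) -logf(e))
    B <- t(chol(solve(H)))
    gh <- pracma::gaussHermite(48)
    s <- 0
    for (i in seq_along(gh$x)) for (j in seq_along(gh$x)) {
      z <- c(gh$x[i], gh$x[j])
      e <- opt$par + sqrt(2) * drop(B %*% z)
      s <- s + gh$w[i] * gh$w[j] * exp(sum(z^2) + logf(e))
    }
    L <- s * 2 * abs(det(B))     # 2^{d/2} |det B| with d = 2
  } else stop("oracle supports 1-2 random effects")
  -2 * log(L)
}
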