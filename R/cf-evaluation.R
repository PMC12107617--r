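#' Prespecified time-bin scheme
#'
#' The eight bins used for correction-quality evaluation and endpoint
#' summaries: pretreatment (t < 0), Week 0--1, Week 2--3, Week 3--4,
#' Week 5--8, Week 9--12, Week 13--20 and Week 20--24. Where two bins share
#' a printed boundary (week 3, week 20) the boundary belongs to the earlier
#' bin (`(start, end]`); a bin that follows a gap in the scheme (weeks 2, 5,
#' 9, 13, and week 0) is closed at its start, so scheduled visits at those
#' weeks are binned. The gap (1, 2) stays unbinned as printed. Bin midpoints
#' (used as the time coordinate of the slope trend) map pretreatment to
#' week 0.
#'
#' @return Data frame with columns `label`, `start`, `end`, `start_closed`,
#'   `midpoint`.
#' @export
time_bin_scheme <- function() {
  scheme <- data.frame(
    label = c("pretreatment", "wk0-1", "wk2-3", "wk3-4", "wk5-8", "wk9-12",
              "wk13-20", "wk20-24"),
    start = c(-Inf, 0, 2, 3, 5, 9, 13, 20),
    end = c(0, 1, 3, 4, 8, 12, 20, 24),
    start_closed = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  scheme$midpoint <- ifelse(scheme$label == "pretreatment", 0,
                            (pmax(scheme$start, 0) + scheme$end) / 2)
  scheme
}

validate_bin_scheme <- function(scheme) {
  stopifnot(is.data.frame(scheme),
            all(c("label", "start", "end") %in% names(scheme)))
  o <- order(scheme$start)
  if (any(scheme$end[o][-nrow(scheme)] > scheme$start[o][-1] + 1e-12))
    stop("time bins overlap")
  if (!"start_closed" %in% names(scheme)) {
    # close a bin's start when no earlier bin ends exactly there
    prev_end <- c(-Inf, scheme$end[o][-nrow(scheme)])
    scheme$start_closed[o] <- scheme$start[o] > prev_end + 1e-12
    scheme$start_closed[is.infinite(scheme$start)] <- FALSE
  }
  if (!"midpoint" %in% names(scheme))
    scheme$midpoint <- (pmax(scheme$start, 0) + pmin(scheme$end, 1e6)) / 2
  scheme
}

#' Assign records to time bins
#'
#' Pretreatment records (`t_weeks < 0`) go to the pretreatment bin; the
#' first treatment bin is closed at 0; the remaining bins are `(start, end]`.
#' Records falling in scheme gaps are left unassigned (`NA`) and their count
#' is logged.
#'
#' @param records ECG record data frame.
#' @param scheme Bin scheme from [time_bin_scheme()].
#' @return The records with a `bin` column (factor ordered by the scheme).
#' @export
assign_bins <- function(records, scheme = time_bin_scheme()) {
  scheme <- validate_bin_scheme(scheme)
  t <- records$t_weeks
  bin <- rep(NA_character_, length(t))
  for (k in seq_len(nrow(scheme))) {
    lo <- scheme$start[k]; hi <- scheme$end[k]
    inbin <- if (is.infinite(lo)) t < hi
             else if (scheme$start_closed[k]) t >= lo & t <= hi
             else t > lo & t <= hi
    bin[inbin] <- scheme$label[k]
  }
  n_out <- sum(is.na(bin))
  if (n_out > 0L)
    tbt_msg(n_out, " record(s) fall outside the bin scheme and are excluded")
  records$bin <- factor(bin, levels = scheme$label)
  records
}

#' Per-bin linear regression of QTc on heart rate
#'
#' Within each time bin fits ordinary least squares `QTc ~ HR` (ms per bpm)
#' and reports the slope with its standard error, t-based 95% CI and
#' \eqn{r^2}. A slope (and \eqn{r^2}) near 0 indicates that the correction
#' has made QTc independent of HR in that bin. Replicates enter
#' individually (they are not averaged); because the replicates and repeated
#' visits of one subject are correlated (shared subject-level QT and HR
#' deviations), the default standard errors are cluster-robust at the
#' subject level, with t CIs on `clusters - 1` degrees of freedom. Classic
#' iid OLS standard errors are available with `se_type = "ols"`. Bins with
#' fewer than 3 records or no HR spread are skipped with a warning.
#'
#' When `se_type = "cluster"` the result also carries the estimated
#' covariance of the bin slopes across bins (attribute `"slope_vcov"`,
#' built from per-subject score contributions), which [slope_trend()] uses
#' for calibrated trend inference.
#'
#' @param records ECG record data frame containing the `qtc_col` column.
#' @param qtc_col Name of the QTc column (e.g. `"qtc_tbt"` from
#'   [add_qtc()]).
#' @param scheme Bin scheme; applied with [assign_bins()] if `records` has
#'   no `bin` column.
#' @param center_hr Centre HR at 60 bpm before regressing (changes the
#'   intercept's meaning, not the slope).
#' @param se_type `"cluster"` (default) or `"ols"`.
#' @return Data frame of class `bin_slope_result`: one row per usable bin
#'   with `bin`, `midpoint`, `n`, `slope`, `intercept`, `se`, `lo95`,
#'   `hi95`, `r2`.
#' @export
bin_regression <- function(records, qtc_col, scheme = time_bin_scheme(),
                           center_hr = FALSE,
                           se_type = c("cluster", "ols")) {
  se_type <- match.arg(se_type)
  scheme <- validate_bin_scheme(scheme)
  if (!qtc_col %in% names(records))
    stop("records have no column '", qtc_col, "'")
  if (!"bin" %in% names(records)) records <- assign_bins(records, scheme)
  subj_all <- unique(records$subject_id)
  G <- length(subj_all)
  U <- NULL    # per-subject slope score contributions, one column per bin
  out <- lapply(levels(records$bin), function(lb) {
    dat <- records[!is.na(records$bin) & records$bin == lb, ]
    if (nrow(dat) < 3L) {
      warning("bin '", lb, "' has fewer than 3 records; skipped")
      return(NULL)
    }
    hr <- dat$hr_bpm - if (center_hr) 60 else 0
    if (var(hr) < 1e-12) {
      warning("bin '", lb, "' has no HR spread; skipped")
      return(NULL)
    }
    fit <- lm(dat[[qtc_col]] ~ hr)
    sm <- summary(fit)
    slope <- coef(fit)[[2]]
    r2 <- sm$r.squared
    # constant QTc: no variance to explain (raw ratio is numerically 0/0)
    if (!is.finite(r2) || var(dat[[qtc_col]]) < 1e-12) r2 <- 0
    if (se_type == "cluster") {
      xt <- hr - mean(hr)
      sxx <- sum(xt^2)
      ui <- rowsum(xt * stats::residuals(fit), dat$subject_id) / sxx
      u <- setNames(rep(0, G), subj_all)
      u[rownames(ui)] <- ui[, 1]
      U <<- cbind(U, u)
      colnames(U)[ncol(U)] <<- lb
      g <- nrow(ui)
      se <- sqrt(g / (g - 1) * sum(ui^2))
      dfree <- g - 1
    } else {
      se <- sm$coefficients[2, 2]
      dfree <- fit$df.residual
    }
    tcrit <- qt(0.975, df = dfree)
    data.frame(bin = lb,
               midpoint = scheme$midpoint[scheme$label == lb],
               n = nrow(dat), slope = slope,
               intercept = coef(fit)[[1]], se = se,
               lo95 = slope - tcrit * se, hi95 = slope + tcrit * se,
               r2 = r2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)       # every bin was skipped
  if (se_type == "cluster" && !is.null(U))
    attr(res, "slope_vcov") <- crossprod(U) * G / (G - 1)
  attr(res, "se_type") <- se_type
  class(res) <- c("bin_slope_result", class(res))
  res
}

#' Trend of QTc-versus-HR slopes over time bins
#'
#' Second step of the two-step evaluation: the per-bin slopes are used as
#' data points in a linear regression against bin midpoint (pretreatment
#' mapped to week 0), weighted by their standard errors (inverse-variance
#' weights \eqn{1/SE^2} by default). For a successful correction both the
#' intercept (the QTc/HR slope at treatment start) and the trend slope
#' should be close to 0.
#'
#' When the bins carry the cross-bin slope covariance (cluster-robust
#' [bin_regression()]), the intercept/trend CIs use that full covariance
#' (slopes from different bins share subjects and are correlated); otherwise
#' they come from the weighted residual scatter of the 8 points.
#'
#' @param bins A [bin_regression()] result (>= 3 usable bins).
#' @param weighting `"inverse_variance"` (\eqn{1/SE^2}) or `"inverse_se"`
#'   (\eqn{1/SE}).
#' @return List of class `slope_trend_result`: `intercept`, `intercept_ci`,
#'   `trend`, `trend_ci`, `weighting`, and (classic path only) the
#'   underlying `lm` fit.
#' @export
slope_trend <- function(bins, weighting = c("inverse_variance",
                                            "inverse_se")) {
  weighting <- match.arg(weighting)
  if (is.null(bins) || nrow(bins) < 3L)
    stop("slope trend requires at least 3 usable bins")
  w <- switch(weighting,
              inverse_variance = 1 / bins$se^2,
              inverse_se = 1 / bins$se)
  Sig <- attr(bins, "slope_vcov")
  if (!is.null(Sig) && all(bins$bin %in% rownames(Sig))) {
    Sig <- Sig[bins$bin, bins$bin, drop = FALSE]
    X <- cbind(1, bins$midpoint)
    A <- solve(crossprod(X, w * X), t(X * w))
    beta <- drop(A %*% bins$slope)
    Vb <- A %*% Sig %*% t(A)
    tcrit <- qt(0.975, df = nrow(bins) - 2L)
    half <- tcrit * sqrt(diag(Vb))
    structure(list(intercept = beta[1],
                   intercept_ci = c(beta[1] - half[1], beta[1] + half[1]),
                   trend = beta[2],
                   trend_ci = c(beta[2] - half[2], beta[2] + half[2]),
                   weighting = weighting, vcov = Vb, fit = NULL),
              class = "slope_trend_result")
  } else {
    fit <- lm(slope ~ midpoint, data = bins, weights = w)
    ci <- confint(fit, level = 0.95)
    structure(list(intercept = coef(fit)[[1]],
                   intercept_ci = unname(ci[1, ]),
                   trend = coef(fit)[[2]],
                   trend_ci = unname(ci[2, ]),
                   weighting = weighting, vcov = vcov(fit), fit = fit),
              class = "slope_trend_result")
  }
}

#' @export
print.slope_trend_result <- function(x, ...) {
  cat(sprintf("slope at time 0 (intercept): %.4f ms/bpm (95%% CI %.4f, %.4f)\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("trend over time: %.4f ms/bpm per week (95%% CI %.4f, %.4f)\n",
              x$trend, x$trend_ci[1], x$trend_ci[2]))
  invisible(x)
}

#' Comparative evaluation of correction methods
#'
#' Runs the two-step evaluation for each requested correction: per-bin
#' QTc-versus-HR regressions, the SE-weighted slope trend, and the number of
#' bins whose slope CI covers 0.
#'
#' @param records ECG record data frame with `qt_ms` filled (QTc columns are
#'   added as needed), or an [ecg_data] object.
#' @param methods Character vector of correction method names.
#' @param scheme Bin scheme.
#' @return List of class `cf_evaluation`: per method a list with `bins`
#'   ([bin_regression()] rows), `trend` ([slope_trend()]), and
#'   `n_cover_zero`.
#' @export
evaluate_corrections <- function(records,
                                 methods = c("tbt", "fridericia", "bazett",
                                             "olliaro"),
                                 scheme = time_bin_scheme()) {
  if (inherits(records, "ecg_data")) records <- records$records
  records <- add_qtc(records, methods)
  records <- assign_bins(records, scheme)
  res <- lapply(methods, function(m) {
    bins <- bin_regression(records, paste0("qtc_", m), scheme)
    trend <- if (!is.null(bins) && nrow(bins) >= 3L) slope_trend(bins)
             else NULL
    list(method = m, bins = bins, trend = trend,
         n_cover_zero = if (is.null(bins)) 0L
                        else sum(bins$lo95 <= 0 & bins$hi95 >= 0),
         n_bins = if (is.null(bins)) 0L else nrow(bins))
  })
  names(res) <- methods
  structure(list(methods = res, records = records), class = "cf_evaluation")
}

#' @export
print.cf_evaluation <- function(x, ...) {
  for (m in x$methods) {
    cat(sprintf("== %s: slope CI covers 0 in %d/%d bins\n", m$method,
                m$n_cover_zero, m$n_bins))
    if (!is.null(m$trend)) print(m$trend)
  }
  invisible(x)
}

#' Panel plot of QTc versus HR by time bin and method
#'
#' A faceted scatter of QTc against HR per bin per correction method, with
#' the per-bin regression line and the reference QTc at 60 bpm.
#'
#' @param x A [evaluate_corrections()] result.
#' @param methods Subset of methods to show (default all).
#' @return A ggplot object.
#' @export
plot_qtc_hr <- function(x, methods = names(x$methods)) {
  stopifnot(inherits(x, "cf_evaluation"))
  recs <- x$records[!is.na(x$records$bin), ]
  long <- do.call(rbind, lapply(methods, function(m) {
    data.frame(method = m, bin = recs$bin, hr_bpm = recs$hr_bpm,
               qtc = recs[[paste0("qtc_", m)]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = hr_bpm, y = qtc)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, linewidth = 0.5,
                         color = "blue") +
    ggplot2::facet_grid(method ~ bin) +
    ggplot2::labs(x = "Heart rate (bpm)", y = "QTc (ms)") +
    ggplot2::theme_bw()
}
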