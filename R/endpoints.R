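utils::globalVariables(c("hr_bpm", "qtc", "midpoint", "percentile", "lo",
                         "hi", "observed"))

#' Baseline corrected QT per subject
#'
#' Pretreatment (baseline) QTc is the mean of the subject's Day −1 triplicate
#' QTc values, corrected with the same method as the endpoint: the Day −1
#' 5 h postdose occasion serves the 5-hour assessments and the Day −1
#' predose occasion all others. Time-varying corrections clamp to the
#' pretreatment exponent at `t < 0`.
#'
#' @param records ECG record data frame with the `qtc_col` column (see
#'   [add_qtc()]); an `assessment` column (values `"predose"`/`"5h"`) selects
#'   the matching baseline occasion when present.
#' @param qtc_col QTc column name.
#' @param kind Assessment kind of the baseline: `"predose"` (default) or
#'   `"5h"`.
#' @return Named numeric vector of baselines (one per subject with Day −1
#'   records); subjects without a matching Day −1 occasion are omitted with a
#'   log message.
#' @export
baseline_qtc <- function(records, qtc_col, kind = "predose") {
  if (!qtc_col %in% names(records))
    stop("records have no column '", qtc_col, "'")
  pre <- records[records$t_weeks < 0, ]
  if ("assessment" %in% names(pre) && any(pre$assessment == kind))
    pre <- pre[pre$assessment == kind, ]
  base <- c(tapply(pre[[qtc_col]], pre$subject_id, mean))  # named vector
  missing <- setdiff(unique(records$subject_id), names(base))
  if (length(missing) > 0L)
    tbt_msg(length(missing),
            " subject(s) lack Day -1 records and are excluded from delta endpoints")
  base
}

#' Change from baseline in QTc
#'
#' Per-record \eqn{\Delta QTc = QTc_{ij} - baseline_i}. Records of subjects
#' without a baseline get `NA`.
#'
#' @inheritParams baseline_qtc
#' @return The records with a `delta` column appended (named
#'   `d<qtc_col>`).
#' @export
delta_qtc <- function(records, qtc_col, kind = "predose") {
  base <- baseline_qtc(records, qtc_col, kind)
  records[[paste0("d", qtc_col)]] <-
    records[[qtc_col]] - unname(base[records$subject_id])
  records
}

# subject-level aggregation within bins, then a one-sample t CI; avoids
# pseudo-replication from triplicates
subject_bin_means <- function(records, col, scheme) {
  if (!"bin" %in% names(records)) records <- assign_bins(records, scheme)
  dat <- records[!is.na(records$bin) & !is.na(records[[col]]), ]
  agg <- stats::aggregate(dat[[col]],
                          by = list(bin = dat$bin, arm = dat$arm,
                                    subject_id = dat$subject_id),
                          FUN = mean)
  names(agg)[4] <- "value"
  agg
}

t_ci <- function(x) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lo95 = NA_real_, hi95 = NA_real_, n = n))
  half <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo95 = m - half, hi95 = m + half, n = n)
}

#' Placebo-corrected change from baseline in QTc
#'
#' Per bin, mean \eqn{\Delta QTc} in the active arm minus mean
#' \eqn{\Delta QTc} in the placebo arm, with a two-sample t-based 95% CI on
#' subject-level bin means. Bins missing either arm are omitted with a
#' warning.
#'
#' @inheritParams baseline_qtc
#' @param scheme Bin scheme ([time_bin_scheme()]).
#' @return Data frame: one row per bin with `bin`, `n_active`, `n_placebo`,
#'   `mean`, `lo95`, `hi95`.
#' @export
delta_delta_qtc <- function(records, qtc_col, scheme = time_bin_scheme(),
                            kind = "predose") {
  if (!all(c("active", "placebo") %in% records$arm))
    stop("placebo-corrected endpoints require both arms in the data")
  records <- delta_qtc(records, qtc_col, kind)
  dcol <- paste0("d", qtc_col)
  agg <- subject_bin_means(records, dcol, scheme)
  out <- lapply(levels(agg$bin), function(lb) {
    a <- agg$value[agg$bin == lb & agg$arm == "active"]
    p <- agg$value[agg$bin == lb & agg$arm == "placebo"]
    if (length(a) == 0L && length(p) == 0L) return(NULL)   # empty bin
    if (length(a) < 2L || length(p) < 2L) {
      warning("bin '", lb, "' lacks one arm; omitted from delta-delta")
      return(NULL)
    }
    d <- mean(a) - mean(p)
    se <- sqrt(var(a) / length(a) + var(p) / length(p))
    df <- length(a) + length(p) - 2
    half <- qt(0.975, df) * se
    data.frame(bin = lb, n_active = length(a), n_placebo = length(p),
               mean = d, lo95 = d - half, hi95 = d + half,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summary table of standard QTc prolongation endpoints
#'
#' Mean and t-based 95% CI (on subject-level bin means) of absolute QTc and
#' \eqn{\Delta QTc} per arm, plus \eqn{\Delta\Delta QTc} when both arms are
#' present, for each correction method over the prespecified time bins.
#'
#' @param records ECG record data frame with `qt_ms` filled, or an
#'   [ecg_data] object.
#' @param methods Character vector of correction method names.
#' @param scheme Bin scheme.
#' @return Data frame with columns `method`, `endpoint` (`absolute`,
#'   `delta`, `delta_delta`), `arm`, `bin`, `n`, `mean`, `lo95`, `hi95`.
#' @export
summarize_endpoints <- function(records,
                                methods = c("tbt", "fridericia"),
                                scheme = time_bin_scheme()) {
  if (inherits(records, "ecg_data")) records <- records$records
  records <- add_qtc(records, methods)
  records <- assign_bins(records, scheme)
  both_arms <- all(c("active", "placebo") %in% records$arm)
  rows <- list()
  for (m in methods) {
    qc <- paste0("qtc_", m)
    recs <- delta_qtc(records, qc)
    for (ep in c("absolute", "delta")) {
      col <- if (ep == "absolute") qc else paste0("d", qc)
      agg <- subject_bin_means(recs, col, scheme)
      for (lb in levels(agg$bin)) for (a in unique(agg$arm)) {
        v <- agg$value[agg$bin == lb & agg$arm == a]
        if (length(v) == 0L) next
        ci <- t_ci(v)
        rows[[length(rows) + 1L]] <-
          data.frame(method = m, endpoint = ep, arm = a, bin = lb,
                     n = ci[["n"]], mean = ci[["mean"]],
                     lo95 = ci[["lo95"]], hi95 = ci[["hi95"]],
                     stringsAsFactors = FALSE)
      }
    }
    if (both_arms) {
      dd <- delta_delta_qtc(records, qc, scheme)
      if (!is.null(dd) && nrow(dd) > 0L)
        rows[[length(rows) + 1L]] <-
          data.frame(method = m, endpoint = "delta_delta", arm = "both",
                     bin = dd$bin, n = dd$n_active + dd$n_placebo,
                     mean = dd$mean, lo95 = dd$lo95, hi95 = dd$hi95,
                     stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
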