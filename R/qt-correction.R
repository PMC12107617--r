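#' Heart rate / RR interval conversion
#'
#' Standard identity `RR(s) = 60 / HR(bpm)` and its inverse.
#'
#' @param hr_bpm Heart rate (beats/min), > 0.
#' @return RR interval in seconds.
#' @export
rr_from_hr <- function(hr_bpm) {
  if (any(hr_bpm <= 0)) stop("hr_bpm must be > 0")
  60 / hr_bpm
}

#' @rdname rr_from_hr
#' @param rr_s RR interval (seconds), > 0.
#' @export
hr_from_rr <- function(rr_s) {
  if (any(rr_s <= 0)) stop("rr_s must be > 0")
  60 / rr_s
}

#' QT correction method specification
#'
#' Named methods and their conventions:
#' \describe{
#'   \item{bazett / fridericia / olliaro}{power-law \eqn{QTc = QT / RR^x}
#'     with exponents 0.5, 0.33 and 0.4081 (RR in seconds). The Fridericia
#'     exponent is 0.33, matching the usage the time-varying factor declines
#'     to.}
#'   \item{framingham}{\eqn{QTc = QT + 154 (1 - RR)} with RR in seconds and
#'     QT in ms (the published 0.154 s rescaled).}
#'   \item{vandewater}{\eqn{QTc = QT - 0.087 (RR - 1000)} with RR in ms.}
#'   \item{tbt}{the time-varying power law for TB patients on treatment:
#'     exponent [cf_tbt()] declining from `cf_pre` (0.4081) to `cf_post`
#'     (0.33) with half-life `t_half` (7.74 weeks).}
#'   \item{power}{custom fixed exponent.}
#'   \item{time_varying}{custom `cf_pre`/`cf_post`/`t_half`.}
#' }
#'
#' @param method One of `"bazett"`, `"fridericia"`, `"olliaro"`,
#'   `"framingham"`, `"vandewater"`, `"tbt"`, `"power"`, `"time_varying"`.
#' @param exponent Exponent for `method = "power"`.
#' @param cf_pre,cf_post,t_half Parameters of the time-varying factor
#'   (`cf_pre >= cf_post > 0`, `t_half > 0`).
#' @return A list of class `correction_spec` with elements `method`,
#'   `label`, and the relevant parameters.
#' @export
#' @examples
#' correction_spec("tbt")
#' correction_spec("power", exponent = 0.42)
correction_spec <- function(method = c("tbt", "fridericia", "bazett",
                                       "olliaro", "framingham", "vandewater",
                                       "power", "time_varying"),
                            exponent = NULL,
                            cf_pre = 0.4081, cf_post = 0.33, t_half = 7.74) {
  method <- match.arg(method)
  spec <- switch(method,
    bazett = list(method = "power", exponent = 0.5, label = "QTcB"),
    fridericia = list(method = "power", exponent = 0.33, label = "QTcF"),
    olliaro = list(method = "power", exponent = 0.4081, label = "QTcO"),
    framingham = list(method = "framingham", label = "QTcFra"),
    vandewater = list(method = "vandewater", label = "QTcVa"),
    tbt = list(method = "time_varying", cf_pre = 0.4081, cf_post = 0.33,
               t_half = 7.74, label = "QTcTBT"),
    power = {
      if (is.null(exponent)) stop("method 'power' requires an exponent")
      list(method = "power", exponent = exponent, label = "QTc")
    },
    time_varying = list(method = "time_varying", cf_pre = cf_pre,
                        cf_post = cf_post, t_half = t_half, label = "QTc"))
  if (method == "time_varying") {
    spec$cf_pre <- cf_pre; spec$cf_post <- cf_post; spec$t_half <- t_half
  }
  if (!is.null(spec$exponent) && spec$exponent <= 0)
    stop("exponent must be > 0")
  if (spec$method == "time_varying") {
    if (spec$cf_pre < spec$cf_post)
      stop("cf_pre must be >= cf_post (the factor declines with recovery)")
    if (spec$cf_post <= 0 || spec$t_half <= 0)
      stop("cf_post and t_half must be > 0")
  }
  structure(spec, class = "correction_spec")
}

#' @export
print.correction_spec <- function(x, ...) {
  if (x$method == "time_varying")
    cat(sprintf("<correction_spec> %s: QT/RR^CF(t), CF %0.4f -> %0.4f, half-life %.2f wk\n",
                x$label, x$cf_pre, x$cf_post, x$t_half))
  else if (x$method == "power")
    cat(sprintf("<correction_spec> %s: QT/RR^%.4f\n", x$label, x$exponent))
  else cat(sprintf("<correction_spec> %s (%s)\n", x$label, x$method))
  invisible(x)
}

#' Time-varying correction factor
#'
#' The exponent of the time-varying QT correction for TB patients on
#' treatment:
#' \deqn{CF(t) = CF_{pre} - (CF_{pre} - CF_{post})(1 - e^{-\ln 2 \, t /
#'   t_{1/2}})}
#' declining from the pretreatment exponent 0.4081 towards the Fridericia
#' exponent 0.33 with the heart-rate recovery half-life 7.74 weeks.
#' Pretreatment times (`t < 0`) clamp to `cf_pre`.
#'
#' @param t_weeks Time after start of treatment (weeks); vectorised.
#' @param spec A [correction_spec()] with `method = "time_varying"`
#'   (default: the published TBT factor).
#' @return Exponent value(s).
#' @export
#' @examples
#' cf_tbt(c(0, 7.74, 1e4))  # 0.4081, 0.36905, ~0.33
cf_tbt <- function(t_weeks, spec = correction_spec("tbt")) {
  if (spec$method != "time_varying")
    stop("cf_tbt requires a time-varying correction spec")
  t <- pmax(t_weeks, 0)
  spec$cf_pre - (spec$cf_pre - spec$cf_post) *
    (1 - exp(-log(2) * t / spec$t_half))
}

# exponent of a power-law correction at given times (NA for linear methods)
correction_exponent <- function(spec, t_weeks) {
  switch(spec$method,
         power = rep(spec$exponent, length(t_weeks)),
         time_varying = cf_tbt(t_weeks, spec),
         stop("correction method '", spec$method, "' has no exponent"))
}

#' Correct a QT interval for heart rate
#'
#' Applies the selected correction: power-law methods divide by
#' \eqn{RR^x} (RR in seconds; the exponent constant or time-varying),
#' Framingham adds \eqn{154 (1 - RR_s)} ms and Van de Water subtracts
#' \eqn{0.087 (RR_{ms} - 1000)} ms. At HR 60 bpm (RR = 1 s) every method
#' returns QT unchanged.
#'
#' @param qt_ms QT interval (ms); vectorised.
#' @param hr_bpm Heart rate (bpm); vectorised.
#' @param t_weeks Treatment time (weeks); needed for time-varying methods.
#' @param spec A [correction_spec()] or a method name accepted by it.
#' @return QTc (ms).
#' @export
#' @examples
#' correct_qt(360, 90, spec = "fridericia")       # ~412.9
#' correct_qt(360, 90, t_weeks = 0, spec = "tbt") # ~424.9
correct_qt <- function(qt_ms, hr_bpm, t_weeks = NULL, spec = "tbt") {
  if (is.character(spec)) spec <- correction_spec(spec)
  if (any(qt_ms <= 0)) stop("qt_ms must be > 0")
  rr_s <- rr_from_hr(hr_bpm)
  switch(spec$method,
         power = qt_ms / rr_s^spec$exponent,
         time_varying = {
           if (is.null(t_weeks))
             stop("time-varying correction requires t_weeks")
           qt_ms / rr_s^cf_tbt(t_weeks, spec)
         },
         framingham = qt_ms + 154 * (1 - rr_s),
         vandewater = qt_ms - 0.087 * (rr_s * 1000 - 1000),
         stop("unknown correction method: ", spec$method))
}

#' Append QTc columns to an ECG table
#'
#' For each requested method adds a column `qtc_<name>` computed from
#' `qt_ms`, `hr_bpm` and `t_weeks`.
#'
#' @param records ECG record data frame (or [ecg_data]; records returned).
#' @param methods Character vector of method names for [correction_spec()],
#'   or a named list of `correction_spec` objects.
#' @return The records with one extra column per method.
#' @export
add_qtc <- function(records, methods = c("tbt", "fridericia", "bazett",
                                         "olliaro")) {
  if (inherits(records, "ecg_data")) records <- records$records
  if (is.character(methods))
    methods <- setNames(lapply(methods, correction_spec), methods)
  for (nm in names(methods)) {
    records[[paste0("qtc_", nm)]] <-
      correct_qt(records$qt_ms, records$hr_bpm, records$t_weeks,
                 methods[[nm]])
  }
  records
}
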