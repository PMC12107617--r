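#' Stepwise covariate selection
#'
#' One direction of stepwise covariate modelling on the heart-rate model,
#' iterated to a fixed point. Forward selection adds, among the remaining
#' candidates, the covariate effect with the largest OFV drop if that drop
#' exceeds 3.84 (1 df, P < 0.05); backward elimination removes the weakest
#' included effect if its removal raises the OFV by less than 6.63 (1 df,
#' P < 0.01).
#'
#' @param records ECG record data frame, or an [ecg_data] object.
#' @param subjects Subject profile data frame.
#' @param base_spec An [hr_model_spec()]; candidate covariate exponents not
#'   yet included should be 0 in it.
#' @param candidates Character vector of covariate parameter names to test
#'   (e.g. `"cov_albumin_exp"`, `"cov_weight_exp"`, `"cov_study"`).
#' @param direction `"forward"` or `"backward"`.
#' @param base_mask Parameters re-estimated in every fit (see [hr_fit()]).
#' @param included Covariate parameters already in the model (backward
#'   starts from these; forward adds to them).
#' @param control Passed to [hr_fit()].
#' @return List of class `scm_result`: `spec` (selected model), `included`,
#'   `trace` (data frame of steps with OFVs and decisions).
#' @export
scm_step <- function(records, subjects = NULL, base_spec = hr_model_spec(),
                     candidates = character(0),
                     direction = c("forward", "backward"),
                     base_mask = c("hr_base", "hr_rec", "t_prog"),
                     included = character(0), control = list()) {
  direction <- match.arg(direction)
  if (inherits(records, "ecg_data")) {
    subjects <- records$subjects; records <- records$records
  }
  refit <- function(spec, mask) {
    hr_fit(records, subjects, init = spec, mask = mask, se = FALSE,
           control = control)
  }
  trace <- list()
  spec <- base_spec
  pool <- setdiff(candidates, included)
  current <- refit(spec, c(base_mask, included))
  repeat {
    if (direction == "forward") {
      if (length(pool) == 0L) break
      fits <- lapply(pool, function(p)
        refit(current$spec, c(base_mask, included, p)))
      dofv <- current$ofv - vapply(fits, function(f) f$ofv, numeric(1))
      best <- which.max(dofv)
      trace[[length(trace) + 1L]] <- data.frame(
        direction = "forward", candidate = pool[best],
        dofv = dofv[best], accepted = dofv[best] > 3.84)
      if (dofv[best] <= 3.84) break
      included <- c(included, pool[best])
      current <- fits[[best]]
      pool <- pool[-best]
    } else {
      if (length(included) == 0L) break
      fits <- lapply(included, function(p) {
        sp <- par_set(current$spec, p, 0)
        refit(sp, c(base_mask, setdiff(included, p)))
      })
      dofv <- vapply(fits, function(f) f$ofv, numeric(1)) - current$ofv
      worst <- which.min(dofv)
      trace[[length(trace) + 1L]] <- data.frame(
        direction = "backward", candidate = included[worst],
        dofv = dofv[worst], accepted = dofv[worst] < 6.63)
      if (dofv[worst] >= 6.63) break
      current <- fits[[worst]]
      included <- setdiff(included, included[worst])
    }
  }
  structure(list(spec = current$spec, included = included, ofv = current$ofv,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame()),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("<scm_result> included covariate effects:",
      if (length(x$included)) paste(x$included, collapse = ", ") else "none",
      sprintf("\n  final OFV %.3f\n", x$ofv))
  if (nrow(x$trace)) print(x$trace, digits = 4)
  invisible(x)
}
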