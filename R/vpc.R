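#' Visual predictive check of the heart-rate model
#'
#' Simulates `n_sim` replicates of the observed design (same subjects,
#' times, clock times and concentrations) from the model, computes the
#' 2.5th/50th/97.5th HR percentiles per time bin in each replicate, and
#' reports the 95% band of each percentile alongside the observed
#' percentiles.
#'
#' @param records ECG record data frame (observed HR), or an [ecg_data].
#' @param subjects Subject profile data frame.
#' @param spec An [hr_model_spec()].
#' @param n_sim Number of simulation replicates (>= 100 for stable bands;
#'   smaller values allowed but flagged).
#' @param scheme Time-bin scheme ([time_bin_scheme()]); empty bins are
#'   dropped with a warning.
#' @param seed Optional integer seed.
#' @return Object of class `vpc_result`: data frame `summary` with, per bin
#'   and percentile, the observed value and the simulation band, plus
#'   `n_sim`.
#' @export
vpc <- function(records, subjects = NULL, spec = hr_model_spec(),
                n_sim = 200L, scheme = time_bin_scheme(), seed = NULL) {
  if (inherits(records, "ecg_data")) {
    subjects <- records$subjects; records <- records$records
  }
  if (n_sim < 100L)
    tbt_msg("n_sim < 100: percentile bands will be noisy")
  if (!is.null(seed)) set.seed(seed)
  records <- assign_bins(records, scheme)
  keep <- !is.na(records$bin)
  if (!all(keep)) records <- records[keep, ]
  empty <- setdiff(scheme$label, unique(as.character(records$bin)))
  if (length(empty) > 0L)
    warning("empty bin(s) dropped: ", paste(empty, collapse = ", "))
  probs <- c(0.025, 0.5, 0.975)
  pct <- function(hr) {
    do.call(rbind, tapply(hr, records$bin, quantile, probs = probs,
                          names = FALSE))
  }
  obs <- pct(records$hr_bpm)
  sims <- array(NA_real_, c(nrow(obs), 3L, n_sim))
  for (k in seq_len(n_sim))
    sims[, , k] <- pct(sim_hr_draw(records, subjects, spec))
  band_lo <- apply(sims, c(1, 2), quantile, probs = 0.025)
  band_hi <- apply(sims, c(1, 2), quantile, probs = 0.975)
  used <- rownames(obs)
  summary <- do.call(rbind, lapply(seq_along(probs), function(j) {
    data.frame(bin = used,
               midpoint = scheme$midpoint[match(used, scheme$label)],
               percentile = 100 * probs[j],
               observed = obs[, j], lo = band_lo[, j], hi = band_hi[, j],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, n_sim = n_sim), class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  inside <- with(x$summary, observed >= lo & observed <= hi)
  cat(sprintf("<vpc_result> %d simulation replicates; observed percentile inside its band in %d/%d bin-percentiles\n",
              x$n_sim, sum(inside), length(inside)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @rdname vpc
#' @param x A `vpc_result`.
#' @param ... Unused.
#' @export
plot.vpc_result <- function(x, ...) {
  s <- x$summary
  s$percentile <- factor(s$percentile)
  ggplot2::ggplot(s, ggplot2::aes(x = midpoint, group = percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi), alpha = 0.25,
                         fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = observed), linetype = 2) +
    ggplot2::labs(x = "Time after start of treatment (weeks)",
                  y = "Heart rate (bpm)") +
    ggplot2::theme_bw()
}
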