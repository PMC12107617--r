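#' @keywords internal
.ecg_record_cols <- c("subject_id", "study", "arm", "t_weeks", "ctime_h",
                      "occasion_id", "replicate", "hr_bpm", "qt_ms", "conc_m2")

#' @keywords internal
.subject_cols <- c("subject_id", "study", "arm", "age_y", "weight_kg",
                   "albumin_gL", "ttp_mgit_h")

#' Covariate reference values of the final heart-rate model
#'
#' Reference covariate values at which all covariate factors equal 1:
#' body weight 56 kg, serum albumin 35 g/L, age 33 years, baseline MGIT
#' time-to-positivity 230.5 h, study C208.
#'
#' @return Named list with elements `weight_kg`, `albumin_gL`, `age_y`,
#'   `ttp_mgit_h`, `study`.
#' @export
reference_covariates <- function() {
  list(weight_kg = 56, albumin_gL = 35, age_y = 33, ttp_mgit_h = 230.5,
       study = "C208")
}

tbt_msg <- function(...) {
  if (!isTRUE(getOption("qtctbt.quiet", FALSE))) message(...)
}

#' Bundle ECG records and subject profiles
#'
#' Light container pairing the long-format ECG replicate table with the
#' one-row-per-subject covariate table. Both components are validated.
#'
#' @param records Data frame of ECG replicates (one row per ECG); see
#'   [validate_ecg_records()] for the required columns and invariants.
#' @param subjects Data frame of subject profiles, one row per subject.
#' @return An object of class `ecg_data`: a list with elements `records` and
#'   `subjects`.
#' @export
ecg_data <- function(records, subjects) {
  records <- validate_ecg_records(records)
  subjects <- validate_subjects(subjects)
  missing_subj <- setdiff(unique(records$subject_id), subjects$subject_id)
  if (length(missing_subj) > 0L)
    stop("records reference subjects absent from the subject table: ",
         paste(head(missing_subj, 5L), collapse = ", "))
  structure(list(records = records, subjects = subjects), class = "ecg_data")
}

#' @export
print.ecg_data <- function(x, ...) {
  cat(sprintf("<ecg_data> %d ECG replicates, %d subjects (%d active / %d placebo)\n",
              nrow(x$records), nrow(x$subjects),
              sum(x$subjects$arm == "active"), sum(x$subjects$arm == "placebo")))
  cat(sprintf("  t range: %.2f to %.2f weeks; HR %.0f-%.0f bpm\n",
              min(x$records$t_weeks), max(x$records$t_weeks),
              min(x$records$hr_bpm), max(x$records$hr_bpm)))
  invisible(x)
}

#' Validate a long-format ECG replicate table
#'
#' Checks the schema and row-level invariants of the canonical ECG table:
#' positive HR and QT, non-negative M2 concentration, clock time in
#' \[0, 24), replicate index in 1--3, and consistency of `subject_id`,
#' `t_weeks` and `ctime_h` within a triplicate occasion. A missing `conc_m2`
#' column is filled with 0 (no measurable exposure, e.g. placebo) with a
#' warning-level log message.
#'
#' @param records Data frame with columns `subject_id`, `study`, `arm`,
#'   `t_weeks`, `ctime_h`, `occasion_id`, `replicate`, `hr_bpm`, `qt_ms`,
#'   `conc_m2` (`qt_ms` may be `NA` before QT simulation/measurement).
#' @return The validated data frame (invisibly modified: `conc_m2` filled).
#' @export
validate_ecg_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"conc_m2" %in% names(records)) {
    tbt_msg("conc_m2 column missing; treating all records as unexposed (conc_m2 = 0)")
    records$conc_m2 <- 0
  }
  missing_cols <- setdiff(.ecg_record_cols, names(records))
  if (length(missing_cols) > 0L)
    stop("ECG table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L)
      stop("invalid ECG records (", what, ") in row(s): ",
           paste(head(idx, 10L), collapse = ", "),
           if (length(idx) > 10L) sprintf(" ... (%d total)", length(idx)) else "")
  }
  bad(!is.finite(records$hr_bpm) | records$hr_bpm <= 0, "hr_bpm must be > 0")
  bad(!is.na(records$qt_ms) & records$qt_ms <= 0, "qt_ms must be > 0")
  bad(!is.finite(records$conc_m2) | records$conc_m2 < 0, "conc_m2 must be >= 0")
  bad(records$ctime_h < 0 | records$ctime_h >= 24, "ctime_h must be in [0, 24)")
  bad(!records$replicate %in% 1:3, "replicate must be 1, 2 or 3")
  bad(!records$arm %in% c("active", "placebo"), "arm must be active/placebo")
  # occasion consistency: replicates of one occasion share subject and times
  for (col in c("t_weeks", "ctime_h")) {
    rng <- tapply(records[[col]], records$occasion_id, function(v) diff(range(v)))
    if (any(rng > 1e-9))
      stop("occasion(s) with inconsistent ", col, ": ",
           paste(head(names(rng)[rng > 1e-9], 5L), collapse = ", "))
  }
  subj_per_occ <- tapply(records$subject_id, records$occasion_id,
                         function(v) length(unique(v)))
  if (any(subj_per_occ > 1L))
    stop("occasion id(s) shared across subjects: ",
         paste(head(names(subj_per_occ)[subj_per_occ > 1L], 5L), collapse = ", "))
  records
}

#' @rdname validate_ecg_records
#' @param subjects Data frame of subject profiles.
#' @export
validate_subjects <- function(subjects) {
  stopifnot(is.data.frame(subjects))
  missing_cols <- setdiff(.subject_cols, names(subjects))
  if (length(missing_cols) > 0L)
    stop("subject table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicated subject_id in subject table")
  ok_num <- function(v) is.na(v) | (is.finite(v) & v > 0)
  if (!all(ok_num(subjects$weight_kg))) stop("weight_kg must be > 0")
  if (!all(ok_num(subjects$ttp_mgit_h))) stop("ttp_mgit_h must be > 0")
  if (any(!is.na(subjects$age_y) & subjects$age_y < 18))
    stop("age_y must be >= 18 (adult trial population)")
  subjects
}

#' Read a long-format ECG table
#'
#' Reads a delimiter-separated ECG table into the canonical record/subject
#' representation. Alternative column headings are absorbed by a `dialect`
#' mapping; subject-level covariate columns (age, weight, albumin, TTP MGIT),
#' if present, are extracted into the subject table.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the file's headings, e.g. `c(hr_bpm = "HR", qt_ms = "QT")`.
#' @param sep Field separator (default `","`).
#' @return An [ecg_data] object.
#' @export
read_ecg_table <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(raw))
        stop("dialect maps '", canon, "' to absent column '", dialect[[canon]], "'")
      names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  if (!"occasion_id" %in% names(raw))
    raw$occasion_id <- paste(raw$subject_id, signif(raw$t_weeks, 10),
                             signif(raw$ctime_h, 10), sep = ":")
  if (!"replicate" %in% names(raw))
    raw$replicate <- stats::ave(seq_len(nrow(raw)), raw$occasion_id,
                                FUN = seq_along)
  if (!"study" %in% names(raw)) raw$study <- "other"
  if (!"arm" %in% names(raw)) raw$arm <- "active"
  cov_cols <- intersect(c("age_y", "weight_kg", "albumin_gL", "ttp_mgit_h",
                          "sex", "hiv"), names(raw))
  subj <- raw[!duplicated(raw$subject_id),
              c("subject_id", "study", "arm", cov_cols), drop = FALSE]
  for (col in setdiff(.subject_cols, names(subj))) subj[[col]] <- NA_real_
  rownames(subj) <- NULL
  keep <- intersect(c(.ecg_record_cols, "assessment"), names(raw))
  ecg_data(raw[, keep, drop = FALSE], subj)
}

#' Write a long-format ECG table
#'
#' Writes the canonical delimiter-separated representation (one row per ECG
#' replicate, subject covariates repeated on each row) such that
#' [read_ecg_table()] recovers the records and subjects field-by-field.
#'
#' @param x An [ecg_data] object, or a bare record data frame.
#' @param path Output path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_ecg_table <- function(x, path, sep = ",") {
  if (inherits(x, "ecg_data")) {
    recs <- x$records
    cov_cols <- setdiff(names(x$subjects), c("study", "arm"))
    recs <- merge(recs, x$subjects[, cov_cols, drop = FALSE],
                  by = "subject_id", sort = FALSE)
  } else {
    recs <- validate_ecg_records(x)
  }
  ok <- tryCatch({
    write.csv(recs, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write ECG table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Analysis configuration
#'
#' Plumbing for reproducible runs: a seed plus the cohort design, estimation
#' and evaluation settings, serialisable to/from YAML.
#'
#' @param seed Integer seed governing every stochastic stage.
#' @param design A [cohort_design()] (stored as a plain list in YAML).
#' @param estimation List of estimation settings (`inner_tol`, `outer_tol`,
#'   `max_iter`).
#' @param correction Correction method name (see [correction_spec()]).
#' @param bins Bin scheme name, currently `"default"` (the eight
#'   prespecified bins of [time_bin_scheme()]).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L, design = cohort_design(),
                            estimation = list(inner_tol = 1e-6,
                                              outer_tol = 1e-4,
                                              max_iter = 500L),
                            correction = "tbt", bins = "default") {
  structure(list(seed = as.integer(seed), design = design,
                 estimation = estimation, correction = correction,
                 bins = bins),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path Path of the YAML file.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  d <- cfg$design
  if (!is.null(d$visits)) d$visits <- as.data.frame(d$visits)
  if (!is.null(d$qt_truth$cf)) {
    cf <- d$qt_truth$cf
    d$qt_truth$cf <- if (identical(cf$method, "time_varying"))
      correction_spec("time_varying", cf_pre = cf$cf_pre,
                      cf_post = cf$cf_post, t_half = cf$t_half)
    else correction_spec("power", exponent = cf$exponent)
  }
  design <- do.call(cohort_design, d)
  analysis_config(seed = cfg$seed, design = design,
                  estimation = cfg$estimation,
                  correction = cfg$correction, bins = cfg$bins)
}

#' @rdname analysis_config
#' @param config An `analysis_config` object.
#' @export
write_analysis_config <- function(config, path) {
  out <- unclass(config)
  out$design <- unclass(out$design)
  yaml::write_yaml(out, path)
  invisible(path)
}
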