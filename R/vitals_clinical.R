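# Vital-sign imputation and summary features; clinical record validation.

#' k-nearest-neighbour imputation of a vital-sign channel
#'
#' Each missing value is replaced by the mean of the `k` observed values
#' nearest in time (distance on the time axis within the channel; ties
#' broken toward the earlier sample). Observed values are never modified,
#' so the operation is idempotent.
#'
#' @param times Sample times (minutes), strictly increasing.
#' @param values Channel values with `NA` for missing samples.
#' @param k Number of neighbours (default 5).
#' @return Numeric vector with no missing values.
#' @export
knn_impute <- function(times, values, k = 5L) {
  if (length(times) != length(values)) stop_invalid("times and values must have equal length")
  obs <- which(!is.na(values))
  if (length(obs) == 0L) stop_insufficient("channel is fully missing")
  if (length(obs) < k) {
    stop_insufficient(sprintf("only %d observed values but k = %d", length(obs), k))
  }
  mis <- which(is.na(values))
  if (length(mis) == 0L) return(values)
  t_obs <- times[obs]
  v_obs <- values[obs]
  # order candidates by (distance, earlier time first) -- deterministic ties
  for (i in mis) {
    d <- abs(t_obs - times[i])
    ord <- order(d, t_obs)
    values[i] <- mean(v_obs[ord[seq_len(k)]])
  }
  values
}

#' Mean and standard deviation of a channel over a window
#'
#' Computed over all minute samples with time in `[h_start, h_end)` hours;
#' SD is the sample SD (denominator N-1).
#'
#' @param times Minutes from admission.
#' @param values Imputed channel values (no `NA`).
#' @param h_start,h_end Window bounds, hours.
#' @return Named list `mean, std`.
#' @export
vital_summary <- function(times, values, h_start, h_end) {
  sel <- times >= h_start * 60 & times < h_end * 60
  if (!any(sel)) stop_insufficient("no samples in the requested window")
  x <- values[sel]
  list(mean = mean(x), std = if (length(x) > 1L) stats::sd(x) else 0)
}

#' Linear trend of a channel over a window
#'
#' Ordinary least squares slope of value against time in hours over
#' `[h_start, h_end)`.
#'
#' @inheritParams vital_summary
#' @return Slope in channel units per hour.
#' @export
vital_slope <- function(times, values, h_start, h_end) {
  sel <- times >= h_start * 60 & times < h_end * 60
  if (sum(sel) < 2L) stop_insufficient("need at least 2 samples for a slope")
  ols_slope(times[sel] / 60, values[sel])
}

#' Vital-sign feature block for one patient
#'
#' Imputes each of the five channels with [knn_impute()], then derives
#' mean, SD and slope per channel over the analysis window, plus the
#' pass-through temperature: the 16 vital-sign features of the feature
#' schema.
#'
#' @param vitals Data frame `time_min, hr, dbp, sbp, abpm, spo2` (missing
#'   as `NA`).
#' @param temperature Single recorded temperature, deg C.
#' @param h_start,h_end Analysis window, hours from admission.
#' @param k Imputation neighbours.
#' @return Named numeric vector of the 16 features.
#' @export
vital_features <- function(vitals, temperature, h_start = 2, h_end = 14, k = 5L) {
  chans <- c(hr = "HR", dbp = "DBP", sbp = "SBP", abpm = "ABPM", spo2 = "SpO2")
  out <- numeric(0)
  for (ch in names(chans)) {
    v <- knn_impute(vitals$time_min, vitals[[ch]], k = k)
    s <- vital_summary(vitals$time_min, v, h_start, h_end)
    sl <- vital_slope(vitals$time_min, v, h_start, h_end)
    vals <- c(s$mean, s$std, sl)
    names(vals) <- paste0(chans[[ch]], c("_mean", "_std", "_slope"))
    out <- c(out, vals)
  }
  c(out, Temperature = as.numeric(temperature))
}

#' Validate a clinical record
#'
#' Enforces ordinal GCS component ranges (eyes 1-4, motor 1-6, verbal 1-5,
#' final total 3-15), positive age and 0/1 gender coding (female = 0,
#' male = 1, so Pearson correlation against the column equals the
#' point-biserial correlation). Missing pathology analytes are flagged in
#' attribute `missing_analytes` but the record is retained.
#'
#' @param record Named list or one-row data frame with the 13 analytes,
#'   `gcs_eyes_12h`, `gcs_motor_12h`, `gcs_verbal_12h`, `gcs_final`,
#'   `age`, `gender` and `temperature`.
#' @return The validated record (as a named list), invisibly unchanged
#'   apart from the `missing_analytes` attribute.
#' @export
validate_clinical <- function(record) {
  record <- as.list(record)
  rng <- list(gcs_eyes_12h = c(1, 4), gcs_motor_12h = c(1, 6),
              gcs_verbal_12h = c(1, 5), gcs_final = c(3, 15))
  for (f in names(rng)) {
    v <- record[[f]]
    if (is.null(v) || is.na(v) || v < rng[[f]][1] || v > rng[[f]][2] || v != round(v)) {
      hrvnet_error("hrvnet_validation_error",
                   sprintf("field %s out of range [%d, %d]: %s",
                           f, rng[[f]][1], rng[[f]][2], format(v)))
    }
  }
  if (is.null(record$age) || is.na(record$age) || record$age <= 0) {
    hrvnet_error("hrvnet_validation_error", "field age must be positive")
  }
  if (!record$gender %in% c(0, 1)) {
    hrvnet_error("hrvnet_validation_error", "field gender must be coded 0 (female) / 1 (male)")
  }
  analytes <- names(analyte_params())
  miss <- analytes[vapply(analytes, function(a) is.null(record[[a]]) || is.na(record[[a]]),
                          logical(1))]
  attr(record, "missing_analytes") <- miss
  record
}

#' Clinical feature block for one patient
#'
#' Orders a validated record into the 19 clinical feature columns of the
#' schema (13 analytes, 4 injury scores, age, gender). Missing analytes
#' propagate as `NA`.
#'
#' @param record Output of [validate_clinical()].
#' @return Named numeric vector of 19 features.
#' @export
clinical_features <- function(record) {
  cols <- c(names(analyte_params()),
            "gcs_eyes_12h", "gcs_motor_12h", "gcs_verbal_12h", "gcs_final",
            "age", "gender")
  out <- vapply(cols, function(f) {
    v <- record[[f]]
    if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  names(out) <- c(names(analyte_params()),
                  "GCS_eyes_12h", "GCS_motor_12h", "GCS_verbal_12h", "GCS_final",
                  "Age", "Gender")
  out
}
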