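# Cohort exclusion, assembly of the patients x 51 feature matrix, and
# standardization. The schema is the single source of truth for feature
# names, order and group membership.

#' The 51-feature schema
#'
#' Ordered feature names with their five-group partition: 16 HRV,
#' 16 vital-sign, 13 pathology, 4 injury-score and 2 demographic features.
#'
#' @return Data frame with columns `feature`, `group`.
#' @export
feature_schema <- function() {
  hrv <- hrv_feature_names()
  vitals <- c(t(outer(c("HR", "DBP", "SBP", "ABPM", "SpO2"),
                      c("_mean", "_std", "_slope"), paste0)))
  vitals <- c(vitals, "Temperature")
  path <- names(analyte_params())
  injury <- c("GCS_eyes_12h", "GCS_motor_12h", "GCS_verbal_12h", "GCS_final")
  demo <- c("Age", "Gender")
  data.frame(
    feature = c(hrv, vitals, path, injury, demo),
    group = rep(c("HRV", "VitalSigns", "Pathology", "InjuryScores", "Demographics"),
                times = c(length(hrv), length(vitals), length(path),
                          length(injury), length(demo))),
    stringsAsFactors = FALSE
  )
}

#' Apply the recording-length exclusion rule
#'
#' Patients whose recording is shorter than `min_hours` (default 12 h) are
#' removed before feature assembly. A CONSORT-style count of screened /
#' excluded / retained patients is attached as attribute `exclusion_log`.
#'
#' @param durations Named numeric vector (or data frame with columns
#'   `patient`, `duration_h`) of recording lengths in hours.
#' @param min_hours Minimum recording length, hours.
#' @return Character vector of retained patient ids.
#' @export
apply_exclusions <- function(durations, min_hours = 12) {
  if (is.data.frame(durations)) {
    durations <- stats::setNames(durations$duration_h, durations$patient)
  }
  if (is.null(names(durations))) stop_invalid("durations must be named by patient id")
  keep <- names(durations)[durations >= min_hours]
  if (length(keep) == 0L) stop_insufficient("exclusion rule removed every patient")
  structure(keep,
            exclusion_log = c(screened = length(durations),
                              excluded = length(durations) - length(keep),
                              retained = length(keep)))
}

#' Assemble the patients x 51 feature matrix
#'
#' Joins the HRV, vital-sign and clinical feature tables by patient id and
#' orders columns by the schema. Every patient must appear in all three
#' sources; missing feature cells propagate as `NA`.
#'
#' @param hrv,vitals,clinical Data frames with a `patient` column and the
#'   group's feature columns.
#' @param patients Optional patient ids to retain (e.g. from
#'   [apply_exclusions()]); defaults to all common ids, sorted.
#' @param schema Feature schema (defaults to [feature_schema()]).
#' @return Object of class `feature_matrix`: list with `values`
#'   (patients x 51 numeric matrix, rownames = ids), `schema`, `patients`.
#' @export
assemble_features <- function(hrv, vitals, clinical, patients = NULL,
                              schema = feature_schema()) {
  srcs <- list(hrv = hrv, vitals = vitals, clinical = clinical)
  for (nm in names(srcs)) {
    if (!"patient" %in% names(srcs[[nm]])) {
      stop_invalid(sprintf("%s table lacks a 'patient' column", nm))
    }
  }
  common <- Reduce(intersect, lapply(srcs, function(d) d$patient))
  if (is.null(patients)) {
    patients <- sort(common)
  } else {
    missing_pt <- setdiff(patients, common)
    if (length(missing_pt) > 0) {
      hrvnet_error("hrvnet_consistency_error",
                   paste("patients absent from some source table:",
                         paste(missing_pt, collapse = ", ")))
    }
  }
  merged <- Reduce(function(a, b) merge(a, b, by = "patient"), srcs)
  missing_cols <- setdiff(schema$feature, names(merged))
  if (length(missing_cols) > 0) {
    stop_invalid(paste("feature columns missing from sources:",
                       paste(missing_cols, collapse = ", ")))
  }
  rownames(merged) <- merged$patient
  values <- as.matrix(merged[patients, schema$feature, drop = FALSE])
  storage.mode(values) <- "double"
  structure(list(values = values, schema = schema, patients = patients),
            class = "feature_matrix")
}

#' Standardize a feature matrix (z-scores)
#'
#' Centers and scales each column to mean 0, sample SD 1 (`NA` cells are
#' ignored in the column statistics and preserved). Pearson correlations
#' are invariant under this transform; the z-scored matrix is the node
#' feature input of the embedding stage.
#'
#' @param fm A `feature_matrix`.
#' @return A `feature_matrix` with standardized values.
#' @export
standardize_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  sds <- apply(fm$values, 2, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    hrvnet_error("hrvnet_zero_variance",
                 paste("zero-variance feature column(s):",
                       paste(colnames(fm$values)[bad], collapse = ", ")))
  }
  mus <- colMeans(fm$values, na.rm = TRUE)
  fm$values <- sweep(sweep(fm$values, 2, mus), 2, sds, `/`)
  fm
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "patients x", ncol(x$values), "features\n")
  print(table(x$schema$group)[unique(x$schema$group)])
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' `feature_matrix.csv` has one row per patient and the 51 named feature
#' columns; `schema.csv` records the feature-to-group map.
#'
#' @param fm A `feature_matrix`.
#' @param dir Directory for the two files.
#' @export
write_feature_matrix <- function(fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(patient = rownames(fm$values), fm$values, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "feature_matrix.csv"), row.names = FALSE, na = "")
  utils::write.csv(fm$schema, file.path(dir, "schema.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(dir) {
  df <- utils::read.csv(file.path(dir, "feature_matrix.csv"), check.names = FALSE)
  schema <- utils::read.csv(file.path(dir, "schema.csv"), stringsAsFactors = FALSE)
  values <- as.matrix(df[, schema$feature, drop = FALSE])
  rownames(values) <- df$patient
  storage.mode(values) <- "double"
  structure(list(values = values, schema = schema, patients = df$patient),
            class = "feature_matrix")
}
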