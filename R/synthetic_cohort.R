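# Synthetic cohort generation: seeded ECG / RR / vitals / clinical records
# with planted latent-factor correlation structure, so the downstream
# feature-network and embedding stages can be exercised and validated
# without any patient data.

#' Generate a synthetic R-R interval series
#'
#' Beat-to-beat intervals follow a sinusoidal two-band model plus white
#' noise: the k-th interval is
#' `mean_rr + sd_lf*sqrt(2)*sin(2*pi*f_lf*t_k) + sd_hf*sqrt(2)*sin(2*pi*f_hf*t_k) + e_k`,
#' where `t_k` is the cumulative beat time and `e_k ~ N(0, sd_noise^2)`.
#' The `sqrt(2)` factor makes each sinusoid contribute variance `sd^2`, so
#' spectral band powers are controllable in closed form. Noise draws that
#' would push an interval below 300 ms are rejection-resampled (up to 100
#' times, then clipped) to keep intervals physiological.
#'
#' @param mean_rr Mean interval, ms. Must be positive.
#' @param sd_lf,sd_hf Standard deviation (ms) of the low- and high-frequency
#'   sinusoidal modulation.
#' @param f_lf,f_hf Modulation frequencies, Hz; `0 < f_lf < f_hf`.
#' @param sd_noise SD of white beat-to-beat noise, ms.
#' @param duration Total duration to cover, seconds.
#' @param seed Integer seed.
#' @return An [rr_series] object.
#' @export
generate_rr_series <- function(mean_rr, sd_lf = 0, sd_hf = 0,
                               f_lf = 0.1, f_hf = 0.25,
                               sd_noise = 0, duration = 3600, seed = 1L) {
  if (!is.finite(mean_rr) || mean_rr <= 0) stop_invalid("mean_rr must be positive")
  if (sd_lf < 0 || sd_hf < 0 || sd_noise < 0) stop_invalid("sd parameters must be non-negative")
  if (!(f_lf > 0 && f_hf > f_lf)) stop_invalid("need 0 < f_lf < f_hf")
  if (duration <= 0) stop_invalid("duration must be positive")
  set.seed(seed)
  n_est <- ceiling(duration / (mean_rr / 1000) * 1.5) + 16L
  rr <- numeric(n_est)
  t <- 0
  k <- 0L
  while (t < duration) {
    k <- k + 1L
    if (k > length(rr)) rr <- c(rr, numeric(length(rr)))
    det_part <- mean_rr +
      sd_lf * sqrt(2) * sin(2 * pi * f_lf * t) +
      sd_hf * sqrt(2) * sin(2 * pi * f_hf * t)
    val <- det_part + if (sd_noise > 0) stats::rnorm(1, 0, sd_noise) else 0
    tries <- 0L
    while (val < 300 && sd_noise > 0 && tries < 100L) {
      val <- det_part + stats::rnorm(1, 0, sd_noise)
      tries <- tries + 1L
    }
    if (val < 300) val <- max(val, 300)
    rr[k] <- val
    t <- t + val / 1000
  }
  # drop the interval that overshot the duration, if we have spares
  if (k > 2L && t > duration) k <- k - 1L
  rr_series(rr[seq_len(k)])
}

#' Synthesize an ECG trace from planted beat times
#'
#' Places a Ricker (negative second-derivative-of-Gaussian) pulse at each
#' beat of `rr`, on a uniform grid at `fs` Hz, plus optional white baseline
#' noise. The pulse has a single sharp central maximum, so a peak detector
#' can recover the planted beat times exactly on noise-free input. Pulse
#' centers are snapped to the sample grid.
#'
#' @param rr An [rr_series] with the planted beats.
#' @param fs Sampling rate, Hz (>= 100).
#' @param template_width Approximate total pulse width, ms; must be smaller
#'   than the smallest interval in `rr`.
#' @param amplitude Peak amplitude, mV.
#' @param baseline_noise_sd SD of additive white noise, mV.
#' @param seed Integer seed (used only when `baseline_noise_sd > 0`).
#' @return An `ecg_trace` object: list with `samples` (mV), `fs`, `t0`
#'   (hours from admission).
#' @export
synthesize_ecg <- function(rr, fs = 240, template_width = 80, amplitude = 1,
                           baseline_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 100) stop_invalid("fs must be >= 100 Hz")
  if (template_width <= 0) stop_invalid("template_width must be positive")
  if (template_width >= min(rr$rr)) {
    stop_invalid("template_width must be below the smallest RR interval (pulses would overlap)")
  }
  peak_t <- rr$peak_times
  n <- ceiling((max(peak_t) + 0.5) * fs) + 1L
  set.seed(seed)
  samples <- if (baseline_noise_sd > 0) stats::rnorm(n, 0, baseline_noise_sd) else numeric(n)
  sigma <- (template_width / 1000) / 6
  half <- ceiling(3 * sigma * fs)
  tt <- (-half:half) / fs
  pulse <- amplitude * (1 - (tt / sigma)^2) * exp(-tt^2 / (2 * sigma^2))
  centers <- round(peak_t * fs) + 1L
  for (c0 in centers) {
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1L & idx <= n
    samples[idx[ok]] <- samples[idx[ok]] + pulse[ok]
  }
  ecg_trace(samples, fs = fs, t0 = 0)
}

#' Construct an ECG trace object
#'
#' @param samples Numeric vector, mV.
#' @param fs Sampling rate, Hz.
#' @param t0 Start offset from ICU admission, hours.
#' @export
ecg_trace <- function(samples, fs, t0 = 0) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    stop_invalid("ECG samples must be finite numeric values")
  }
  if (fs <= 0) stop_invalid("fs must be positive")
  if (length(samples) < 2 * fs) stop_insufficient("ECG trace shorter than 2 seconds")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "ecg_trace")
}

#' Generate minute-by-minute vital-sign channels
#'
#' Five channels (HR, DBP, SBP, ABPM, SpO2) at 1-minute resolution.
#' Cross-channel correlation is planted through shared minute-level latent
#' factors: `value[c, t] = baseline[c] + level_shift[c] + loadings[c, ] %*% f_t
#' + trend_per_h[c] * t_h + noise`, with `f_t ~ N(0, I)` i.i.d. per minute,
#' so the population cross-channel covariance is `loadings %*% t(loadings)`
#' plus diagonal noise. Gaps are planted per channel as a Poisson number of
#' runs with geometric lengths and recorded as `NA`.
#'
#' @param duration_h Recording length, hours.
#' @param loadings 5 x k matrix (rows HR, DBP, SBP, ABPM, SpO2) of factor
#'   loadings in channel units; `NULL` for independent channels.
#' @param baselines,trend_per_h,noise_sd Named numeric vectors (names
#'   `hr, dbp, sbp, abpm, spo2`), channel units (trend per hour).
#' @param level_shift Per-channel additive offset (patient-level planted
#'   effects), channel units.
#' @param gap_spec List per channel: `list(gaps_per_hour =, mean_gap_min =)`,
#'   or `NULL` for complete data.
#' @param seed Integer seed.
#' @return Data frame `time_min, hr, dbp, sbp, abpm, spo2`; missing = `NA`.
#' @export
generate_vitals <- function(duration_h, loadings = NULL,
                            baselines = c(hr = 75, dbp = 70, sbp = 120, abpm = 87, spo2 = 97.5),
                            trend_per_h = c(hr = 0, dbp = 0, sbp = 0, abpm = 0, spo2 = 0),
                            noise_sd = c(hr = 2, dbp = 3, sbp = 4, abpm = 3, spo2 = 0.8),
                            level_shift = c(hr = 0, dbp = 0, sbp = 0, abpm = 0, spo2 = 0),
                            gap_spec = NULL, seed = 1L) {
  if (duration_h <= 0) stop_invalid("duration_h must be positive")
  chans <- c("hr", "dbp", "sbp", "abpm", "spo2")
  n <- as.integer(floor(duration_h * 60))
  t_min <- seq_len(n) - 1L
  t_h <- t_min / 60
  set.seed(seed)
  vals <- matrix(0, n, 5L, dimnames = list(NULL, chans))
  f <- NULL
  if (!is.null(loadings)) {
    if (nrow(loadings) != 5L) stop_invalid("loadings must have 5 rows (hr, dbp, sbp, abpm, spo2)")
    f <- matrix(stats::rnorm(n * ncol(loadings)), n, ncol(loadings))
  }
  for (j in seq_along(chans)) {
    ch <- chans[j]
    v <- baselines[[ch]] + level_shift[[ch]] + trend_per_h[[ch]] * t_h
    if (!is.null(f)) v <- v + as.numeric(f %*% loadings[j, ])
    if (noise_sd[[ch]] > 0) v <- v + stats::rnorm(n, 0, noise_sd[[ch]])
    if (ch == "spo2") v <- pmin(pmax(v, 0), 100)
    vals[, j] <- v
  }
  if (!is.null(gap_spec)) {
    for (ch in intersect(names(gap_spec), chans)) {
      gs <- gap_spec[[ch]]
      n_gaps <- stats::rpois(1, gs$gaps_per_hour * duration_h)
      if (n_gaps > 0) {
        starts <- sample.int(n, n_gaps, replace = TRUE)
        lens <- 1L + stats::rgeom(n_gaps, prob = 1 / gs$mean_gap_min)
        for (g in seq_len(n_gaps)) {
          idx <- starts[g]:min(n, starts[g] + lens[g] - 1L)
          vals[idx, ch] <- NA_real_
        }
        # never blank an entire channel
        if (all(is.na(vals[, ch]))) vals[1L, ch] <- baselines[[ch]]
      }
    }
  }
  data.frame(time_min = t_min, vals)
}

# Truncated-normal draw by resampling (plausible-range clinical values).
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

# Pathology analyte reference points: mean, sd, lower, upper (plausibility
# only; values carry no clinical claim).
analyte_params <- function() {
  list(
    SO2 = c(96, 2.5, 75, 100), PO2 = c(95, 20, 40, 300), PCO2 = c(40, 5, 20, 80),
    Haemoglobin = c(135, 18, 60, 190), Carboxyhemoglobin = c(1.5, 0.6, 0, 8),
    Methemoglobin = c(0.9, 0.3, 0, 4), Chloride = c(103, 3.5, 85, 125),
    Calcium = c(2.25, 0.12, 1.5, 3), Anion_gap = c(11, 2.5, 3, 25),
    Potassium = c(4.0, 0.4, 2.5, 6.5), Sodium = c(139, 3.5, 120, 160),
    Lactate = c(1.6, 0.7, 0.3, 8), Glucose = c(7.5, 1.8, 3, 20)
  )
}

#' Cohort generation configuration
#'
#' Collects the knobs of [generate_cohort()] with defaults matching the
#' study design the pipeline targets: 34 patients of whom 5 have
#' recordings shorter than 12 h (and are excluded downstream), 14 h of
#' monitoring for the rest so the default \[2 h, 14 h) analysis window is
#' covered, ECG at 240 Hz.
#'
#' @param n_patients Number of patients.
#' @param n_short_patients Patients with recordings shorter than 12 h.
#' @param duration_h Recording length of full patients, hours.
#' @param short_duration_h Recording length of short patients, hours.
#' @param ecg_fs ECG sampling rate, Hz.
#' @param ecg_mode `"rr"` stores R-R series only (fast); `"ecg"`
#'   synthesizes the full waveform.
#' @param mean_rr_pop,mean_rr_sd Population mean / between-patient SD of the
#'   mean R-R interval, ms.
#' @param sd_lf,sd_hf,sd_noise R-R modulation SDs, ms (see
#'   [generate_rr_series()]).
#' @param gap_spec Per-channel missingness spec (see [generate_vitals()]).
#' @param seed Integer master seed.
#' @export
cohort_config <- function(n_patients = 34L, n_short_patients = 5L,
                          duration_h = 14, short_duration_h = 8,
                          ecg_fs = 240, ecg_mode = c("rr", "ecg"),
                          mean_rr_pop = 850, mean_rr_sd = 70,
                          sd_lf = 25, sd_hf = 15, sd_noise = 18,
                          gap_spec = default_gap_spec(), seed = 1L) {
  ecg_mode <- match.arg(ecg_mode)
  if (n_short_patients > n_patients) stop_invalid("n_short_patients must be <= n_patients")
  if (ecg_fs <= 0 || duration_h <= 0 || short_duration_h <= 0) {
    stop_invalid("ecg_fs and durations must be positive")
  }
  structure(list(
    n_patients = as.integer(n_patients), n_short_patients = as.integer(n_short_patients),
    duration_h = duration_h, short_duration_h = short_duration_h,
    ecg_fs = ecg_fs, ecg_mode = ecg_mode,
    mean_rr_pop = mean_rr_pop, mean_rr_sd = mean_rr_sd,
    sd_lf = sd_lf, sd_hf = sd_hf, sd_noise = sd_noise,
    gap_spec = gap_spec, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default per-channel gap specification
#'
#' Around one gap every two hours per channel with mean length 6 min,
#' emulating intermittent monitor dropouts of varying length.
#' @export
default_gap_spec <- function() {
  g <- list(gaps_per_hour = 0.5, mean_gap_min = 6)
  list(hr = g, dbp = g, sbp = g, abpm = g, spo2 = g)
}

#' Generate a full synthetic cohort
#'
#' Per patient: an R-R series (optionally rendered to a 240 Hz ECG
#' waveform), five minute-level vital channels with gaps, one temperature,
#' 13 pathology analytes, GCS components at 12 h plus a final total, age
#' and gender. Two patient-level latent factors plant cross-feature
#' correlation: an *autonomic* factor shared by the mean R-R interval and
#' heart-rate level (HR is derived from the same R-R process), and a
#' *severity* factor loading on GCS components (negative), diastolic /
#' mean arterial pressure variability-free levels, SpO2 level (negative)
#' and age. The implied population correlation matrix over the generator
#' variables is returned as ground truth. The last `n_short_patients`
#' patients receive recordings of `short_duration_h` hours, exercising the
#' downstream exclusion rule.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with `patients` (each: `id`,
#'   `duration_h`, `rr`, optional `ecg`, `vitals`, `clinical`),
#'   `ground_truth` (correlation matrix), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  short <- ids[seq.int(n - config$n_short_patients + 1L, length.out = config$n_short_patients)]

  # patient-level latent factors and linear effect sizes (generator units)
  set.seed(derive_seed(config$seed, 0L))
  autonomic <- stats::rnorm(n)
  severity <- stats::rnorm(n)

  eff <- list(
    mean_rr = c(a = config$mean_rr_sd * 0.9, s = 0, noise = config$mean_rr_sd * sqrt(1 - 0.81)),
    dbp_level = c(a = 0, s = -5, noise = 3.5),
    abpm_level = c(a = 0, s = -4.5, noise = 3.5),
    spo2_level = c(a = 0, s = -0.9, noise = 0.7),
    gcs_sev = c(a = 0, s = -2.2, noise = 1.1),
    age = c(a = 0, s = 9, noise = 9)
  )
  gt <- ground_truth_correlation(eff)

  patients <- vector("list", n)
  for (p in seq_len(n)) {
    sp <- derive_seed(config$seed, p)
    id <- ids[p]
    dur <- if (id %in% short) config$short_duration_h else config$duration_h
    set.seed(sp)
    e <- function(nm) eff[[nm]][["a"]] * autonomic[p] + eff[[nm]][["s"]] * severity[p] +
      stats::rnorm(1, 0, eff[[nm]][["noise"]])
    mean_rr_p <- max(500, config$mean_rr_pop + e("mean_rr"))
    dbp_shift <- e("dbp_level"); abpm_shift <- e("abpm_level"); spo2_shift <- e("spo2_level")
    gcs_lat <- e("gcs_sev"); age_p <- min(90, max(18, round(45 + e("age"))))

    rr <- generate_rr_series(mean_rr_p, sd_lf = config$sd_lf, sd_hf = config$sd_hf,
                             sd_noise = config$sd_noise, duration = dur * 3600,
                             seed = derive_seed(sp, 1L))
    ecg <- NULL
    if (config$ecg_mode == "ecg") {
      ecg <- synthesize_ecg(rr, fs = config$ecg_fs, baseline_noise_sd = 0.02,
                            seed = derive_seed(sp, 2L))
    }
    # HR channel level tied to the same cardiac process; shared minute factor
    # couples the pressure channels within a patient
    hr_base <- 60000 / mean_rr_p
    loadings <- matrix(c(0.6, 2.2, 2.8, 2.4, 0), 5, 1,
                       dimnames = list(c("hr", "dbp", "sbp", "abpm", "spo2"), NULL))
    vit <- generate_vitals(
      duration_h = dur, loadings = loadings,
      level_shift = c(hr = hr_base - 75, dbp = dbp_shift, sbp = 0.6 * dbp_shift,
                      abpm = abpm_shift, spo2 = spo2_shift),
      trend_per_h = c(hr = stats::rnorm(1, 0, 0.4), dbp = stats::rnorm(1, 0, 0.3),
                      sbp = stats::rnorm(1, 0, 0.4), abpm = stats::rnorm(1, 0, 0.3),
                      spo2 = stats::rnorm(1, 0, 0.05)),
      gap_spec = config$gap_spec, seed = derive_seed(sp, 3L)
    )
    clin <- generate_clinical(gcs_lat, age_p, seed = derive_seed(sp, 4L))
    patients[[p]] <- list(id = id, duration_h = dur, rr = rr, ecg = ecg,
                          vitals = vit, clinical = clin)
  }
  structure(list(patients = patients, ground_truth = gt, config = config),
            class = "synthetic_cohort")
}

# One patient's temperature, pathology panel, GCS scores and demographics.
generate_clinical <- function(gcs_latent, age, seed) {
  set.seed(seed)
  ap <- analyte_params()
  panel <- vapply(ap, function(q) rtruncnorm1(1, q[1], q[2], q[3], q[4]), numeric(1))
  # map a latent severity score (higher = worse) onto ordinal GCS components
  g <- function(max_val) as.integer(min(max_val, max(1, round(max_val + gcs_latent / 2 +
                                                                stats::rnorm(1, 0, 0.6)))))
  eyes <- g(4L); motor <- g(6L); verbal <- g(5L)
  final <- as.integer(min(15L, max(3L, eyes + motor + verbal + round(stats::rnorm(1, 0, 1)))))
  c(list(temperature = rtruncnorm1(1, 37.0, 0.6, 34.5, 40.0)),
    as.list(panel),
    list(gcs_eyes_12h = eyes, gcs_motor_12h = motor, gcs_verbal_12h = verbal,
         gcs_final = final, age = age,
         gender = stats::rbinom(1, 1, 0.7)))
}

# Population correlation matrix implied by the patient-level linear effects.
ground_truth_correlation <- function(eff) {
  L <- t(vapply(eff, function(v) v[c("a", "s")], numeric(2)))
  psi <- vapply(eff, function(v) v[["noise"]]^2, numeric(1))
  S <- L %*% t(L) + diag(psi)
  d <- 1 / sqrt(diag(S))
  R <- S * outer(d, d)
  dimnames(R) <- list(names(eff), names(eff))
  R
}

#' Simulate a patient-by-feature table with closed-form correlations
#'
#' Draws `values = F %*% t(loadings) + noise_sd * E` with independent
#' standard-normal factors `F` (patients x k) and noise `E`, so the
#' population correlation of features i, j is
#' `(L L')_ij / sqrt((L L')_ii + sd_i^2) / sqrt((L L')_jj + sd_j^2)`.
#' This is the generator behind the network-recovery and hub-recovery
#' property suites: planted correlations are exact by construction, and
#' the 51 columns are returned pre-split into the three source tables the
#' assembly stage expects.
#'
#' @param n_patients Number of rows.
#' @param loadings 51 x k matrix, rownames = feature names of
#'   [feature_schema()]; `NULL` for all-independent features.
#' @param noise_sd Scalar or length-51 vector of idiosyncratic noise SDs.
#' @param seed Integer seed.
#' @return List: `hrv`, `vitals`, `clinical` data frames (with `patient`
#'   column), `truth` (51 x 51 population correlation matrix), `patients`.
#' @export
simulate_feature_table <- function(n_patients, loadings = NULL, noise_sd = 1,
                                   seed = 1L) {
  schema <- feature_schema()
  p <- nrow(schema)
  if (is.null(loadings)) loadings <- matrix(0, p, 1, dimnames = list(schema$feature, NULL))
  if (nrow(loadings) != p) stop_invalid("loadings must have one row per schema feature")
  if (is.null(rownames(loadings))) rownames(loadings) <- schema$feature
  loadings <- loadings[schema$feature, , drop = FALSE]
  noise_sd <- rep_len(noise_sd, p)
  set.seed(seed)
  F <- matrix(stats::rnorm(n_patients * ncol(loadings)), n_patients)
  E <- matrix(stats::rnorm(n_patients * p), n_patients)
  X <- F %*% t(loadings) + sweep(E, 2, noise_sd, `*`)
  colnames(X) <- schema$feature
  S <- loadings %*% t(loadings) + diag(noise_sd^2, p)
  d <- 1 / sqrt(diag(S))
  truth <- S * outer(d, d)
  dimnames(truth) <- list(schema$feature, schema$feature)
  ids <- sprintf("P%03d", seq_len(n_patients))
  split_df <- function(group) {
    cols <- schema$feature[schema$group == group]
    data.frame(patient = ids, X[, cols, drop = FALSE], check.names = FALSE)
  }
  list(hrv = split_df("HRV"),
       vitals = split_df("VitalSigns"),
       clinical = data.frame(patient = ids,
                             X[, schema$feature[schema$group %in%
                                                  c("Pathology", "InjuryScores", "Demographics")],
                               drop = FALSE], check.names = FALSE),
       truth = truth, patients = ids)
}

#' Loadings for a planted-hub feature table
#'
#' Builds a 51 x (m+1) loadings matrix in which `hub` has population
#' correlation `r` with each of `m` spoke features while the spoke-spoke
#' correlation is held at its minimum feasible value
#' `r^2 - (1 - r^2) / (m - 1)` (the positive-semidefiniteness bound is
#' approached by giving the spokes centered, mutually canceling loadings on
#' their own factors). All other features stay independent. Unit feature
#' variances throughout; use `noise_sd = 0` in [simulate_feature_table()].
#'
#' @param hub Feature name of the hub.
#' @param spokes Character vector of spoke feature names (length >= 2).
#' @param r Planted hub-spoke correlation magnitude.
#' @export
hub_loadings <- function(hub, spokes, r = 0.8) {
  schema <- feature_schema()
  m <- length(spokes)
  if (m < 2) stop_invalid("need at least two spokes")
  if (!all(c(hub, spokes) %in% schema$feature)) stop_invalid("unknown feature names")
  k <- m + 1L
  L <- matrix(0, nrow(schema), k, dimnames = list(schema$feature, NULL))
  L[hub, 1] <- 1
  cc <- sqrt((1 - r^2) / (1 - 1 / m))
  for (i in seq_len(m)) {
    L[spokes[i], 1] <- r
    L[spokes[i], 1 + seq_len(m)] <- -cc / m
    L[spokes[i], 1 + i] <- cc * (1 - 1 / m)
  }
  # all remaining features get unit idiosyncratic variance via noise_sd = 1;
  # hub/spokes already have unit variance from the factors, so their noise
  # must be zero -- return the per-feature noise alongside
  noise <- rep(1, nrow(schema))
  names(noise) <- schema$feature
  noise[c(hub, spokes)] <- 0
  list(loadings = L, noise_sd = noise)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  durs <- vapply(x$patients, `[[`, numeric(1), "duration_h")
  cat("Synthetic ICU cohort:", length(x$patients), "patients\n")
  cat("  recording length:", paste(range(durs), collapse = "-"), "h;",
      sum(durs < 12), "patients below 12 h\n")
  cat("  ECG mode:", x$config$ecg_mode, "at", x$config$ecg_fs, "Hz\n")
  invisible(x)
}

#' Write a cohort to a directory of CSV files
#'
#' Layout: `rr/<id>.csv` (`time_s, rr_ms`) or `ecg/<id>.csv`
#' (`time_s, mv`), `vitals/<id>.csv` (`time_min, hr, dbp, sbp, abpm, spo2`;
#' empty cells = missing), `clinical.csv`, `durations.csv`,
#' `ground_truth.csv` (planted correlation matrix). UTF-8, comma-separated,
#' header row, `.` decimal.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vitals"), showWarnings = FALSE)
  has_ecg <- !is.null(cohort$patients[[1]]$ecg)
  sig_dir <- file.path(dir, if (has_ecg) "ecg" else "rr")
  dir.create(sig_dir, showWarnings = FALSE)
  clin <- NULL
  durs <- data.frame(patient = character(0), duration_h = numeric(0))
  for (pt in cohort$patients) {
    if (has_ecg) {
      tr <- pt$ecg
      df <- data.frame(time_s = (seq_along(tr$samples) - 1) / tr$fs,
                       mv = round(tr$samples, 6))
      utils::write.csv(df, file.path(sig_dir, paste0(pt$id, ".csv")), row.names = FALSE)
    } else {
      df <- data.frame(time_s = pt$rr$times, rr_ms = pt$rr$rr)
      utils::write.csv(df, file.path(sig_dir, paste0(pt$id, ".csv")), row.names = FALSE)
    }
    utils::write.csv(pt$vitals, file.path(dir, "vitals", paste0(pt$id, ".csv")),
                     row.names = FALSE, na = "")
    clin <- rbind(clin, data.frame(patient = pt$id, pt$clinical, check.names = FALSE))
    durs <- rbind(durs, data.frame(patient = pt$id, duration_h = pt$duration_h))
  }
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(durs, file.path(dir, "durations.csv"), row.names = FALSE)
  gt <- data.frame(variable = rownames(cohort$ground_truth), cohort$ground_truth,
                   check.names = FALSE)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
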