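# R-peak detection and heart-rate-variability feature extraction.
# 16 features per patient: 5 time-domain, 4 frequency-domain (Welch),
# 7 nonlinear (Poincare, recurrence analysis, detrended fluctuation
# analysis), computed over consecutive hourly windows and averaged.

#' Construct an R-R interval series
#'
#' @param rr Intervals, ms (all > 0).
#' @param start_time Time of the first beat, seconds from admission.
#' @param peak_times Optional explicit beat times (s, strictly increasing,
#'   length `length(rr) + 1`); overrides `start_time`.
#' @param times Optional interval start times (s); used after cleaning when
#'   intervals are no longer contiguous.
#' @return Object of class `rr_series` with `rr` (ms), `times` (interval
#'   start, s) and, when contiguous, `peak_times` (s).
#' @export
rr_series <- function(rr, start_time = 0, peak_times = NULL, times = NULL) {
  if (length(rr) < 1L) stop_insufficient("empty RR series")
  if (any(!is.finite(rr)) || any(rr <= 0)) stop_invalid("RR intervals must be positive and finite")
  if (!is.null(peak_times)) {
    if (length(peak_times) != length(rr) + 1L || any(diff(peak_times) <= 0)) {
      stop_invalid("peak_times must be strictly increasing with length(rr) + 1")
    }
    times <- peak_times[-length(peak_times)]
  } else if (is.null(times)) {
    peak_times <- start_time + cumsum(c(0, rr)) / 1000
    times <- peak_times[-length(peak_times)]
  } else {
    if (length(times) != length(rr) || any(diff(times) <= 0)) {
      stop_invalid("times must be strictly increasing, one per interval")
    }
  }
  structure(list(rr = as.numeric(rr), times = as.numeric(times),
                 peak_times = peak_times), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat("RR series:", length(x$rr), "intervals, mean",
      sprintf("%.1f ms", mean(x$rr)), "spanning",
      sprintf("%.2f h", diff(range(x$times)) / 3600), "\n")
  invisible(x)
}

#' Detect R peaks in an ECG trace
#'
#' Hilbert-envelope detector: zero-phase band-pass (8-40 Hz Butterworth,
#' order 3, applied forward-backward), envelope = modulus of the analytic
#' signal, adaptive threshold `median + 3 * MAD` of the envelope (with a
#' floor at 20% of the envelope maximum against near-silent baselines),
#' local maxima above threshold, 250 ms refractory period keeping the
#' stronger candidate, and final peak refinement to the raw-signal maximum
#' within +/- 60 ms. On noise-free synthetic input every planted beat is
#' recovered to +/- 1 sample.
#'
#' @param ecg An [ecg_trace].
#' @return An [rr_series] (beat times in seconds from admission).
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_trace"))
  if (ecg$fs < 100) hrvnet_error("hrvnet_unsupported_rate", "ECG sampling rate below 100 Hz")
  x <- ecg$samples
  fs <- ecg$fs
  ny <- fs / 2
  bf <- signal::butter(3, c(8, 40) / ny, type = "pass")
  # odd-reflection padding suppresses filter edge transients that would
  # otherwise masquerade as beats at the trace boundaries
  n0 <- length(x)
  npad <- min(n0 - 1L, as.integer(2 * fs))
  xp <- c(2 * x[1] - rev(x[2:(npad + 1L)]), x,
          2 * x[n0] - rev(x[(n0 - npad):(n0 - 1L)]))
  xf_pad <- signal::filtfilt(bf, xp)
  # zero-pad to a 2-3-5-smooth length: keeps the FFT of the Hilbert
  # transform O(n log n) for arbitrary trace lengths; the zero-pad
  # transient falls inside the reflection padding, which is stripped
  m <- stats::nextn(length(xf_pad), c(2, 3, 5))
  env <- Mod(analytic_signal(c(xf_pad, numeric(m - length(xf_pad)))))
  keep_idx <- (npad + 1L):(npad + n0)
  xf <- xf_pad[keep_idx]
  env <- env[keep_idx]
  thr <- max(stats::median(env) + 3 * stats::mad(env), 0.2 * max(env))
  n <- length(env)
  if (max(env) <= 0 || thr <= 0) hrvnet_error("hrvnet_no_beats", "no R peaks found in trace")
  # one candidate per contiguous above-threshold region: its envelope maximum
  above <- env > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  reg <- which(runs$values)
  if (length(reg) == 0L) hrvnet_error("hrvnet_no_beats", "no R peaks found in trace")
  cand <- vapply(reg, function(k) {
    s <- starts[k]
    s + which.max(env[s:ends[k]]) - 1L
  }, integer(1))
  # refractory: single time-ordered pass, keeping the stronger of any two
  # candidates closer than 250 ms
  refr <- round(0.25 * fs)
  kept <- integer(length(cand))
  nk <- 0L
  for (i in cand) {
    if (nk > 0L && i - kept[nk] < refr) {
      if (env[i] > env[kept[nk]]) kept[nk] <- i
    } else {
      nk <- nk + 1L
      kept[nk] <- i
    }
  }
  peaks <- kept[seq_len(nk)]
  # refine to the raw-signal maximum near each envelope peak
  half <- as.integer(round(0.06 * fs))
  peaks <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) < 2L) hrvnet_error("hrvnet_no_beats", "fewer than two R peaks found")
  pt <- ecg$t0 * 3600 + (peaks - 1) / fs
  rr_series(diff(pt) * 1000, peak_times = pt)
}

#' Remove non-physiological R-R intervals
#'
#' Drops intervals outside `[min_ms, max_ms]` (default 300-2000 ms,
#' i.e. 30-200 bpm) and re-links the series, preserving each retained
#' interval's original start time. The number and fraction removed are
#' attached as attributes `n_removed` / `fraction_removed`.
#'
#' @param rr An [rr_series].
#' @param min_ms,max_ms Acceptance bounds, ms.
#' @export
clean_rr <- function(rr, min_ms = 300, max_ms = 2000) {
  stopifnot(inherits(rr, "rr_series"))
  ok <- rr$rr >= min_ms & rr$rr <= max_ms
  if (!any(ok)) stop_insufficient("all RR intervals removed by cleaning")
  out <- rr_series(rr$rr[ok], times = rr$times[ok])
  attr(out, "n_removed") <- sum(!ok)
  attr(out, "fraction_removed") <- mean(!ok)
  out
}

#' Time-domain HRV features
#'
#' * `MeanRR`: arithmetic mean (ms).
#' * `SDNN`: sample SD (denominator N-1), ms.
#' * `SDANN`: sample SD of 5-minute segment means (needs >= 2 segments,
#'   else `NA`), ms.
#' * `RMSSD`: root of the mean squared successive difference, ms.
#' * `pNN50`: percent of absolute successive differences strictly greater
#'   than 50 ms, with the *total interval count* as denominator.
#'
#' @param rr Intervals, ms (numeric vector or [rr_series]).
#' @param times Optional interval start times (s) for segment assignment;
#'   taken from the `rr_series` or cumulated when absent.
#' @return Named list `SDNN, SDANN, MeanRR, RMSSD, pNN50`.
#' @export
time_domain_features <- function(rr, times = NULL) {
  if (inherits(rr, "rr_series")) {
    times <- rr$times
    rr <- rr$rr
  }
  if (length(rr) < 2L) stop_insufficient("need at least 2 intervals for time-domain features")
  if (is.null(times)) times <- cumsum(c(0, rr[-length(rr)])) / 1000
  d <- diff(rr)
  seg <- floor((times - times[1]) / 300)
  seg_means <- tapply(rr, seg, mean)
  sdann <- if (length(seg_means) >= 2L) stats::sd(seg_means) else NA_real_
  list(
    SDNN = stats::sd(rr),
    SDANN = sdann,
    MeanRR = mean(rr),
    RMSSD = sqrt(mean(d^2)),
    pNN50 = 100 * sum(abs(d) > 50) / length(rr)
  )
}

#' Frequency-domain HRV features
#'
#' The unevenly sampled R-R series is resampled to a uniform 4 Hz grid by
#' cubic spline interpolation, mean-detrended, and its power spectral
#' density estimated by Welch's method (256-sample Hann segments, 50%
#' overlap). Band powers are integrated over VLF `[0.005, 0.04)`,
#' LF `[0.04, 0.15)` and HF `[0.15, 0.4)` Hz; percentages are relative to
#' the VLF+LF+HF total and `HF_LF` is the HF/LF power ratio (`NA` when LF
#' power is zero).
#'
#' @param rr An [rr_series] spanning at least `min_duration` seconds.
#' @param resample_fs Resampling rate, Hz.
#' @param bands List with `vlf`, `lf`, `hf` two-element ranges, Hz.
#' @param min_duration Minimum span of the series, s.
#' @return Named list `p_VLF, p_LF, p_HF, HF_LF` (percent / ratio), plus
#'   `total_power` (ms^2).
#' @export
frequency_domain_features <- function(rr, resample_fs = 4,
                                      bands = list(vlf = c(0.005, 0.04),
                                                   lf = c(0.04, 0.15),
                                                   hf = c(0.15, 0.4)),
                                      min_duration = 300) {
  stopifnot(inherits(rr, "rr_series"))
  span <- diff(range(rr$times))
  if (span < min_duration) {
    stop_insufficient(sprintf("window of %.0f s is below the %.0f s minimum for spectral analysis",
                              span, min_duration))
  }
  grid <- seq(min(rr$times), max(rr$times), by = 1 / resample_fs)
  y <- stats::spline(rr$times, rr$rr, xout = grid, method = "fmm")$y
  spec <- welch_psd(y - mean(y), fs = resample_fs)
  p <- vapply(bands, function(b) band_power(spec, b[1], b[2]), numeric(1))
  total <- sum(p)
  if (total <= 0) stop_insufficient("zero spectral power in the VLF+LF+HF range")
  list(p_VLF = 100 * p[["vlf"]] / total,
       p_LF = 100 * p[["lf"]] / total,
       p_HF = 100 * p[["hf"]] / total,
       HF_LF = if (p[["lf"]] > 0) p[["hf"]] / p[["lf"]] else NA_real_,
       total_power = total)
}

#' Poincare plot descriptors
#'
#' Closed forms on the lag-1 return map with population (denominator N)
#' variances: `SD1 = sqrt(var(diff(rr)) / 2)` (short-term variability,
#' width of the ellipse across the identity line) and
#' `SD2 = sqrt(2 * var(rr) - var(diff(rr)) / 2)` (long-term variability,
#' length along it). A negative radicand from rounding is clipped to zero.
#' The identity `SD1^2 + SD2^2 = 2 * var(rr)` holds exactly.
#'
#' @param rr Intervals, ms (numeric vector or [rr_series]), length >= 3.
#' @return Named list `SD1, SD2` (ms).
#' @export
poincare_features <- function(rr) {
  if (inherits(rr, "rr_series")) rr <- rr$rr
  if (length(rr) < 3L) stop_insufficient("need at least 3 intervals for Poincare features")
  vd <- var_pop(diff(rr))
  v <- var_pop(rr)
  sd2sq <- 2 * v - vd / 2
  list(SD1 = sqrt(vd / 2), SD2 = sqrt(max(sd2sq, 0)))
}

#' Hourly HRV features averaged over the observation window
#'
#' Splits the series into consecutive hourly windows covering
#' `[window_start, window_end)` (hours from admission), computes all 16
#' features in each window, and averages each feature over the windows in
#' which its preconditions hold. The per-feature count of contributing
#' windows is attached as attribute `n_windows`.
#'
#' @param rr An [rr_series] (cleaned).
#' @param window_start,window_end Analysis window bounds, hours from
#'   admission. Defaults give 12 hourly segments starting at the 2nd hour.
#' @param rqa An [rqa_params()] configuration.
#' @param bands Frequency bands passed to [frequency_domain_features()].
#' @return Object of class `hrv_features`: named numeric vector of the 16
#'   features, `NA` where undefined in every window.
#' @export
hourly_hrv <- function(rr, window_start = 2, window_end = 14,
                       rqa = rqa_params(), bands = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  if (window_end <= window_start) stop_invalid("window_end must exceed window_start")
  starts <- seq(window_start, window_end - 1e-9, by = 1)
  feat_names <- hrv_feature_names()
  acc <- matrix(NA_real_, length(starts), length(feat_names),
                dimnames = list(NULL, feat_names))
  for (w in seq_along(starts)) {
    lo <- starts[w] * 3600
    hi <- min(starts[w] + 1, window_end) * 3600
    sel <- rr$times >= lo & rr$times < hi
    if (sum(sel) < 2L) next
    sub <- rr_series(rr$rr[sel], times = rr$times[sel])
    acc[w, ] <- window_hrv(sub, rqa = rqa, bands = bands)
  }
  n_win <- colSums(!is.na(acc))
  if (all(n_win == 0)) stop_insufficient("no window yielded any HRV feature")
  out <- colMeans(acc, na.rm = TRUE)
  out[n_win == 0] <- NA_real_
  structure(out, n_windows = n_win, class = c("hrv_features", "numeric"))
}

hrv_feature_names <- function() {
  c("SDNN", "SDANN", "MeanRR", "RMSSD", "pNN50",
    "p_VLF", "p_LF", "p_HF", "HF_LF",
    "REC", "DET", "LAM", "SD1", "SD2", "Alpha1", "Alpha2")
}

# All 16 features on one window; families failing their preconditions
# contribute NA for that window.
window_hrv <- function(sub, rqa, bands = NULL) {
  out <- stats::setNames(rep(NA_real_, 16L), hrv_feature_names())
  td <- tryCatch(time_domain_features(sub), hrvnet_error = function(e) NULL)
  if (!is.null(td)) out[c("SDNN", "SDANN", "MeanRR", "RMSSD", "pNN50")] <-
    unlist(td)[c("SDNN", "SDANN", "MeanRR", "RMSSD", "pNN50")]
  fd <- tryCatch(
    if (is.null(bands)) frequency_domain_features(sub)
    else frequency_domain_features(sub, bands = bands),
    hrvnet_error = function(e) NULL)
  if (!is.null(fd)) out[c("p_VLF", "p_LF", "p_HF", "HF_LF")] <-
    unlist(fd)[c("p_VLF", "p_LF", "p_HF", "HF_LF")]
  pc <- tryCatch(poincare_features(sub), hrvnet_error = function(e) NULL)
  if (!is.null(pc)) out[c("SD1", "SD2")] <- unlist(pc)
  rq <- tryCatch(rqa_features(sub$rr, params = rqa), hrvnet_error = function(e) NULL)
  if (!is.null(rq)) out[c("REC", "DET", "LAM")] <- unlist(rq)[c("REC", "DET", "LAM")]
  df <- tryCatch(dfa_features(sub$rr), hrvnet_error = function(e) NULL)
  if (!is.null(df)) out[c("Alpha1", "Alpha2")] <- unlist(df)
  out
}

#' @export
print.hrv_features <- function(x, ...) {
  cat("HRV features (window averages):\n")
  print(round(unclass(x), 4))
  invisible(x)
}
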