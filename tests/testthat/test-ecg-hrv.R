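test_that("R-peak detector recovers planted beats exactly on clean input", {
  rr <- rr_series(c(800, 850, 900))
  det <- detect_r_peaks(synthesize_ecg(rr, fs = 240))
  expect_equal(length(det$peak_times), 4)
  expect_true(all(abs(det$rr - rr$rr) <= 1000 / 240))
})

test_that("detector errors on flat traces and unsupported rates", {
  flat <- ecg_trace(numeric(1000), fs = 240)
  expect_error(detect_r_peaks(flat), class = "hrvnet_no_beats")
  tr <- ecg_trace(sin(seq(0, 20, length.out = 500)), fs = 90)
  expect_error(detect_r_peaks(tr), class = "hrvnet_unsupported_rate")
})

test_that("detector is robust to 5% baseline noise over 5 minutes of regular rhythm", {
  perfect <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    rr <- rr_series(rep(1000, 299))  # 60 bpm, 5 min
    ecg <- synthesize_ecg(rr, fs = 240, amplitude = 1, baseline_noise_sd = 0.05,
                          seed = s)
    det <- detect_r_peaks(ecg)
    if (length(det$peak_times) == 300) perfect <- perfect + 1L
  }
  expect_gte(perfect / n_seeds, 0.95)
})

test_that("interval cleaning drops exactly the out-of-range intervals", {
  ok <- rr_series(c(800, 900, 1000))
  cleaned <- clean_rr(ok)
  expect_equal(cleaned$rr, ok$rr)
  expect_equal(attr(cleaned, "n_removed"), 0L)

  one_bad <- rr_series(c(800, 2500, 900, 850))
  cl <- clean_rr(one_bad)
  expect_equal(cl$rr, c(800, 900, 850))
  expect_equal(attr(cl, "n_removed"), 1L)

  alt <- rr_series(rep(c(800, 2500), 5))
  cla <- clean_rr(alt)
  expect_equal(cla$rr, rep(800, 5))
  expect_equal(attr(cla, "fraction_removed"), 0.5)

  allbad <- rr_series(rep(2500, 4))
  expect_error(clean_rr(allbad), class = "hrvnet_insufficient_data")
})

test_that("time-domain features match hand enumeration", {
  td <- time_domain_features(c(800, 860, 870, 940))
  expect_equal(td$pNN50, 50)  # |diffs| = 60, 10, 70 -> 2 of 4 intervals
  expect_equal(td$MeanRR, mean(c(800, 860, 870, 940)))

  td2 <- time_domain_features(c(800, 850, 800))
  expect_equal(td2$RMSSD, 50)  # sqrt((50^2 + 50^2) / 2)

  cst <- time_domain_features(rep(900, 50))
  expect_equal(cst$SDNN, 0)
  expect_equal(cst$RMSSD, 0)
  expect_equal(cst$pNN50, 0)
  expect_equal(cst$MeanRR, 900)

  expect_error(time_domain_features(800), class = "hrvnet_insufficient_data")
})

test_that("time-domain and Poincare features match brute-force oracles on random series", {
  for (s in 1:20) {
    set.seed(s)
    rr <- stats::rnorm(200, 850, 40)
    td <- time_domain_features(rr)
    n <- length(rr)
    expect_equal(td$MeanRR, sum(rr) / n, tolerance = 1e-9)
    expect_equal(td$SDNN, sqrt(sum((rr - sum(rr) / n)^2) / (n - 1)), tolerance = 1e-9)
    d <- rr[-1] - rr[-n]
    expect_equal(td$RMSSD, sqrt(sum(d^2) / (n - 1)), tolerance = 1e-9)
    expect_equal(td$pNN50, 100 * sum(abs(d) > 50) / n, tolerance = 1e-9)
    pc <- poincare_features(rr)
    vd <- mean((d - mean(d))^2)
    vr <- mean((rr - mean(rr))^2)
    expect_equal(pc$SD1, sqrt(vd / 2), tolerance = 1e-9)
    expect_equal(pc$SD2, sqrt(2 * vr - vd / 2), tolerance = 1e-9)
    # ellipse identity: SD1^2 + SD2^2 = 2 * population SDNN^2
    expect_equal(pc$SD1^2 + pc$SD2^2, 2 * vr, tolerance = 1e-9)
  }
})

test_that("SDANN is the SD of five-minute segment means", {
  # 12 min of 1 s beats: segments 0-5, 5-10, 10-12 min
  rr <- rep(1000, 720)
  rr[1:300] <- 900
  t_s <- cumsum(c(0, rr[-720])) / 1000
  td <- time_domain_features(rr, times = t_s)
  seg <- floor(t_s / 300)
  expect_equal(td$SDANN, stats::sd(tapply(rr, seg, mean)), tolerance = 1e-12)
  # too short for two segments -> NA
  expect_true(is.na(time_domain_features(rep(800, 10))$SDANN))
})

test_that("single-tone modulations land in their spectral bands", {
  lf <- generate_rr_series(800, sd_lf = 30, f_lf = 0.10, duration = 600, seed = 5)
  hf <- generate_rr_series(800, sd_hf = 30, f_hf = 0.25, duration = 600, seed = 5)
  fd_lf <- frequency_domain_features(lf)
  fd_hf <- frequency_domain_features(hf)
  expect_gt(fd_lf$p_LF, 90)
  expect_gt(fd_hf$p_HF, 90)
  expect_lt(fd_hf$p_LF + fd_hf$p_VLF, 10)
  expect_equal(fd_lf$p_VLF + fd_lf$p_LF + fd_lf$p_HF, 100, tolerance = 1e-6)
  expect_equal(fd_hf$p_VLF + fd_hf$p_LF + fd_hf$p_HF, 100, tolerance = 1e-6)
})

test_that("spectral analysis refuses windows shorter than five minutes", {
  rr <- generate_rr_series(800, sd_noise = 10, duration = 200, seed = 1)
  expect_error(frequency_domain_features(rr), class = "hrvnet_insufficient_data")
})

test_that("Poincare features on alternating and constant series match closed forms", {
  alt <- rep(c(800, 820), 300)
  pc <- poincare_features(alt)
  expect_equal(pc$SD1, sqrt(200), tolerance = 1e-2)
  expect_lt(pc$SD2, 1)
  cst <- poincare_features(rep(777, 10))
  expect_equal(cst$SD1, 0)
  expect_equal(cst$SD2, 0)
  expect_error(poincare_features(c(800, 810)), class = "hrvnet_insufficient_data")
})

test_that("hourly averaging approximates the full-window value on stationary input", {
  rr <- generate_rr_series(850, sd_noise = 25, duration = 4 * 3600, seed = 9)
  hf <- hourly_hrv(rr, window_start = 0, window_end = 4)
  expect_lt(abs(hf[["SDNN"]] - stats::sd(rr$rr)) / stats::sd(rr$rr), 0.10)
  expect_equal(unname(attr(hf, "n_windows")[["SDNN"]]), 4)
})

test_that("hourly features fall back to the windows where they are defined", {
  # 90 minutes of data in a 3-hour window: hour 1 full, hour 2 half, hour 3 empty
  rr <- generate_rr_series(800, sd_noise = 15, duration = 5400, seed = 2)
  hf <- hourly_hrv(rr, window_start = 0, window_end = 3)
  nw <- attr(hf, "n_windows")
  expect_equal(unname(nw[["SDNN"]]), 2)
  expect_false(anyNA(hf[c("SDNN", "MeanRR", "RMSSD")]))
  # single-window input returns that window's features
  rr1 <- generate_rr_series(800, sd_noise = 15, duration = 3600, seed = 3)
  one <- hourly_hrv(rr1, window_start = 0, window_end = 1)
  sub <- rr_series(rr1$rr[rr1$times < 3600], times = rr1$times[rr1$times < 3600])
  expect_equal(one[["SDNN"]], time_domain_features(sub)$SDNN, tolerance = 1e-12)
  # no data in the window at all
  expect_error(hourly_hrv(rr1, window_start = 5, window_end = 6),
               class = "hrvnet_insufficient_data")
})

test_that("RR and ECG input paths agree on noise-free round-trip data", {
  rr <- generate_rr_series(850, sd_lf = 20, sd_hf = 15, sd_noise = 10,
                           duration = 1200, seed = 6)
  det <- detect_r_peaks(synthesize_ecg(rr, fs = 240))
  td_rr <- time_domain_features(rr)
  td_ecg <- time_domain_features(det)
  expect_equal(td_ecg$MeanRR, td_rr$MeanRR, tolerance = 1e-3)
  expect_equal(td_ecg$SDNN, td_rr$SDNN, tolerance = 0.02)
  fd_rr <- frequency_domain_features(rr)
  fd_ecg <- frequency_domain_features(det)
  expect_equal(fd_ecg$p_HF, fd_rr$p_HF, tolerance = 0.05)
})
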