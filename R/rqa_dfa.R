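# Nonlinear HRV: recurrence quantification analysis and detrended
# fluctuation analysis.

#' Recurrence analysis parameters
#'
#' @param embedding_dim Embedding dimension (>= 1).
#' @param delay Embedding delay, beats (>= 1).
#' @param radius Recurrence threshold as a fraction of the maximum
#'   phase-space distance, in (0, 1].
#' @param l_min Minimum diagonal/vertical line length (>= 2).
#' @param max_beats Upper bound on the number of intervals analysed per
#'   window; longer windows are truncated to their first `max_beats`
#'   intervals (contiguous, preserving successive-beat structure) to keep
#'   the O(N^2) recurrence matrix affordable.
#' @export
rqa_params <- function(embedding_dim = 10L, delay = 1L, radius = 0.1,
                       l_min = 2L, max_beats = 1500L) {
  if (embedding_dim < 1L || delay < 1L || l_min < 2L) {
    stop_invalid("embedding_dim >= 1, delay >= 1 and l_min >= 2 required")
  }
  if (radius <= 0 || radius > 1) stop_invalid("radius must be in (0, 1]")
  structure(list(embedding_dim = as.integer(embedding_dim), delay = as.integer(delay),
                 radius = radius, l_min = as.integer(l_min),
                 max_beats = as.integer(max_beats)), class = "rqa_params")
}

#' Recurrence quantification of an R-R series
#'
#' Delay-embeds the series, thresholds pairwise Euclidean distances at
#' `radius * max(distance)` to obtain the recurrence matrix (main diagonal
#' excluded), and reports:
#' * `REC`: percentage of recurrent points,
#' * `DET`: fraction of recurrent points lying on diagonal lines of length
#'   >= `l_min` (determinism),
#' * `LAM`: fraction lying on vertical lines of length >= `l_min`
#'   (laminarity).
#'
#' @param rr Intervals, ms (numeric vector or [rr_series]).
#' @param params An [rqa_params()].
#' @return Named list `REC` (percent), `DET`, `LAM` (fractions in [0, 1]).
#' @export
rqa_features <- function(rr, params = rqa_params()) {
  if (inherits(rr, "rr_series")) rr <- rr$rr
  m <- params$embedding_dim
  tau <- params$delay
  need <- (m - 1L) * tau + params$l_min + 1L
  if (length(rr) < need) {
    stop_insufficient(sprintf("need at least %d intervals for recurrence analysis", need))
  }
  if (length(rr) > params$max_beats) rr <- rr[seq_len(params$max_beats)]
  N <- length(rr) - (m - 1L) * tau
  emb <- sapply(seq_len(m), function(j) rr[(1:N) + (j - 1L) * tau])
  if (is.null(dim(emb))) emb <- matrix(emb, ncol = m)
  D <- as.matrix(stats::dist(emb))
  thr <- params$radius * max(D)
  R <- D <= thr
  diag(R) <- FALSE
  n_rec <- sum(R)
  rec <- 100 * n_rec / (N * (N - 1L))
  if (n_rec == 0L) return(list(REC = 0, DET = 0, LAM = 0))
  # diagonal lines (parallel to the line of identity), both triangles
  det_pts <- 0L
  for (k in seq_len(N - 1L)) {
    di <- R[cbind(1:(N - k), (1:(N - k)) + k)]
    r <- rle(di)
    long <- r$values & r$lengths >= params$l_min
    det_pts <- det_pts + 2L * sum(r$lengths[long])
  }
  # vertical lines (columns)
  lam_pts <- 0L
  for (j in seq_len(N)) {
    r <- rle(R[, j])
    long <- r$values & r$lengths >= params$l_min
    lam_pts <- lam_pts + sum(r$lengths[long])
  }
  list(REC = rec, DET = det_pts / n_rec, LAM = lam_pts / n_rec)
}

#' Detrended fluctuation analysis exponents
#'
#' Standard DFA: integrate the mean-centered series, split the profile
#' into non-overlapping boxes of size `s`, detrend each box by its least
#' squares line, and take the RMS residual `F(s)`. `Alpha1` is the slope
#' of `log F` on `log s` over boxes of 4-16 beats (short-range scaling),
#' `Alpha2` over 16-64 beats (long-range). White noise gives alpha near
#' 0.5, a random walk near 1.5.
#'
#' @param rr Intervals, ms (numeric vector or [rr_series]), length >= 70
#'   so the largest (64-beat) box fits.
#' @param scales1,scales2 Box sizes for the two fits.
#' @return Named list `Alpha1, Alpha2`.
#' @export
dfa_features <- function(rr, scales1 = 4:16,
                         scales2 = c(16L, 20L, 25L, 32L, 40L, 51L, 64L)) {
  if (inherits(rr, "rr_series")) rr <- rr$rr
  if (length(rr) < 70L) stop_insufficient("need at least 70 intervals for DFA")
  y <- cumsum(rr - mean(rr))
  fl <- function(scales) {
    vapply(scales, function(s) dfa_fluct(y, s), numeric(1))
  }
  fit <- function(scales, F) {
    keep <- F > 0
    if (sum(keep) < 2L) return(NA_real_)
    ols_slope(log(scales[keep]), log(F[keep]))
  }
  F1 <- fl(scales1)
  F2 <- fl(scales2)
  list(Alpha1 = fit(scales1, F1), Alpha2 = fit(scales2, F2))
}

# RMS fluctuation of the integrated profile at box size s (non-overlapping
# boxes, per-box linear detrend), vectorized over boxes.
dfa_fluct <- function(y, s) {
  nb <- length(y) %/% s
  if (nb < 1L) return(NA_real_)
  Y <- matrix(y[seq_len(nb * s)], nrow = s)
  x <- seq_len(s)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  beta <- colSums(Y * xc) / sxx
  alpha <- colMeans(Y)
  res <- Y - outer(xc, beta) - matrix(alpha, s, nb, byrow = TRUE)
  sqrt(mean(res^2))
}
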