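# Shared internal helpers: error conditions, seed derivation, spectral tools.

hrvnet_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "hrvnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_invalid <- function(msg) hrvnet_error("hrvnet_validation_error", msg)
stop_insufficient <- function(msg) hrvnet_error("hrvnet_insufficient_data", msg)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed from a master seed; stays below 2^31 - 1.
# Doubles are exact up to 2^53, so the product never loses integer precision.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647L)
}

# Discrete analytic signal via FFT (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(as.complex(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# Welch PSD: mean of Hann-windowed, mean-detrended, 50%-overlapping
# modified periodograms. Returns a one-sided density (unit^2 / Hz).
welch_psd <- function(x, fs, nseg = 256L, overlap = 0.5) {
  n <- length(x)
  if (n < 64L) stop_insufficient("series too short for Welch PSD (need >= 64 samples)")
  nseg <- as.integer(min(nseg, 2^floor(log2(n))))
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  w <- hann_window(nseg)
  scale <- fs * sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / scale
    P <- P[seq_len(nfreq)]
    # fold two-sided density into one-sided (DC and Nyquist not doubled)
    if (nseg %% 2L == 0L) P[2:(nfreq - 1L)] <- 2 * P[2:(nfreq - 1L)]
    else P[2:nfreq] <- 2 * P[2:nfreq]
    acc <- acc + P
  }
  list(freq = (0:(nfreq - 1L)) * fs / nseg, psd = acc / length(starts),
       df = fs / nseg, n_segments = length(starts))
}

band_power <- function(spec, lo, hi) {
  sel <- spec$freq >= lo & spec$freq < hi
  sum(spec$psd[sel]) * spec$df
}

# Population (denominator N) variance.
var_pop <- function(x) mean((x - mean(x))^2)

# Ordinary least squares slope of y on x; assumes length >= 2, var(x) > 0.
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}
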