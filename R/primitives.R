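#' @title Common signal-processing primitives
#' @description Zero-phase filtering, differentiation, extremum and
#'   sharp-change detection, envelopes, PCA, power spectra, empirical mode
#'   decomposition and Hilbert-Huang instantaneous energy. These are the
#'   building blocks shared by all macro and micro detectors.
#' @name signal_primitives
NULL

#' Zero-phase low-pass Butterworth filter
#'
#' Second order (by default) Butterworth filter applied forward and backward
#' (`signal::filtfilt`), so that the filtered signal has no phase lag and
#' detected event times are not shifted. The effective magnitude response is
#' the squared one-pass response; DC gain is exactly 1.
#'
#' @param ts a [swim_ts()] object.
#' @param fc cutoff frequency in Hz; must satisfy 0 < fc < fs / 2.
#' @param order filter order (>= 1), default 2.
#' @return a filtered `swim_ts` of equal length.
#' @export
lowpass <- function(ts, fc, order = 2L) {
  stopifnot(inherits(ts, "swim_ts"))
  if (!is.finite(fc) || fc <= 0 || fc >= ts$fs / 2) {
    stop(sprintf("lowpass: fc must lie in (0, fs/2) = (0, %g); got %g",
                 ts$fs / 2, fc), call. = FALSE)
  }
  if (order < 1L) stop("lowpass: order must be >= 1", call. = FALSE)
  bf <- signal::butter(order, fc / (ts$fs / 2), type = "low")
  same_grid_ts(ts, filtfilt_padded(bf, ts$values, ts$fs, fc))
}

# zero-phase filtering with odd-reflection padding at both ends, so that a
# nonzero boundary level does not inject a startup transient
filtfilt_padded <- function(bf, x, fs, fc) {
  n <- length(x)
  k <- min(n - 1L, as.integer(ceiling(6 * fs / fc)))
  if (k < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  head_pad <- 2 * x[1L] - x[(k + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - k)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(k + 1L):(k + n)]
}

#' Numerical derivative of a time series
#'
#' Central differences scaled by the sampling rate; one-sided differences at
#' the two edges. Exact for linear signals.
#'
#' @param ts a [swim_ts()] object with at least two samples.
#' @return a `swim_ts` of equal length with the derivative (units/s).
#' @export
ts_derivative <- function(ts) {
  stopifnot(inherits(ts, "swim_ts"))
  v <- ts$values
  n <- length(v)
  if (n < 2L) stop("ts_derivative: need at least 2 samples", call. = FALSE)
  d <- numeric(n)
  if (n > 2L) d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) * ts$fs / 2
  d[1L] <- (v[2L] - v[1L]) * ts$fs
  d[n] <- (v[n] - v[n - 1L]) * ts$fs
  same_grid_ts(ts, d)
}

# prominence of the k-th strict local maximum of v (indices ext_idx)
peak_prominence <- function(v, idx) {
  vapply(idx, function(i) {
    h <- v[i]
    # walk left until a higher sample (or the edge); track the minimum
    left <- i
    lmin <- h
    while (left > 1L && v[left] <= h) {
      left <- left - 1L
      if (v[left] < lmin) lmin <- v[left]
    }
    right <- i
    rmin <- h
    n <- length(v)
    while (right < n && v[right] <= h) {
      right <- right + 1L
      if (v[right] < rmin) rmin <- v[right]
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Extremum detection (peaks and troughs against a threshold)
#'
#' Finds strict local maxima with amplitude `>= threshold` (peaks) or strict
#' local minima with amplitude `<= threshold` (troughs); on a signed signal a
#' negative threshold together with `polarity = "trough"` expresses the
#' trough criteria used by several detectors. Events are returned sorted by
#' time.
#'
#' @param ts a [swim_ts()] object.
#' @param threshold amplitude threshold in signal units.
#' @param polarity `"peak"` or `"trough"`.
#' @param min_prominence optional minimal topographic prominence; events
#'   below it are dropped.
#' @return a data.frame with columns `time`, `amplitude`, `polarity`
#'   (zero rows when nothing qualifies).
#' @export
detect_extrema <- function(ts, threshold, polarity = c("peak", "trough"),
                           min_prominence = NULL) {
  stopifnot(inherits(ts, "swim_ts"))
  polarity <- match.arg(polarity)
  v <- if (polarity == "peak") ts$values else -ts$values
  th <- if (polarity == "peak") threshold else -threshold
  n <- length(v)
  empty <- data.frame(time = numeric(0), amplitude = numeric(0),
                      polarity = character(0), stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  i <- 2:(n - 1L)
  idx <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L] & v[i] >= th]
  if (!is.null(min_prominence) && length(idx)) {
    idx <- idx[peak_prominence(v, idx) >= min_prominence]
  }
  if (!length(idx)) return(empty)
  data.frame(time = ts$t0 + (idx - 1L) / ts$fs,
             amplitude = ts$values[idx],
             polarity = polarity,
             stringsAsFactors = FALSE)
}

#' Sharp-change detection on the derivative of a low-passed signal
#'
#' Low-pass filters the signal, differentiates it, and thresholds the
#' derivative at `fraction` of its global extremum magnitude: derivative
#' peaks above the threshold are returned with polarity `"rise"`, troughs
#' below the negative threshold with polarity `"fall"`. Applied to the
#' longitudinal acceleration this detects the abrupt posture changes bounding
#' a swimming bout (falls are approximate bout starts, rises approximate
#' ends).
#'
#' @param ts a [swim_ts()] object.
#' @param fraction fraction (0, 1] of the global derivative extremum used as
#'   the threshold; the bout detector uses 0.3.
#' @param fc cutoff of the internal low-pass in Hz. Posture changes are slow,
#'   so the default (0.15 Hz) suppresses stroke-frequency content.
#' @param order Butterworth order of the internal low-pass.
#' @return a data.frame with columns `time`, `amplitude` (derivative value,
#'   units/s) and `polarity` (`"rise"`/`"fall"`), sorted by time; empty for
#'   constant input.
#' @export
detect_sharp_change <- function(ts, fraction, fc = 0.15, order = 2L) {
  stopifnot(inherits(ts, "swim_ts"))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("detect_sharp_change: fraction must lie in (0, 1]", call. = FALSE)
  }
  if (diff(range(ts$values)) < 1e-12) {
    return(data.frame(time = numeric(0), amplitude = numeric(0),
                      polarity = character(0), stringsAsFactors = FALSE))
  }
  d <- ts_derivative(lowpass(ts, fc = fc, order = order))
  m <- max(abs(d$values))
  if (m < 1e-12) {
    return(data.frame(time = numeric(0), amplitude = numeric(0),
                      polarity = character(0), stringsAsFactors = FALSE))
  }
  th <- fraction * m
  rises <- detect_extrema(d, th, "peak")
  falls <- detect_extrema(d, -th, "trough")
  if (nrow(rises)) rises$polarity <- "rise"
  if (nrow(falls)) falls$polarity <- "fall"
  out <- rbind(rises, falls)
  out[order(out$time), , drop = FALSE]
}

# discrete analytic signal via the FFT (complex; Re = input - mean handling
# is left to callers)
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = rep(0, n)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# moving average with shrinking (partial) windows at the edges
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  n <- length(x)
  if (k == 1L || n == 1L) return(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Amplitude envelope of a time series
#'
#' Magnitude of the analytic signal of the running-mean-removed series, added
#' back to the running mean and smoothed with a moving average of length
#' `window`. For an oscillation of amplitude A about a slowly varying mean m
#' the result approximates m + A. Used to detect wrist activity periods.
#'
#' @param ts a [swim_ts()] object.
#' @param window smoothing window in seconds (>= 2 samples).
#' @return a `swim_ts` with the envelope.
#' @export
envelope <- function(ts, window = 1) {
  stopifnot(inherits(ts, "swim_ts"))
  k <- as.integer(round(window * ts$fs))
  if (!is.finite(window) || window <= 0 || k < 2L) {
    stop("envelope: 'window' must cover at least 2 samples", call. = FALSE)
  }
  x <- ts$values
  runmean <- moving_average(x, k)
  env <- Mod(analytic_signal(x - runmean)) + runmean
  same_grid_ts(ts, moving_average(env, k))
}

#' Principal components of a 3-axis sample cloud
#'
#' Eigen-decomposition of the sample covariance of mean-centered N x 3 data,
#' components sorted by decreasing explained variance. Used to identify the
#' dominant rotation or acceleration axis of a movement.
#'
#' @param samples numeric matrix with N >= 3 rows and 3 columns.
#' @return list with `components` (3 x 3 matrix, orthonormal columns) and
#'   `variance_ratios` (length-3 fractions summing to 1).
#' @export
principal_components <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 3L || ncol(samples) != 3L) {
    stop("principal_components: need an N x 3 matrix with N >= 3",
         call. = FALSE)
  }
  centered <- scale(samples, center = TRUE, scale = FALSE)
  cv <- stats::cov(centered)
  if (sum(diag(cv)) < 1e-24) {
    stop("principal_components: degenerate input (no variance)",
         call. = FALSE)
  }
  eg <- eigen(cv, symmetric = TRUE)
  list(components = eg$vectors,
       variance_ratios = pmax(eg$values, 0) / sum(pmax(eg$values, 0)))
}

#' Single-sided power density spectrum
#'
#' FFT-based periodogram with frequency resolution fs/N, scaled so that the
#' total power `sum(power) * df` equals the mean square of the series
#' (Parseval identity).
#'
#' @param ts a [swim_ts()] object with at least 8 samples.
#' @return list with `frequencies` (Hz) and `power` (units^2/Hz).
#' @export
power_spectrum <- function(ts) {
  stopifnot(inherits(ts, "swim_ts"))
  v <- ts$values
  n <- length(v)
  if (n < 8L) stop("power_spectrum: need at least 8 samples", call. = FALSE)
  df <- ts$fs / n
  X <- stats::fft(v)
  nh <- n %/% 2L + 1L
  p <- (Mod(X[seq_len(nh)])^2) / (n^2 * df)
  scale <- rep(2, nh)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[nh] <- 1
  list(frequencies = (seq_len(nh) - 1L) * df, power = p * scale)
}

# amplitude spectrum (2|X_k|/N) restricted to a frequency band; used by the
# technique identifiers, which threshold spectral magnitude in g
amplitude_spectrum <- function(ts, band = NULL) {
  v <- ts$values - mean(ts$values)
  n <- length(v)
  X <- stats::fft(v)
  nh <- n %/% 2L + 1L
  freq <- (seq_len(nh) - 1L) * ts$fs / n
  amp <- 2 * Mod(X[seq_len(nh)]) / n
  amp[1L] <- amp[1L] / 2
  if (!is.null(band)) {
    keep <- freq >= band[1L] & freq <= band[2L]
    freq <- freq[keep]
    amp <- amp[keep]
  }
  list(frequencies = freq, amplitude = amp)
}

# strict local extrema indices (maxima of v)
local_max_idx <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
}

# cubic-spline envelope through extrema with mirror boundary extension
spline_envelope <- function(idx, val, n) {
  if (length(idx) < 2L) return(rep(if (length(val)) val[1L] else 0, n))
  # mirror the two outermost extrema about each boundary
  k <- min(2L, length(idx))
  xi <- c(2 - rev(idx[seq_len(k)]), idx, 2 * n - rev(idx)[seq_len(k)])
  yi <- c(rev(val[seq_len(k)]), val, rev(val)[seq_len(k)])
  stats::spline(xi, yi, xout = seq_len(n), method = "natural")$y
}

#' Empirical mode decomposition
#'
#' Classic sifting with cubic-spline envelopes (mirror boundary extension)
#' and the standard-deviation stopping criterion (0.2). IMFs are returned
#' fast-to-slow; the residual is the input minus the sum of the IMFs, so the
#' reconstruction identity holds exactly.
#'
#' @param ts a [swim_ts()] object with at least 16 samples.
#' @param max_imfs maximum number of IMFs to extract (>= 1).
#' @param sd_stop sifting stop threshold (Cauchy-type SD criterion).
#' @return list with `imfs` (list of `swim_ts`, possibly empty) and
#'   `residual` (`swim_ts`).
#' @export
emd <- function(ts, max_imfs = 8L, sd_stop = 0.2) {
  stopifnot(inherits(ts, "swim_ts"))
  n <- length(ts$values)
  if (n < 16L) stop("emd: need at least 16 samples", call. = FALSE)
  if (max_imfs < 1L) stop("emd: max_imfs must be >= 1", call. = FALSE)
  residual <- ts$values
  imfs <- list()
  repeat {
    if (length(imfs) >= max_imfs) break
    mx <- local_max_idx(residual)
    mn <- local_max_idx(-residual)
    if (length(mx) + length(mn) < 3L) break   # monotone-ish: residual reached
    h <- residual
    for (sift in seq_len(50L)) {
      mxi <- local_max_idx(h)
      mni <- local_max_idx(-h)
      if (length(mxi) < 2L || length(mni) < 2L) break
      upper <- spline_envelope(mxi, h[mxi], n)
      lower <- spline_envelope(mni, h[mni], n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sdc <- sum(m^2) / sum(h^2 + 1e-12)
      h <- h_new
      if (sdc < sd_stop) break
    }
    imfs[[length(imfs) + 1L]] <- same_grid_ts(ts, h)
    residual <- residual - h
  }
  list(imfs = imfs, residual = same_grid_ts(ts, residual))
}

#' Hilbert-Huang instantaneous energy
#'
#' Squared magnitude of the analytic signal of the mean-removed input: for a
#' pure tone of amplitude A the energy is A^2 away from the edges. Applied to
#' angular velocity (deg/s) the energy carries units (deg/s)^2; the onset
#' thresholds quoted in deg/s^2 by the detector rules are applied to this
#' quantity at face value.
#'
#' @param ts a [swim_ts()] object with at least 16 samples.
#' @return a nonnegative `swim_ts` (units^2).
#' @export
instantaneous_energy <- function(ts) {
  stopifnot(inherits(ts, "swim_ts"))
  if (length(ts$values) < 16L) {
    stop("instantaneous_energy: need at least 16 samples", call. = FALSE)
  }
  x <- ts$values - mean(ts$values)
  same_grid_ts(ts, Mod(analytic_signal(x))^2)
}
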