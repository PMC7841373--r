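#' Regularly sampled single-axis time series
#'
#' Light container used by all signal primitives: a numeric vector of samples,
#' a sampling rate `fs` (Hz) and a start time `t0` (s). Acceleration is
#' expressed in g and angular velocity in deg/s throughout the package.
#'
#' @param values numeric vector of samples (finite, length >= 1).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return an object of class `swim_ts`.
#' @export
#' @examples
#' x <- swim_ts(sin(2 * pi * 2 * seq(0, 1, by = 1 / 500)), fs = 500)
#' range(ts_time(x))
swim_ts <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("swim_ts: 'values' must have length >= 1", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("swim_ts: all values must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("swim_ts: 'fs' must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "swim_ts")
}

#' @export
print.swim_ts <- function(x, ...) {
  cat(sprintf("<swim_ts> %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              length(x$values), x$fs, x$t0,
              x$t0 + (length(x$values) - 1L) / x$fs))
  invisible(x)
}

#' Sample times of a time series
#'
#' @param ts a [swim_ts()] object.
#' @return numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) {
  ts$t0 + (seq_along(ts$values) - 1L) / ts$fs
}

#' @export
length.swim_ts <- function(x) length(x$values)

# nearest-sample index for a time, clipped to the series
ts_index <- function(ts, time) {
  i <- as.integer(round((time - ts$t0) * ts$fs)) + 1L
  pmin(pmax(i, 1L), length(ts$values))
}

#' Extract a time window from a time series
#'
#' Clips `[from, to]` to the span of the series and returns the enclosed
#' samples as a new `swim_ts` (t0 adjusted accordingly).
#'
#' @param ts a [swim_ts()] object.
#' @param from,to window boundaries in seconds.
#' @return a `swim_ts` covering the clipped window.
#' @export
ts_window <- function(ts, from, to) {
  if (to < from) stop("ts_window: 'to' must be >= 'from'", call. = FALSE)
  i0 <- ts_index(ts, from)
  i1 <- ts_index(ts, to)
  swim_ts(ts$values[i0:i1], fs = ts$fs, t0 = ts$t0 + (i0 - 1L) / ts$fs)
}

same_grid_ts <- function(ts, values) swim_ts(values, fs = ts$fs, t0 = ts$t0)
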