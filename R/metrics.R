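#' @title Validation metrics
#' @description Detection scores (sensitivity, precision, accuracy), event
#'   error statistics, phase-duration errors, Bland-Altman agreement and
#'   threshold-sensitivity sweeps.
#' @name validation_metrics
NULL

# greedy one-to-one matching of two sorted event lists within a tolerance;
# symmetric in the two roles
match_events <- function(detected, truth, tolerance) {
  detected <- sort(detected)
  truth <- sort(truth)
  i <- j <- 1L
  pairs <- matrix(numeric(0), ncol = 2L)
  while (i <= length(detected) && j <= length(truth)) {
    d <- detected[i]
    tr <- truth[j]
    if (abs(d - tr) <= tolerance) {
      pairs <- rbind(pairs, c(d, tr))
      i <- i + 1L
      j <- j + 1L
    } else if (d < tr) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  pairs
}

#' Detection scores against ground truth
#'
#' Events are matched one-to-one in time order within `tolerance`; matched
#' events are true positives, unmatched detections false positives,
#' unmatched truths false negatives. True negatives are zero by convention
#' (the detectors only report occurrences), so
#' sensitivity = tp / (tp + fn), precision = tp / (tp + fp) and
#' accuracy = (tp + tn) / total with total = tp + fp + fn. With no truth
#' and no detections all scores are 1 (vacuously perfect); with truths but
#' no detections, precision is defined as 0.
#'
#' @param detected numeric vector of detected event times (s).
#' @param truth numeric vector of true event times (s).
#' @param tolerance matching tolerance in seconds (> 0).
#' @return list of class `detection_score` with counts and scores.
#' @export
detection_scores <- function(detected, truth, tolerance = 0.3) {
  if (!is.finite(tolerance) || tolerance <= 0) {
    stop("detection_scores: tolerance must be > 0", call. = FALSE)
  }
  pairs <- match_events(detected, truth, tolerance)
  tp <- nrow(pairs)
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  tn <- 0L
  total <- tp + fp + fn
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, total = total,
    sensitivity = if (tp + fn == 0L) 1 else tp / (tp + fn),
    precision = if (tp + fp == 0L) {
      if (total == 0L) 1 else 0
    } else tp / (tp + fp),
    accuracy = if (total == 0L) 1 else (tp + tn) / total
  ), class = "detection_score")
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf(paste0("<detection_score> tp=%d fp=%d fn=%d | ",
                     "sensitivity=%.3f precision=%.3f accuracy=%.3f\n"),
              x$tp, x$fp, x$fn, x$sensitivity, x$precision, x$accuracy))
  invisible(x)
}

#' Event timing error statistics
#'
#' Matches detected to true events within `tolerance` and summarizes the
#' signed errors detected - truth in ms (negative = early detection).
#'
#' @param detected,truth numeric vectors of event times (s).
#' @param tolerance matching tolerance in seconds.
#' @return list of class `error_stats` with `mean` (ms), `sd` (ms; 0 when
#'   only one pair) and `n`.
#' @export
event_error_stats <- function(detected, truth, tolerance = 0.3) {
  pairs <- match_events(detected, truth, tolerance)
  if (!nrow(pairs)) {
    stop("event_error_stats: no matched pairs", call. = FALSE)
  }
  err <- (pairs[, 1L] - pairs[, 2L]) * 1000
  structure(list(mean = mean(err),
                 sd = if (length(err) > 1L) stats::sd(err) else 0,
                 n = length(err), errors = err),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("<error_stats> %.1f +/- %.1f ms (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Phase-duration errors
#'
#' For each phase, the duration error is the estimated minus the true
#' duration (ms) and the relative error is that difference divided by the
#' true duration, in percent.
#'
#' @param est named numeric vector (or `lap_segmentation$durations`) of
#'   estimated phase durations in ms.
#' @param truth named numeric vector of true durations in ms (same names).
#' @return data.frame with columns `phase`, `est_ms`, `true_ms`, `error_ms`,
#'   `relative_pct` (NA with a warning entry when the true duration is 0).
#' @export
phase_duration_errors <- function(est, truth) {
  if (inherits(est, "lap_segmentation")) est <- est$durations
  common <- intersect(names(est), names(truth))
  if (!length(common)) {
    stop("phase_duration_errors: no common phase names", call. = FALSE)
  }
  err <- as.numeric(est[common]) - as.numeric(truth[common])
  rel <- ifelse(truth[common] == 0, NA_real_,
                err / as.numeric(truth[common]) * 100)
  data.frame(phase = common, est_ms = as.numeric(est[common]),
             true_ms = as.numeric(truth[common]), error_ms = err,
             relative_pct = rel, stringsAsFactors = FALSE)
}

#' Bland-Altman agreement
#'
#' Bias (mean difference) and 95% limits of agreement
#' (bias +/- 1.96 sd of the paired differences).
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return list with `bias`, `loa_low`, `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    stop("bland_altman: inputs must have equal length", call. = FALSE)
  }
  if (length(a) < 2L) {
    stop("bland_altman: need at least 2 pairs", call. = FALSE)
  }
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(d))
}

#' Threshold sensitivity sweep
#'
#' Reruns a detector pipeline with every numeric threshold perturbed by
#' `-pct` and `+pct` (default 10% in both directions) and tabulates the
#' change of each reported metric relative to the unperturbed run. A
#' pipeline failure under a perturbed threshold is recorded in the `status`
#' column, not raised.
#'
#' @param pipeline function `(session, truth, th) -> named numeric vector`
#'   of metrics.
#' @param session a [session_recording()].
#' @param truth a [ground_truth()] (passed through to `pipeline`).
#' @param th the baseline [threshold_set()].
#' @param pct relative perturbation (fraction).
#' @param fields threshold names to sweep; defaults to every numeric scalar
#'   field.
#' @return data.frame with one row per threshold and direction: `threshold`,
#'   `direction`, `value`, `status`, and one `delta_<metric>` column per
#'   metric.
#' @export
threshold_sensitivity <- function(pipeline, session, truth,
                                  th = threshold_set(), pct = 0.1,
                                  fields = NULL) {
  base <- pipeline(session, truth, th)
  if (is.null(fields)) fields <- sweepable_thresholds(th)
  rows <- list()
  for (f in fields) {
    for (dir in c(-1, 1)) {
      th2 <- th
      th2[[f]] <- th[[f]] * (1 + dir * pct)
      res <- tryCatch(pipeline(session, truth, th2),
                      error = function(e) e)
      if (inherits(res, "error")) {
        delta <- rep(NA_real_, length(base))
        status <- paste0("error: ", conditionMessage(res))
      } else {
        delta <- as.numeric(res[names(base)]) - as.numeric(base)
        status <- "ok"
      }
      row <- data.frame(threshold = f,
                        direction = if (dir < 0) "-" else "+",
                        value = th2[[f]], status = status,
                        stringsAsFactors = FALSE)
      for (k in seq_along(base)) {
        row[[paste0("delta_", names(base)[k])]] <- delta[k]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
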