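#' Run the full macro-micro analysis for one sensor location
#'
#' Detects bouts, approximate turns and per-lap technique (macro), then
#' segments every lap into its five phases (micro). Per-lap detector
#' failures are recorded in the lap's `status` field and the analysis
#' continues with the remaining laps. When ground truth is supplied the
#' report embeds validation metrics: bout/turn detection scores and
#' per-event error statistics.
#'
#' @param session a [session_recording()] in the anatomical frame.
#' @param location sensor location to analyze.
#' @param th a [threshold_set()].
#' @param truth optional [ground_truth()].
#' @param turn_types optional named override of turn types per bout index;
#'   default maps tumble to front crawl/backstroke and simple to
#'   breaststroke/butterfly.
#' @param anchor_location location whose macro outputs (bouts, approximate
#'   turns, technique) anchor the micro detectors; defaults to `location`.
#'   Useful for the wrists, whose own bout detection only starts with the
#'   first strokes and cannot anchor the first-lap push-off.
#' @return list of class `analysis_report`.
#' @export
run_full_analysis <- function(session, location = "SA",
                              th = threshold_set(), truth = NULL,
                              turn_types = NULL, anchor_location = NULL) {
  macro_loc <- if (is.null(anchor_location)) location else anchor_location
  bouts <- detect_bouts(session, macro_loc, th)
  report_bouts <- list()
  for (b in seq_len(nrow(bouts))) {
    bout <- bouts[b, ]
    turns <- detect_approximate_turn(session, bout, macro_loc, th)
    laps <- build_lap_contexts(bout, turns, techniques = "front_crawl")
    lap_entries <- list()
    for (i in seq_along(laps)) {
      lap <- laps[[i]]
      lap$technique <- tryCatch(
        identify_technique(session, lap, macro_loc, th),
        error = function(e) NA_character_)
      lap$turn_type <- if (!is.null(turn_types)) {
        rep_len(turn_types, length(laps))[i]
      } else if (is.na(lap$technique)) "tumble" else {
        default_turn_type(lap$technique)
      }
      laps[[i]] <- lap
      entry <- list(lap_index = i, technique = lap$technique,
                    turn_type = lap$turn_type, status = "ok",
                    events_ms = NULL, durations_ms = NULL)
      seg <- tryCatch(segment_lap(session, lap, location, th,
                                  turn_end = bout$approx_end),
                      error = function(e) e)
      if (inherits(seg, "error")) {
        entry$status <- conditionMessage(seg)
      } else {
        entry$events_ms <- as.list(round(seg$events * 1000))
        entry$durations_ms <- as.list(round(seg$durations))
      }
      lap_entries[[i]] <- entry
    }
    # turn phase of lap i ends at lap i+1's Push_B (bout end for the last)
    for (i in seq_along(lap_entries)) {
      e <- lap_entries[[i]]
      if (!identical(e$status, "ok")) next
      turn_end_ms <- if (i < length(lap_entries) &&
                         identical(lap_entries[[i + 1L]]$status, "ok")) {
        lap_entries[[i + 1L]]$events_ms$push_b
      } else {
        round(bout$approx_end * 1000)
      }
      e$durations_ms$turn <- turn_end_ms - e$events_ms$turn_b
      lap_entries[[i]] <- e
    }
    report_bouts[[b]] <- list(
      interval_ms = list(approx_start = round(bout$approx_start * 1000),
                         approx_end = round(bout$approx_end * 1000)),
      approximate_turns_ms = as.list(round(turns * 1000)),
      n_laps = length(lap_entries),
      laps = lap_entries)
  }

  report <- list(schema = "swimseg-report-1",
                 location = location,
                 software_version = as.character(
                   utils::packageVersion("swimseg")),
                 thresholds = unclass(th),
                 n_bouts = nrow(bouts),
                 bouts = report_bouts)

  if (!is.null(truth)) {
    report$validation <- validate_report(report, truth, th)
  }
  structure(report, class = "analysis_report")
}

# detected event times (s) of one event type across all ok laps
report_event_times <- function(report, event) {
  out <- numeric(0)
  for (b in report$bouts) {
    for (l in b$laps) {
      if (identical(l$status, "ok")) {
        out <- c(out, l$events_ms[[event]] / 1000)
      }
    }
  }
  sort(out)
}

report_techniques <- function(report) {
  unlist(lapply(report$bouts, function(b) {
    vapply(b$laps, function(l) {
      if (is.null(l$technique) || is.na(l$technique)) {
        NA_character_
      } else {
        l$technique
      }
    }, character(1))
  }))
}

validate_report <- function(report, truth, th) {
  tol <- th$tolerance_match
  bout_sc <- detection_scores(
    unlist(lapply(report$bouts, function(b) {
      b$interval_ms$approx_start / 1000
    })),
    truth$bouts$start, tolerance = max(tol, 0.5))
  turn_sc <- detection_scores(
    unlist(lapply(report$bouts, function(b) {
      unlist(b$approximate_turns_ms) / 1000
    })),
    truth$turns$time, tolerance = max(tol, 0.5))
  ev_stats <- list()
  for (event in c("push_b", "glid_b", "stpr_b", "swim_b", "turn_b")) {
    det <- report_event_times(report, event)
    tru <- truth$laps[[event]]
    st <- tryCatch(event_error_stats(det, tru, tolerance = tol),
                   error = function(e) NULL)
    if (!is.null(st)) {
      ev_stats[[event]] <- list(mean_ms = st$mean, sd_ms = st$sd, n = st$n)
    }
  }
  tech_det <- report_techniques(report)
  tech_acc <- if (length(tech_det) == nrow(truth$laps)) {
    mean(tech_det == truth$laps$technique, na.rm = FALSE)
  } else {
    NA_real_
  }
  list(bout_scores = unclass(bout_sc)[c("tp", "fp", "fn", "sensitivity",
                                        "precision", "accuracy")],
       turn_scores = unclass(turn_sc)[c("tp", "fp", "fn", "sensitivity",
                                        "precision", "accuracy")],
       technique_accuracy = tech_acc,
       event_errors = ev_stats)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s: %d bout(s)\n", x$location, x$n_bouts))
  for (b in seq_along(x$bouts)) {
    bt <- x$bouts[[b]]
    ok <- sum(vapply(bt$laps, function(l) identical(l$status, "ok"),
                     logical(1)))
    cat(sprintf("  bout %d: [%.1f, %.1f] s, %d lap(s) (%d segmented), %s\n",
                b, bt$interval_ms$approx_start / 1000,
                bt$interval_ms$approx_end / 1000, bt$n_laps, ok,
                paste(vapply(bt$laps, function(l) {
                  if (is.null(l$technique) || is.na(l$technique)) {
                    "?"
                  } else {
                    l$technique
                  }
                }, character(1)), collapse = "/")))
  }
  invisible(x)
}

#' Write an analysis report as canonical JSON
#'
#' All times are serialized in ms as integers, so reruns with identical
#' inputs produce byte-identical files.
#'
#' @param report an `analysis_report` from [run_full_analysis()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
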