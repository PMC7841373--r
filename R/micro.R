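#' @title Micro analysis: lap segmentation into five phases
#' @description Detects the beginning of wall push-off, glide, strokes
#'   preparation, swimming and turn within each lap, per sensor location
#'   and technique, anchored on the macro outputs.
#' @name micro_analysis
NULL

detection_error <- function(event, location, msg) {
  stop(structure(class = c("swimseg_detection_error", "error", "condition"),
                 list(message = sprintf("%s detection failed on %s: %s",
                                        event, location, msg),
                      call = NULL)))
}

ordering_error <- function(pair, values) {
  stop(structure(class = c("swimseg_order_error", "error", "condition"),
                 list(message = sprintf(
                   "phase events out of order: %s (%.3f s >= %.3f s)",
                   pair, values[1L], values[2L]), call = NULL)))
}

#' Build per-lap contexts from macro outputs
#'
#' Combines a bout interval, its approximate turns and per-lap metadata into
#' the lap context objects consumed by the micro detectors: lap `i` is
#' anchored at the bout's approximate start (first lap) or the preceding
#' approximate turn, and its turn anchor is the following approximate turn
#' (last lap: the bout's approximate end).
#'
#' @param bout one row of [detect_bouts()] output.
#' @param turns numeric vector of approximate turn times inside the bout.
#' @param techniques technique label(s), recycled over laps.
#' @param turn_types turn type(s) (`"simple"`/`"tumble"`); default derived
#'   from the technique.
#' @return list of lap-context lists with fields `lap_index`,
#'   `anchor_start`, `anchor_turn`, `is_last`, `technique`, `turn_type`,
#'   `bout`.
#' @export
build_lap_contexts <- function(bout, turns, techniques,
                               turn_types = NULL) {
  turns <- sort(turns)
  n_laps <- length(turns) + 1L
  techniques <- rep_len(techniques, n_laps)
  if (is.null(turn_types)) turn_types <- default_turn_type(techniques)
  turn_types <- rep_len(turn_types, n_laps)
  lapply(seq_len(n_laps), function(i) {
    list(lap_index = i,
         anchor_start = if (i == 1L) bout$approx_start else turns[i - 1L],
         anchor_turn = if (i < n_laps) turns[i] else bout$approx_end,
         is_last = i == n_laps,
         technique = techniques[i],
         turn_type = turn_types[i],
         bout = bout)
  })
}

# last sign change of v before index i_end (exclusive); NA when none
last_zero_crossing_before <- function(v, i_end) {
  if (i_end < 2L) return(NA_integer_)
  sgn <- sign(v[seq_len(i_end)])
  flips <- which(sgn[-1L] * sgn[-i_end] < 0)
  if (!length(flips)) NA_integer_ else flips[length(flips)] + 1L
}

#' Detect the beginning of wall push-off
#'
#' Anchored at the approximate start (first lap) or approximate turn
#' (subsequent laps). Sacrum: concavity change (last zero crossing of the
#' second derivative) of the longitudinal acceleration before the push peak;
#' backstroke uses the Acc_y peak directly. Head: |Acc| peak (Acc_y peak for
#' backstroke). Wrist: deepest Acc_y trough (downward hand motion). Shank:
#' |Gyr| peak of the leg extension.
#'
#' @param session,lap,location,th see [segment_lap()].
#' @return Push_B time in seconds.
#' @export
detect_push_begin <- function(session, lap, location = "SA",
                              th = threshold_set()) {
  require_anatomical(session, location)
  # the first lap's anchor is the posture change itself; searching before it
  # would reach back into the upright rest period
  w0 <- lap$anchor_start - if (lap$lap_index == 1L) 0 else th$push_window_pre
  w1 <- lap$anchor_start + th$push_window_post
  tech <- lap$technique

  if (location == "SA") {
    y <- session_channel_lp(session, location, "acc_y", th, w0, w1)
    dev <- y$values - stats::median(y$values)
    if (tech == "backstroke") {
      pk <- detect_extrema(y, stats::median(y$values) + 0.3, "peak")
      if (!nrow(pk)) detection_error("Push_B", location, "no Acc_y peak")
      return(pk$time[which.max(pk$amplitude)])
    }
    # the push peak is a genuine local maximum (the posture-change slope at
    # the window edge is not)
    pk <- detect_extrema(same_grid_ts(y, dev), 0.3, "peak")
    if (!nrow(pk)) {
      detection_error("Push_B", location, "no push peak on Acc_y")
    }
    i_pk <- ts_index(y, pk$time[which.max(pk$amplitude)])
    d2 <- ts_derivative(ts_derivative(y))$values
    i_cc <- last_zero_crossing_before(d2, i_pk)
    if (is.na(i_cc)) {
      detection_error("Push_B", location, "no concavity change before peak")
    }
    return(y$t0 + (i_cc - 1L) / y$fs)
  }

  if (location == "HE") {
    ch <- if (tech == "backstroke") "acc_y" else "acc_norm"
    s <- session_channel_lp(session, location, ch, th, w0, w1)
    pk <- detect_extrema(s, stats::median(s$values) + 0.3, "peak")
    if (!nrow(pk)) detection_error("Push_B", location, "no qualifying peak")
    if (lap$lap_index == 1L || tech == "backstroke") {
      return(pk$time[which.max(pk$amplitude)])
    }
    # after a turn the wall spike dominates the window: the push-off is the
    # first qualifying |Acc| peak following it
    i_max <- which.max(pk$amplitude)
    after <- pk$time > pk$time[i_max]
    if (!any(after)) {
      detection_error("Push_B", location, "no |Acc| peak after the turn")
    }
    return(pk$time[after][1L])
  }

  if (location %in% c("RW", "LW")) {
    s <- session_channel_lp(session, location, "acc_y", th, w0, w1)
    tr <- detect_extrema(s, stats::median(s$values) - 0.3, "trough")
    if (!nrow(tr)) detection_error("Push_B", location, "no Acc_y trough")
    return(tr$time[which.min(tr$amplitude)])
  }

  if (location %in% c("RS", "LS")) {
    s <- session_channel_lp(session, location, "gyr_norm", th, w0, w1)
    pk <- detect_extrema(s, 200, "peak")
    if (!nrow(pk)) detection_error("Push_B", location, "no |Gyr| peak")
    if (lap$lap_index == 1L) return(pk$time[1L])
    # after a turn the window also holds the turn spikes: the push is the
    # first qualifying peak after the dominant (wall) peak
    i_max <- which.max(pk$amplitude)
    after <- pk$time > pk$time[i_max]
    if (!any(after)) {
      detection_error("Push_B", location, "no |Gyr| peak after the turn")
    }
    return(pk$time[after][1L])
  }
  stop("detect_push_begin: unsupported location", call. = FALSE)
}

#' Detect the beginning of glide
#'
#' First qualifying extremum after Push_B: an Acc_y trough on sacrum/head,
#' the first |Gyr| peak on the shank, the first Acc_y peak on the wrist
#' (the wrist signal settles near zero while gliding).
#'
#' @param session,lap,location,th see [segment_lap()].
#' @param push_b detected Push_B time (s).
#' @return Glid_B time in seconds.
#' @export
detect_glide_begin <- function(session, lap, location = "SA",
                               th = threshold_set(), push_b) {
  require_anatomical(session, location)
  w0 <- push_b + th$event_guard
  w1 <- push_b + th$glide_window

  if (location %in% c("SA", "HE")) {
    s <- session_channel_lp(session, location, "acc_y", th, w0, w1)
    tr <- detect_extrema(s, th$th_glide_sahe, "trough")
    if (!nrow(tr)) detection_error("Glid_B", location, "no Acc_y trough")
    return(tr$time[1L])
  }
  if (location %in% c("RS", "LS")) {
    s <- session_channel_lp(session, location, "gyr_norm", th, w0, w1)
    pk <- detect_extrema(s, th$th_glide_rs, "peak")
    if (!nrow(pk)) detection_error("Glid_B", location, "no |Gyr| peak")
    return(pk$time[1L])
  }
  if (location %in% c("RW", "LW")) {
    s <- session_channel_lp(session, location, "acc_y", th, w0, w1)
    pk <- detect_extrema(s, th$th_glide_rw, "peak")
    if (!nrow(pk)) detection_error("Glid_B", location, "no Acc_y peak")
    return(pk$time[1L])
  }
  stop("detect_glide_begin: unsupported location", call. = FALSE)
}

# rolling standard deviation over +/- half s around each sample
rolling_sd <- function(v, fs, half = 0.25) {
  k <- max(2L, as.integer(half * fs))
  n <- length(v)
  cs <- cumsum(c(0, v))
  cs2 <- cumsum(c(0, v^2))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  m <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  m2 <- (cs2[hi + 1L] - cs2[lo]) / (hi - lo + 1L)
  sqrt(pmax(m2 - m^2, 0))
}

#' Detect the beginning of strokes preparation
#'
#' Sacrum: first anterior-acceleration extremum of the kick burst exceeding
#' `TH_SPSA` with a local-variability gate `TH_SPSAvar`. Head: first Acc_y
#' trough below `TH_SPHE` with prominence `TH_SPHEprom`. Wrist: first trough
#' of (|Acc| - 1 g) below `TH_SPRW` (near free-fall during the initial
#' sweep). Shank: first positive Acc_y peak (backstroke), otherwise the
#' first |Acc_x| kick extremum above `TH_SPRS` traced back to the adjacent
#' crossing of 1 g on |Acc| (the kick onset).
#'
#' @param session,lap,location,th see [segment_lap()].
#' @param glid_b detected Glid_B time (s).
#' @return StPr_B time in seconds.
#' @export
detect_stroke_prep_begin <- function(session, lap, location = "SA",
                                     th = threshold_set(), glid_b) {
  require_anatomical(session, location)
  w0 <- glid_b + th$event_guard
  w1 <- glid_b + th$stpr_window
  tech <- lap$technique

  if (location == "SA") {
    s <- session_channel_lp(session, location, "acc_x", th, w0, w1)
    dev <- same_grid_ts(s, s$values - stats::median(s$values))
    ext <- rbind(detect_extrema(dev, th$TH_SPSA, "peak"),
                 detect_extrema(dev, -th$TH_SPSA, "trough"))
    if (nrow(ext)) {
      rs <- rolling_sd(dev$values, dev$fs)
      idx <- ts_index(dev, ext$time)
      ext <- ext[rs[idx] >= th$TH_SPSAvar, , drop = FALSE]
    }
    if (!nrow(ext)) detection_error("StPr_B", location, "no qualifying burst")
    return(min(ext$time))
  }

  if (location == "HE") {
    s <- session_channel_lp(session, location, "acc_y", th, w0, w1)
    tr <- detect_extrema(s, th$TH_SPHE, "trough",
                         min_prominence = th$TH_SPHEprom)
    if (!nrow(tr)) detection_error("StPr_B", location, "no qualifying trough")
    return(tr$time[1L])
  }

  if (location %in% c("RW", "LW")) {
    s <- session_channel_lp(session, location, "acc_norm", th, w0, w1)
    off <- same_grid_ts(s, s$values - 1)
    tr <- detect_extrema(off, th$TH_SPRW, "trough")
    if (!nrow(tr)) detection_error("StPr_B", location, "no |Acc| drop")
    return(tr$time[1L])
  }

  if (location %in% c("RS", "LS")) {
    if (tech == "backstroke") {
      s <- session_channel_lp(session, location, "acc_y", th, w0, w1)
      pk <- detect_extrema(s, th$th_stpr_rs_bas, "peak")
      if (!nrow(pk)) detection_error("StPr_B", location, "no Acc_y peak")
      return(pk$time[1L])
    }
    ax <- session_channel_lp(session, location, "acc_x", th, w0, w1)
    absx <- same_grid_ts(ax, abs(ax$values))
    pk <- detect_extrema(absx, th$TH_SPRS, "peak")
    if (!nrow(pk)) detection_error("StPr_B", location, "no |Acc_x| kick peak")
    nrm <- session_channel_lp(session, location, "acc_norm", th, w0, w1)
    i_pk <- ts_index(nrm, pk$time[1L])
    below <- which(nrm$values[seq_len(i_pk)] <= 1)
    if (!length(below)) {
      detection_error("StPr_B", location, "no 1 g crossing before the kick")
    }
    i_cross <- min(below[length(below)] + 1L, i_pk)
    return(nrm$t0 + (i_cross - 1L) / nrm$fs)
  }
  stop("detect_stroke_prep_begin: unsupported location", call. = FALSE)
}

# first upward (or armed downward) crossing of a level; a window that
# starts already beyond the level (filter/EMD edge transients) does not
# count -- a genuine below-to-above transition is required
first_crossing <- function(ts, level, direction = c("up", "down"),
                           arm = FALSE, sustain = 0, from = NULL) {
  direction <- match.arg(direction)
  v <- if (direction == "up") ts$values else -ts$values
  lv <- if (direction == "up") level else -level
  # samples before `from` are transform context only (they absorb filter,
  # Hilbert and EMD edge artifacts), never crossing candidates
  i0 <- if (is.null(from)) 1L else max(1L, ts_index(ts, from))
  above <- v >= lv
  up <- which(diff(above) == 1L) + 1L
  up <- up[up >= i0]
  if (arm) {
    # require the signal to have been beyond the level before dropping
    first_above <- if (above[i0]) i0 else if (length(up)) up[1L] else NA
    if (is.na(first_above)) return(NA_integer_)
    down <- which(diff(above) == -1L) + 1L
    down <- down[down > first_above]
    return(if (length(down)) down[1L] else NA_integer_)
  }
  if (sustain > 0) {
    # envelope onsets must stay beyond the level (ringing transients do
    # not); a search range already beyond the level at its start counts as
    # an onset only if sustained (short preparation phases merge the onset
    # with the window edge)
    if (above[i0]) up <- c(i0, up)
    k <- max(1L, as.integer(sustain * ts$fs))
    ok <- vapply(up, function(i) {
      seg <- above[i:min(i + k, length(above))]
      mean(seg) >= 0.8
    }, logical(1))
    up <- up[ok]
  }
  if (length(up)) up[1L] else NA_integer_
}

crossing_time <- function(ts, i) ts$t0 + (i - 1L) / ts$fs

# the intrinsic mode carrying the stroke-band oscillation (the second mode
# on typical noisy recordings, where the first mode holds residual noise);
# selected by spectral dominance so the mode count cannot shift the rule.
# Detection error when EMD yields fewer than two modes.
stroke_mode_of <- function(sig, event, location, band = c(0.3, 1.5)) {
  dec <- emd(sig, max_imfs = 6L)
  if (length(dec$imfs) < 2L) {
    detection_error(event, location, "EMD produced fewer than 2 IMFs")
  }
  band_peak <- vapply(dec$imfs, function(m) {
    sp <- amplitude_spectrum(m, band = band)
    if (length(sp$amplitude)) max(sp$amplitude) else 0
  }, numeric(1))
  dec$imfs[[which.max(band_peak)]]
}

#' Detect the beginning of swimming
#'
#' Onset of the arm-cycle motion. Sacrum: first |Gyr_y| crossing of the
#' rolling threshold (front crawl/backstroke), instantaneous-energy crossing
#' of the 2nd IMF of Gyr_z (breaststroke), or the first 2nd-IMF Acc_y
#' crossing (butterfly). Head: instantaneous-energy crossings of Gyr_y/Gyr_z
#' (a decrease below threshold for backstroke). Wrists: the trough before
#' the first cycle peak, on Acc_y (front crawl/butterfly), Acc_x
#' (backstroke) or Gyr_y (breaststroke), taking the earliest of the two
#' wrists. Shank: the trough before the first 2nd-IMF cycle peak of Acc_x
#' (Acc_y for breaststroke).
#'
#' @param session,lap,location,th see [segment_lap()].
#' @param stpr_b detected StPr_B time (s).
#' @return Swim_B time in seconds.
#' @export
detect_swim_begin <- function(session, lap, location = "SA",
                              th = threshold_set(), stpr_b) {
  require_anatomical(session, location)
  w0 <- stpr_b + th$event_guard
  w1 <- stpr_b + th$swim_window
  tech <- lap$technique
  grab <- function(loc, ch) {
    session_channel_lp(session, loc, ch, th, w0, w1)
  }
  # EMD/Hilbert-based rules analyze a window extended 2 s to the left so
  # that decomposition edge artifacts fall outside the search range
  grab_ext <- function(loc, ch) {
    session_channel_lp(session, loc, ch, th, max(0, w0 - 2), w1)
  }

  if (location == "SA") {
    if (tech %in% c("front_crawl", "backstroke")) {
      s <- grab("SA", "gyr_y")
      i <- first_crossing(same_grid_ts(s, abs(s$values)), th$TH_SSA_FCBaS)
      if (is.na(i)) detection_error("Swim_B", location, "no rolling onset")
      return(crossing_time(s, i))
    }
    if (tech == "breaststroke") {
      e <- instantaneous_energy(stroke_mode_of(grab_ext("SA", "gyr_z"),
                                             "Swim_B", "SA"))
      i <- first_crossing(e, th$TH_SSA_BrS, sustain = 1, from = w0)
      if (is.na(i)) detection_error("Swim_B", location, "no energy rise")
      return(crossing_time(e, i))
    }
    m2 <- stroke_mode_of(grab_ext("SA", "acc_y"), "Swim_B", "SA")
    i <- first_crossing(m2, th$TH_SSA_BF, from = w0)
    if (is.na(i)) detection_error("Swim_B", location, "no undulation onset")
    return(crossing_time(m2, i))
  }

  if (location == "HE") {
    if (tech == "front_crawl") {
      e <- instantaneous_energy(grab_ext("HE", "gyr_y"))
      i <- first_crossing(e, th$TH_SHE_FC, sustain = 1, from = w0)
    } else if (tech == "backstroke") {
      e <- instantaneous_energy(grab_ext("HE", "gyr_z"))
      i <- first_crossing(e, th$TH_SHE_BaS, arm = TRUE, from = w0)
    } else {
      e <- instantaneous_energy(grab_ext("HE", "gyr_z"))
      i <- first_crossing(e, th$TH_SHE_BFBrS, sustain = 1, from = w0)
    }
    if (is.na(i)) detection_error("Swim_B", location, "no energy transition")
    return(crossing_time(e, i))
  }

  if (location %in% c("RW", "LW")) {
    wrists <- intersect(c("RW", "LW"), names(session$recordings))
    cand <- numeric(0)
    for (wloc in wrists) {
      res <- tryCatch({
        if (tech == "breaststroke") {
          s <- grab(wloc, "gyr_y")
          lim <- th$th_swim_wrist_gyr
        } else {
          s <- grab(wloc, if (tech == "backstroke") "acc_x" else "acc_y")
          s <- same_grid_ts(s, s$values - stats::median(s$values))
          lim <- th$th_swim_wrist_acc
        }
        pk <- detect_extrema(s, lim, "peak")
        if (!nrow(pk)) stop("no cycle peak")
        tr <- detect_extrema(s, Inf, "trough")  # all troughs
        tr <- tr[tr$time < pk$time[1L], , drop = FALSE]
        if (!nrow(tr)) stop("no trough before the first cycle peak")
        tr$time[nrow(tr)]
      }, error = function(e) NA_real_)
      cand <- c(cand, res)
    }
    cand <- cand[!is.na(cand)]
    if (!length(cand)) {
      detection_error("Swim_B", location, "no wrist cycle onset")
    }
    return(min(cand))
  }

  if (location %in% c("RS", "LS")) {
    ch <- if (tech == "breaststroke") "acc_y" else "acc_x"
    m2 <- stroke_mode_of(grab(location, ch), "Swim_B", location)
    pk <- detect_extrema(m2, th$TH_T_RS, "peak")
    if (!nrow(pk)) detection_error("Swim_B", location, "no 2nd-IMF peak")
    tr <- detect_extrema(m2, Inf, "trough")
    tr <- tr[tr$time < pk$time[1L], , drop = FALSE]
    if (!nrow(tr)) detection_error("Swim_B", location, "no preceding trough")
    return(tr$time[nrow(tr)])
  }
  stop("detect_swim_begin: unsupported location", call. = FALSE)
}

#' Detect the beginning of turn
#'
#' Backstroke inter-lap turns take the approximate turn directly. Otherwise:
#' sacrum reads the first trough before the large anterior-acceleration
#' peak; head the dominant |Acc| peak (tumble) or Gyr_x peak (simple)
#' shortly before the approximate turn; wrist the dominant Acc_y peak
#' (extra-smoothed for tumble turns); shank the first dominant Gyr_z
#' (tumble) or Acc_z (simple) peak around the approximate turn.
#'
#' @param session,lap,location,th see [segment_lap()].
#' @return Turn_B time in seconds.
#' @export
detect_turn_begin <- function(session, lap, location = "SA",
                              th = threshold_set()) {
  require_anatomical(session, location)
  anchor <- lap$anchor_turn
  tech <- lap$technique
  bas <- tech == "backstroke"
  if (bas && !lap$is_last) return(anchor)
  w0 <- anchor - th$turn_window_pre
  w1 <- anchor + th$turn_window_post

  if (location == "SA") {
    s <- session_channel_lp(session, location, "acc_x", th, w0, w1)
    dev <- same_grid_ts(s, s$values - stats::median(s$values))
    if (bas) {
      # final-lap backstroke: the wall spike itself marks the turn begin
      i <- which.max(abs(dev$values))
      return(dev$t0 + (i - 1L) / dev$fs)
    }
    pk <- detect_extrema(dev, 0.5, "peak")
    if (!nrow(pk)) detection_error("Turn_B", location, "no turn peak on Acc_x")
    t_pk <- pk$time[which.max(pk$amplitude)]
    tr <- detect_extrema(dev, Inf, "trough", min_prominence = th$th_turn_prom)
    tr <- tr[tr$time < t_pk, , drop = FALSE]
    if (!nrow(tr)) detection_error("Turn_B", location, "no preceding trough")
    return(tr$time[nrow(tr)])
  }

  if (location == "HE") {
    tumble <- lap$turn_type == "tumble"
    ch <- if (tumble) "acc_norm" else "gyr_x"
    w_end <- if (!tumble) anchor - th$event_guard
             else if (lap$is_last) anchor - 1 else anchor - 0.3
    s <- session_channel_lp(session, location, ch, th, w0, w_end)
    pk <- detect_extrema(s, -Inf, "peak")
    if (!nrow(pk)) detection_error("Turn_B", location, "no pre-turn peak")
    return(pk$time[which.max(pk$amplitude)])
  }

  if (location %in% c("RW", "LW")) {
    s <- session_channel_lp(session, location, "acc_y", th, w0, anchor - th$event_guard)
    if (lap$turn_type == "tumble") s <- lowpass(s, th$rw_turn_fc)
    pk <- detect_extrema(s, -Inf, "peak")
    if (!nrow(pk)) detection_error("Turn_B", location, "no pre-turn peak")
    return(pk$time[which.max(pk$amplitude)])
  }

  if (location %in% c("RS", "LS")) {
    ch <- if (lap$turn_type == "tumble") "gyr_z" else "acc_z"
    s <- session_channel_lp(session, location, ch, th, w0, anchor + 0.5)
    m <- max(s$values)
    pk <- detect_extrema(s, th$turn_rel_frac * m, "peak")
    if (!nrow(pk)) detection_error("Turn_B", location, "no turn peak")
    return(pk$time[1L])
  }
  stop("detect_turn_begin: unsupported location", call. = FALSE)
}

#' Segment one lap into its five phases
#'
#' Chains the five phase-begin detectors, enforces the ordering invariant
#' (Push_B < Glid_B < StPr_B < Swim_B < Turn_B) and derives the phase
#' durations in ms; the turn phase ends at `turn_end` (the next lap's
#' Push_B, or the bout's approximate end for the final lap).
#'
#' @param session a [session_recording()] in the anatomical frame.
#' @param lap a lap context from [build_lap_contexts()].
#' @param location sensor location to analyze.
#' @param th a [threshold_set()].
#' @param turn_end end of the turn phase (s); when `NULL` it is derived by
#'   detecting the next lap's Push_B (or using the bout's approximate end
#'   for the final lap).
#' @return list of class `lap_segmentation` with `events` (named times, s)
#'   and `durations` (named `push`, `glid`, `stpr`, `swim`, `turn` in ms).
#' @export
segment_lap <- function(session, lap, location = "SA", th = threshold_set(),
                        turn_end = NULL) {
  push_b <- detect_push_begin(session, lap, location, th)
  glid_b <- detect_glide_begin(session, lap, location, th, push_b)
  stpr_b <- detect_stroke_prep_begin(session, lap, location, th, glid_b)
  swim_b <- detect_swim_begin(session, lap, location, th, stpr_b)
  turn_b <- detect_turn_begin(session, lap, location, th)
  ev <- c(push_b = push_b, glid_b = glid_b, stpr_b = stpr_b,
          swim_b = swim_b, turn_b = turn_b)
  nm <- names(ev)
  for (i in seq_len(length(ev) - 1L)) {
    if (ev[i + 1L] <= ev[i]) {
      ordering_error(paste(nm[i], ">=", nm[i + 1L]), ev[c(i, i + 1L)])
    }
  }
  if (is.null(turn_end)) {
    turn_end <- if (lap$is_last) {
      lap$bout$approx_end
    } else {
      next_lap <- lap
      next_lap$lap_index <- lap$lap_index + 1L
      next_lap$anchor_start <- lap$anchor_turn
      detect_push_begin(session, next_lap, location, th)
    }
  }
  if (turn_end <= turn_b) {
    ordering_error("turn_b >= turn end", c(turn_b, turn_end))
  }
  durations <- c(push = glid_b - push_b, glid = stpr_b - glid_b,
                 stpr = swim_b - stpr_b, swim = turn_b - swim_b,
                 turn = turn_end - turn_b) * 1000
  structure(list(events = ev, durations = durations, location = location,
                 technique = lap$technique, turn_type = lap$turn_type,
                 lap_index = lap$lap_index),
            class = "lap_segmentation")
}

#' @export
print.lap_segmentation <- function(x, ...) {
  cat(sprintf("<lap_segmentation> lap %d (%s, %s turn) on %s\n",
              x$lap_index, x$technique, x$turn_type, x$location))
  cat("  events (s): ",
      paste(sprintf("%s=%.3f", names(x$events), x$events), collapse = ", "),
      "\n  durations (ms): ",
      paste(sprintf("%s=%.0f", names(x$durations), x$durations),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
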