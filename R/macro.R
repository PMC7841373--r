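#' @title Macro analysis: bouts, laps and technique
#' @description Detects swimming bouts (approximate start/end), the
#'   approximate turn separating laps, and the swimming technique of each
#'   lap, independently per sensor location.
#' @name macro_analysis
NULL

# pair alternating fall/rise sharp-change events into intervals; unpaired
# leading rises and trailing falls are discarded
pair_fall_rise <- function(events) {
  starts <- ends <- numeric(0)
  open <- NA_real_
  for (i in seq_len(nrow(events))) {
    if (events$polarity[i] == "fall") {
      if (is.na(open)) open <- events$time[i]    # extra falls while open: keep first
    } else if (!is.na(open)) {
      starts <- c(starts, open)
      ends <- c(ends, events$time[i])
      open <- NA_real_
    }
  }
  data.frame(approx_start = starts, approx_end = ends)
}

# contiguous TRUE runs of a logical vector as (from, to) sample indices
logical_runs <- function(flag) {
  r <- rle(flag)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  data.frame(from = lo[r$values], to = hi[r$values])
}

#' Detect swimming bouts
#'
#' Sacrum, head and shank: sharp-change detection on the longitudinal
#' acceleration (the abrupt posture change between upright rest and
#' horizontal swimming); derivative troughs are approximate starts, peaks
#' approximate ends, paired in temporal order. Right wrist: periods where
#' the 1-s envelope of |Acc| exceeds `TH_BW`, merged across within-bout
#' pauses, with the start refined to the onset of upper-limb cycling.
#'
#' @param session a [session_recording()] in the anatomical frame.
#' @param location one of `SA`, `HE`, `RS`, `RW` (also accepts `LS`/`LW`).
#' @param th a [threshold_set()].
#' @return data.frame with columns `approx_start`, `approx_end`,
#'   `source_location` (zero rows if nothing is detected).
#' @export
detect_bouts <- function(session, location = "SA", th = threshold_set()) {
  require_anatomical(session, location)
  if (location %in% c("SA", "HE", "RS", "LS")) {
    acc_y <- session_channel(session, location, "acc_y")
    ev <- detect_sharp_change(acc_y, th$fraction_B, fc = th$sc_fc,
                              order = th$filter_order)
    # a posture change has a minimal slope; noise-only sessions yield none
    ev <- ev[abs(ev$amplitude) >= th$sc_min_slope, , drop = FALSE]
    out <- pair_fall_rise(ev)
  } else if (location %in% c("RW", "LW")) {
    env <- envelope(session_channel(session, location, "acc_norm"),
                    window = 1)
    runs <- logical_runs(env$values > th$TH_BW)
    if (!nrow(runs)) {
      out <- data.frame(approx_start = numeric(0), approx_end = numeric(0))
    } else {
      from <- (runs$from - 1L) / env$fs
      to <- (runs$to - 1L) / env$fs
      # merge runs separated by within-bout pauses (turn + glide + kicks)
      ks <- kf <- numeric(0)
      cs <- from[1L]; ce <- to[1L]
      for (i in seq_len(nrow(runs))[-1L]) {
        if (from[i] - ce <= th$bout_merge_gap) {
          ce <- to[i]
        } else {
          ks <- c(ks, cs); kf <- c(kf, ce)
          cs <- from[i]; ce <- to[i]
        }
      }
      ks <- c(ks, cs); kf <- c(kf, ce)
      keep <- (kf - ks) >= th$min_bout_time
      ks <- ks[keep]; kf <- kf[keep]
      # refine each start to the first |Acc| crossing of the cycling level
      ks <- vapply(ks, function(t0) {
        w <- session_channel_lp(session, location, "acc_norm", th,
                                t0 - 2, t0 + 2)
        hit <- which(w$values > th$rw_bout_refine)
        if (length(hit)) w$t0 + (hit[1L] - 1L) / w$fs else t0
      }, numeric(1))
      out <- data.frame(approx_start = ks, approx_end = kf)
    }
  } else {
    stop("detect_bouts: unsupported location '", location, "'",
         call. = FALSE)
  }
  if (!nrow(out)) {
    return(data.frame(approx_start = numeric(0), approx_end = numeric(0),
                      source_location = character(0),
                      stringsAsFactors = FALSE))
  }
  out$source_location <- location
  out
}

# greedy selection of cluster representatives with a minimal separation
select_separated <- function(times, amps, min_sep) {
  keep <- logical(length(times))
  for (i in order(-amps)) {
    if (!any(keep & abs(times - times[i]) < min_sep)) keep[i] <- TRUE
  }
  sort(times[keep])
}

# a turn separates two laps: drop candidates too close to the bout edges
# (the final wall touch at the bout end is not an inter-lap turn)
inside_lap_guard <- function(times, amps, b0, b1, min_lap_time) {
  keep <- times >= b0 + 0.8 * min_lap_time & times <= b1 - 0.8 * min_lap_time
  list(times = times[keep], amps = amps[keep])
}

#' Detect the approximate turn(s) within a bout
#'
#' Sacrum/head: the dominant peaks of the (median-removed) anterior
#' acceleration and of |Acc_yz| within the bout; peaks above
#' `turn_peak_frac` of the bout maximum, separated by at least
#' `min_lap_time`, are accepted. Shank: extrema of Acc_z or Gyr_z above a
#' runtime threshold `TH_LS` (the highest peak in a 2-s reference window
#' during swimming), taking the earlier channel within each turn. Wrist:
#' midpoints of sustained drops of the smoothed |Gyr| below `TH_LW`
#' following continuous arm cycling.
#'
#' @param session a [session_recording()] in the anatomical frame.
#' @param bout one row of [detect_bouts()] output (or a list with
#'   `approx_start`, `approx_end`).
#' @param location one of `SA`, `HE`, `RS`, `RW`.
#' @param th a [threshold_set()].
#' @return numeric vector of approximate turn times (s), possibly empty.
#' @export
detect_approximate_turn <- function(session, bout, location = "SA",
                                    th = threshold_set()) {
  require_anatomical(session, location)
  b0 <- bout$approx_start
  b1 <- bout$approx_end
  if (b1 - b0 < th$min_lap_time) return(numeric(0))

  if (location %in% c("SA", "HE")) {
    cand_t <- cand_a <- numeric(0)
    for (ch in c("acc_x", "acc_norm_yz")) {
      sig <- session_channel_lp(session, location, ch, th, b0, b1)
      dev <- same_grid_ts(sig, sig$values - stats::median(sig$values))
      m <- max(abs(dev$values))
      if (m < 1e-9) next
      lim <- th$turn_peak_frac * m
      pk <- detect_extrema(dev, lim, "peak")
      tr <- detect_extrema(dev, -lim, "trough")
      cand_t <- c(cand_t, pk$time, tr$time)
      cand_a <- c(cand_a, abs(pk$amplitude), abs(tr$amplitude))
    }
    g <- inside_lap_guard(cand_t, cand_a, b0, b1, th$min_lap_time)
    if (!length(g$times)) return(numeric(0))
    return(select_separated(g$times, g$amps, th$min_lap_time))
  }

  if (location %in% c("RS", "LS")) {
    ref0 <- b0 + 0.3 * (b1 - b0) - th$ls_ref_window / 2
    cand_t <- cand_a <- numeric(0)
    for (ch in c("acc_z", "gyr_z")) {
      sig <- session_channel_lp(session, location, ch, th, b0, b1)
      ref <- ts_window(sig, ref0, ref0 + th$ls_ref_window)
      th_ls <- max(abs(ref$values))
      m <- max(abs(sig$values))
      lim <- max(th_ls, th$turn_peak_frac * m)
      pk <- detect_extrema(sig, lim, "peak")
      # relative amplitude so the two channels are comparable
      cand_t <- c(cand_t, pk$time)
      cand_a <- c(cand_a, pk$amplitude / max(m, 1e-9))
    }
    if (!length(cand_t)) return(numeric(0))
    # within each turn keep the earlier channel event: cluster, then earliest
    ord <- order(cand_t)
    cand_t <- cand_t[ord]; cand_a <- cand_a[ord]
    groups <- cumsum(c(TRUE, diff(cand_t) > 2))
    t_g <- vapply(split(cand_t, groups), function(x) x[1L], numeric(1))
    a_g <- vapply(split(cand_a, groups), max, numeric(1))
    g <- inside_lap_guard(t_g, a_g, b0, b1, th$min_lap_time)
    if (!length(g$times)) return(numeric(0))
    return(select_separated(g$times, g$amps, th$min_lap_time))
  }

  if (location %in% c("RW", "LW")) {
    g <- ts_window(session_channel(session, location, "gyr_norm"), b0, b1)
    sm <- same_grid_ts(g, moving_average(g$values, as.integer(g$fs)))
    low <- logical_runs(sm$values < th$TH_LW)
    if (!nrow(low)) return(numeric(0))
    out <- numeric(0)
    for (i in seq_len(nrow(low))) {
      t_from <- sm$t0 + (low$from[i] - 1L) / sm$fs
      t_to <- sm$t0 + (low$to[i] - 1L) / sm$fs
      if (t_to - t_from < th$rw_turn_min_gap) next
      if (t_from - b0 < 3 || b1 - t_to < 3) next      # bout edges, not turns
      pre <- ts_window(sm, t_from - 3, t_from - 0.5)
      if (mean(pre$values) <= th$TH_LW) next          # no sustained cycling before
      out <- c(out, (t_from + t_to) / 2)
    }
    return(select_separated(out, rep(1, length(out)), th$min_lap_time))
  }

  stop("detect_approximate_turn: unsupported location '", location, "'",
       call. = FALSE)
}

#' Identify the swimming technique of one lap
#'
#' Sacrum/head: PCA of the angular velocity separates pitching techniques
#' (breaststroke/butterfly, dominant mediolateral axis) from rolling ones
#' (front crawl/backstroke, dominant longitudinal axis); the gravity sign of
#' the anterior acceleration singles out backstroke; the spectral magnitude
#' of the stroke harmonic (anterior acceleration on sacrum, |Acc_xy| on
#' head) above `TH_StyleSA`/`TH_StyleHE` separates butterfly from
#' breaststroke. Shank: gravity sign plus PCA of angular velocity and the
#' kick frequency. Wrist: PCA of acceleration separates backstroke; low
#' |Acc| variance identifies front crawl, high mean |Acc| butterfly, else
#' breaststroke.
#'
#' The feature window covers `technique_window` seconds centered at
#' `technique_pos` of the lap span, which falls inside the swimming phase
#' for realistic phase durations.
#'
#' @param session a [session_recording()] in the anatomical frame.
#' @param lap a lap context (see [build_lap_contexts()]), or any list with
#'   `anchor_start` and `anchor_turn` times.
#' @param location one of `SA`, `HE`, `RS`, `RW`.
#' @param th a [threshold_set()].
#' @return one of `"front_crawl"`, `"breaststroke"`, `"butterfly"`,
#'   `"backstroke"`.
#' @export
identify_technique <- function(session, lap, location = "SA",
                               th = threshold_set()) {
  require_anatomical(session, location)
  a0 <- lap$anchor_start
  a1 <- lap$anchor_turn
  center <- a0 + th$technique_pos * (a1 - a0)
  w0 <- center - th$technique_window / 2
  w1 <- center + th$technique_window / 2
  if (w1 - w0 < 2 / th$stroke_freq_nom) {
    stop("identify_technique: window shorter than two stroke cycles",
         call. = FALSE)
  }
  grab <- function(ch) session_channel_lp(session, location, ch, th, w0, w1)

  if (location %in% c("SA", "HE")) {
    G <- cbind(grab("gyr_x")$values, grab("gyr_y")$values,
               grab("gyr_z")$values)
    pc1 <- principal_components(G)$components[, 1L]
    rolling <- abs(pc1[2L]) > abs(pc1[3L])
    if (rolling) {
      mx <- mean(grab("acc_x")$values)
      return(if (mx > 0) "backstroke" else "front_crawl")
    }
    sig <- if (location == "SA") grab("acc_x") else grab("acc_norm_xy")
    sp <- amplitude_spectrum(sig, band = th$stroke_band)
    peak <- if (length(sp$amplitude)) max(sp$amplitude) else 0
    lim <- if (location == "SA") th$TH_StyleSA else th$TH_StyleHE
    return(if (peak >= lim) "butterfly" else "breaststroke")
  }

  if (location %in% c("RS", "LS")) {
    if (mean(grab("acc_x")$values) > 0) return("backstroke")
    G <- cbind(grab("gyr_x")$values, grab("gyr_y")$values,
               grab("gyr_z")$values)
    pc1 <- principal_components(G)$components[, 1L]
    if (abs(pc1[2L]) > abs(pc1[3L])) return("breaststroke")
    sp <- amplitude_spectrum(grab("gyr_z"), band = c(0.5, 4))
    f_dom <- sp$frequencies[which.max(sp$amplitude)]
    return(if (f_dom >= th$rs_kick_freq_split) "front_crawl" else "butterfly")
  }

  if (location %in% c("RW", "LW")) {
    Aw <- cbind(grab("acc_x")$values, grab("acc_y")$values,
                grab("acc_z")$values)
    pc1 <- principal_components(Aw)$components[, 1L]
    if (abs(pc1[1L]) > max(abs(pc1[2L]), abs(pc1[3L]))) return("backstroke")
    nrm <- grab("acc_norm")$values
    if (stats::var(nrm) < th$TH_StyleWvar) return("front_crawl")
    if (mean(nrm) > th$TH_StyleWmean) return("butterfly")
    return("breaststroke")
  }

  stop("identify_technique: unsupported location '", location, "'",
       call. = FALSE)
}
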