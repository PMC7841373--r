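#' Configuration for the synthetic-session simulator
#'
#' Defines the structure and signal statistics of a simulated training
#' session: bouts, laps per bout, technique and turn type per bout, phase
#' duration distributions, stroke and kick frequencies, rest durations and
#' sensor noise. The default phase-duration statistics are the validated
#' true values of the method's study conditions: wall push-off 218 +/- 29 ms,
#' glide 880 +/- 476 ms, strokes preparation 2673 +/- 1268 ms, swimming
#' 12423 +/- 1905 ms, turn 1223 +/- 166 ms. Durations are sampled from a
#' normal distribution truncated at +/- 3 sd (and below at 20% of the mean,
#' so every duration stays positive).
#'
#' @param n_bouts number of swimming bouts.
#' @param laps_per_bout laps per bout (the study protocol used 2).
#' @param techniques character vector (recycled over bouts) of technique
#'   labels among `front_crawl`, `breaststroke`, `butterfly`, `backstroke`.
#' @param turn_types optional turn types per bout; defaults to the
#'   competition convention: tumble for front crawl/backstroke, simple for
#'   breaststroke/butterfly.
#' @param fs sampling rate in Hz.
#' @param phase_mean,phase_sd named vectors (`push`, `glid`, `stpr`, `swim`,
#'   `turn`) of phase-duration means and sds in ms.
#' @param stroke_freq arm-cycle frequency in Hz.
#' @param kick_freq underwater kick frequency in Hz.
#' @param rest_duration rest between bouts in s.
#' @param lead_in,tail upright rest before the first and after the last
#'   bout in s.
#' @param noise_sd_acc,noise_sd_gyr additive white-noise sd (g, deg/s).
#' @param shank_kick_amp amplitude (g) of the shank anterior-acceleration
#'   kick oscillation during strokes preparation.
#' @param locations sensor locations to synthesize.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_bouts = 4L,
                       laps_per_bout = 2L,
                       techniques = swim_techniques(),
                       turn_types = NULL,
                       fs = 500,
                       phase_mean = c(push = 218, glid = 880, stpr = 2673,
                                      swim = 12423, turn = 1223),
                       phase_sd = c(push = 29, glid = 476, stpr = 1268,
                                    swim = 1905, turn = 166),
                       stroke_freq = 0.6,
                       kick_freq = 2.5,
                       rest_duration = 30,
                       lead_in = 10,
                       tail = 10,
                       noise_sd_acc = 0.05,
                       noise_sd_gyr = 5,
                       shank_kick_amp = 1.6,
                       locations = sensor_locations()) {
  techniques <- rep_len(techniques, n_bouts)
  if (!all(techniques %in% swim_techniques())) {
    stop("sim_config: unknown technique label", call. = FALSE)
  }
  if (is.null(turn_types)) turn_types <- default_turn_type(techniques)
  turn_types <- rep_len(turn_types, n_bouts)
  if (!all(turn_types %in% c("simple", "tumble"))) {
    stop("sim_config: turn_types must be 'simple' or 'tumble'", call. = FALSE)
  }
  need <- c("push", "glid", "stpr", "swim", "turn")
  if (!all(need %in% names(phase_mean)) || !all(need %in% names(phase_sd))) {
    stop("sim_config: phase_mean/phase_sd need fields ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (fs <= 0) stop("sim_config: fs must be positive", call. = FALSE)
  lower <- pmax(phase_mean[need] - 3 * phase_sd[need], 0.2 * phase_mean[need])
  if (any(lower <= 0)) {
    stop("sim_config: phase durations must stay positive after truncation",
         call. = FALSE)
  }
  structure(list(n_bouts = as.integer(n_bouts),
                 laps_per_bout = as.integer(laps_per_bout),
                 techniques = techniques, turn_types = turn_types,
                 fs = fs, phase_mean = phase_mean[need],
                 phase_sd = phase_sd[need],
                 stroke_freq = stroke_freq, kick_freq = kick_freq,
                 rest_duration = rest_duration, lead_in = lead_in,
                 tail = tail, noise_sd_acc = noise_sd_acc,
                 noise_sd_gyr = noise_sd_gyr,
                 shank_kick_amp = shank_kick_amp,
                 locations = intersect(locations, sensor_locations())),
            class = "sim_config")
}

#' Default simulator configuration of the study conditions
#'
#' Four bouts of two laps covering the four main techniques once each, with
#' the validated phase-duration statistics (see [sim_config()]).
#'
#' @return a [sim_config()].
#' @export
default_study_config <- function() sim_config()

#' Default turn type for a technique
#'
#' Competition convention: flip (tumble) turns in front crawl and
#' backstroke, open (simple) turns in breaststroke and butterfly.
#'
#' @param technique character vector of technique labels.
#' @return character vector of `"tumble"`/`"simple"`.
#' @export
default_turn_type <- function(technique) {
  ifelse(technique %in% c("front_crawl", "backstroke"), "tumble", "simple")
}

# truncated-normal sampler: [max(mean - 3 sd, 0.2 mean), mean + 3 sd]
rtrunc_duration <- function(mean, sd) {
  lo <- max(mean - 3 * sd, 0.2 * mean)
  hi <- mean + 3 * sd
  for (i in 1:100) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# --- waveform helpers (operate on a value vector v over time grid t) --------

# raised-cosine bell of half-width w centered at c
add_bell <- function(v, t, fs, center, w, A) {
  i0 <- max(1L, ceiling((center - w) * fs) + 1L)
  i1 <- min(length(v), floor((center + w) * fs) + 1L)
  if (i1 < i0) return(v)
  idx <- i0:i1
  v[idx] <- v[idx] + A * 0.5 * (1 + cos(pi * (t[idx] - center) / w))
  v
}

# odd derivative-of-Gaussian transient: trough at c - sigma, peak at c + sigma,
# inflection (second-derivative zero crossing) exactly at c
add_dog <- function(v, t, fs, center, sigma, K) {
  i0 <- max(1L, ceiling((center - 5 * sigma) * fs) + 1L)
  i1 <- min(length(v), floor((center + 5 * sigma) * fs) + 1L)
  if (i1 < i0) return(v)
  idx <- i0:i1
  u <- (t[idx] - center) / sigma
  v[idx] <- v[idx] + K * u * exp(-u^2 / 2)
  v
}

# sinusoid on [from, to] with linear onset/offset ramps
add_sine <- function(v, t, fs, from, to, freq, A, phase = 0, ramp = 0) {
  i0 <- max(1L, ceiling(from * fs) + 1L)
  i1 <- min(length(v), floor(to * fs) + 1L)
  if (i1 < i0) return(v)
  idx <- i0:i1
  w <- rep(1, length(idx))
  if (ramp > 0) {
    w <- pmin(1, (t[idx] - from) / ramp) * pmin(1, (to - t[idx]) / ramp)
    w <- pmax(w, 0)
  }
  v[idx] <- v[idx] + A * w * sin(2 * pi * freq * (t[idx] - from) + phase)
  v
}

# smooth box indicator of [from, to] with logistic edges (time constant tau)
smooth_box <- function(t, from, to, tau = 0.08) {
  stats::plogis((t - from) / tau) - stats::plogis((t - to) / tau)
}

#' Simulate a multi-location IMU swimming session with exact ground truth
#'
#' Generates piecewise-smooth template signals (raised-cosine pulses and
#' amplitude-modulated sinusoids, plus white noise) that contain every
#' signature the macro and micro detectors key on -- posture-change level
#' shifts, push-off transients, glide quiescence, kick bursts, arm-cycle
#' oscillations, turn spikes -- each placed at the event time stamped into
#' the returned ground truth. This is a detector test-bed, not a
#' biomechanical simulation.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `session` (a [session_recording()]) and `truth`
#'   (a [ground_truth()]).
#' @export
simulate_session <- function(config = default_study_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  fs <- config$fs
  s <- config$stroke_freq
  k <- config$kick_freq

  # ---- sample the timeline --------------------------------------------------
  laps <- empty_truth_laps()
  bouts <- data.frame(start = numeric(0), end = numeric(0))
  turns <- data.frame(time = numeric(0), turn_type = character(0),
                      bout = integer(0), stringsAsFactors = FALSE)
  cursor <- config$lead_in
  for (b in seq_len(config$n_bouts)) {
    tech <- config$techniques[b]
    ttype <- config$turn_types[b]
    bout_start <- cursor
    for (l in seq_len(config$laps_per_bout)) {
      d <- vapply(names(config$phase_mean), function(ph) {
        rtrunc_duration(config$phase_mean[[ph]], config$phase_sd[[ph]])
      }, numeric(1)) / 1000
      push_b <- cursor
      glid_b <- push_b + d[["push"]]
      stpr_b <- glid_b + d[["glid"]]
      swim_b <- stpr_b + d[["stpr"]]
      turn_b <- swim_b + d[["swim"]]
      lap_end <- turn_b + d[["turn"]]
      wall <- if (tech == "backstroke") turn_b else turn_b + 0.75 * d[["turn"]]
      laps <- rbind(laps, data.frame(
        bout = b, lap = l, technique = tech, turn_type = ttype,
        push_b = push_b, glid_b = glid_b, stpr_b = stpr_b, swim_b = swim_b,
        turn_b = turn_b, lap_end = lap_end, stringsAsFactors = FALSE))
      attr(laps, paste0("wall_", nrow(laps))) <- wall
      if (l < config$laps_per_bout) {
        turns <- rbind(turns, data.frame(time = wall, turn_type = ttype,
                                         bout = b, stringsAsFactors = FALSE))
      }
      cursor <- lap_end
    }
    bouts <- rbind(bouts, data.frame(start = bout_start, end = cursor))
    cursor <- cursor + config$rest_duration
  }
  total <- max(cursor - config$rest_duration, config$lead_in) + config$tail
  n <- as.integer(ceiling(total * fs))
  t <- (seq_len(n) - 1L) / fs
  walls <- vapply(seq_len(nrow(laps)),
                  function(i) attr(laps, paste0("wall_", i)), numeric(1))

  # ---- per-location signal synthesis ---------------------------------------
  upright <- rep(1, n)
  for (b in seq_len(nrow(bouts))) {
    upright <- upright - smooth_box(t, bouts$start[b] - 0.35,
                                    bouts$end[b] + 0.35)
  }
  # direction of the gravity component on the anterior axis while swimming:
  # prone techniques read -1 g, supine backstroke +1 g
  dir_of <- function(tech) if (tech == "backstroke") +1 else -1
  horiz <- list()  # per-bout smooth indicator of "in the water, horizontal"
  for (b in seq_len(nrow(bouts))) {
    horiz[[b]] <- smooth_box(t, bouts$start[b] - 0.35, bouts$end[b] + 0.35)
  }

  base_acc <- function() {
    ax <- numeric(n)
    for (b in seq_len(nrow(bouts))) {
      ax <- ax + dir_of(config$techniques[b]) * horiz[[b]]
    }
    list(x = ax, y = upright + numeric(n), z = numeric(n))
  }

  recs <- list()
  for (loc in config$locations) {
    A <- base_acc()
    G <- list(x = numeric(n), y = numeric(n), z = numeric(n))
    side <- if (loc %in% c("LW", "LS")) "L" else "R"
    kind <- if (loc %in% c("RW", "LW")) "wrist"
            else if (loc %in% c("RS", "LS")) "shank"
            else loc

    for (i in seq_len(nrow(laps))) {
      lp <- laps[i, ]
      dirg <- dir_of(lp$technique)
      bas <- lp$technique == "backstroke"
      tech <- lp$technique
      wall <- walls[i]
      swim_end <- lp$turn_b

      if (kind == "SA") {
        if (bas) {
          A$y <- add_bell(A$y, t, fs, lp$push_b, 0.15, 0.9)
        } else {
          A$y <- add_dog(A$y, t, fs, lp$push_b, 0.06, 1.2)
        }
        A$y <- add_bell(A$y, t, fs, lp$glid_b, 0.15, -0.35)
        A$y <- add_sine(A$y, t, fs, lp$swim_b, swim_end, s,
                        if (tech == "butterfly") 0.35 else 0.04, ramp = 0.3)
        A$x <- add_bell(A$x, t, fs, lp$push_b + 0.1, 0.15, dirg * 0.8)
        A$x <- add_sine(A$x, t, fs, lp$stpr_b, lp$swim_b, k, dirg * 1.3)
        A$x <- add_sine(A$x, t, fs, lp$swim_b, swim_end, s,
                        if (tech == "butterfly") 0.4 else 0.05, ramp = 0.3)
        if (!bas) A$x <- add_bell(A$x, t, fs, lp$turn_b, 0.175, dirg * 1.2)
        A$x <- add_bell(A$x, t, fs, wall, 0.15, -dirg * 3.5)
        A$z <- add_bell(A$z, t, fs, wall, 0.15, 2.5)
        roll <- tech %in% c("front_crawl", "backstroke")
        G$y <- add_sine(G$y, t, fs, lp$swim_b, swim_end, s,
                        if (roll) 300 else 10, ramp = 0.2)
        # breaststroke pitching builds up over the first cycles, so the
        # energy-onset threshold is crossed near the true onset
        G$z <- add_sine(G$z, t, fs, lp$swim_b, swim_end, s,
                        if (roll) 10 else 250,
                        ramp = if (tech == "breaststroke") 3 else 0.2)
        if (!roll) {
          G$z <- add_sine(G$z, t, fs, lp$swim_b, swim_end, k, 60,
                          ramp = 0.2)
          # kick-transmitted pitch ripple during preparation keeps the EMD
          # mode allocation stable across window choices
          G$z <- add_sine(G$z, t, fs, lp$stpr_b, lp$swim_b, k, 15)
        }
        G$x <- add_sine(G$x, t, fs, lp$swim_b, swim_end, s, 10, ramp = 0.2)
      }

      if (kind == "HE") {
        if (bas) A$y <- add_bell(A$y, t, fs, lp$push_b, 0.15, 0.9)
        A$y <- add_bell(A$y, t, fs, lp$glid_b, 0.15, -0.35)
        # kick-synchronous head dips during strokes preparation
        jc <- lp$stpr_b + seq(0, lp$swim_b - lp$stpr_b - 0.12, by = 1 / k)
        for (cc in jc) A$y <- add_bell(A$y, t, fs, cc, 0.14, -0.65)
        A$x <- add_bell(A$x, t, fs, lp$push_b, 0.15, dirg * 1.5)
        A$x <- add_sine(A$x, t, fs, lp$swim_b, swim_end, s,
                        dirg * switch(tech, butterfly = 0.45,
                                      breaststroke = 0.08, 0.05),
                        ramp = 0.3)
        A$x <- add_bell(A$x, t, fs, wall, 0.15, -dirg * 3.0)
        A$z <- add_bell(A$z, t, fs, wall, 0.15, 2.5)
        if (lp$turn_type == "tumble") {
          A$z <- add_bell(A$z, t, fs, lp$turn_b, 0.15, 2.4)
        } else {
          G$x <- add_bell(G$x, t, fs, lp$turn_b, 0.15, 250)
        }
        G$y <- add_sine(G$y, t, fs, lp$swim_b, swim_end, s,
                        if (tech == "front_crawl") 300 else 10, ramp = 0.2)
        if (tech %in% c("breaststroke", "butterfly")) {
          G$z <- add_sine(G$z, t, fs, lp$swim_b, swim_end, s, 250, ramp = 1)
        } else if (bas) {
          G$z <- add_sine(G$z, t, fs, lp$stpr_b, lp$swim_b, k, 160)
        }
      }

      if (kind == "wrist") {
        # left arm starts half a cycle later in alternating techniques
        lag <- if (side == "L" &&
                   tech %in% c("front_crawl", "backstroke")) 1 / (2 * s) else 0
        swb <- lp$swim_b + lag
        A$y <- add_bell(A$y, t, fs, lp$push_b, 0.15, -0.8)
        A$y <- add_bell(A$y, t, fs, lp$glid_b, 0.12, 0.5)
        A$x <- add_bell(A$x, t, fs, lp$stpr_b, 0.25, -dirg * 1.0)  # free-fall dip
        lvl <- switch(tech, front_crawl = 0.85, butterfly = 1.0,
                      breaststroke = 0.0, backstroke = 0.6)
        if (lvl != 0) {
          A$x <- A$x + dirg * lvl * smooth_box(t, swb, swim_end, 0.15)
        }
        if (tech %in% c("front_crawl", "butterfly")) {
          A$y <- add_bell(A$y, t, fs, swb, 0.3, -0.6)
          A$y <- add_sine(A$y, t, fs, swb, swim_end, s, 0.8)
        } else if (bas) {
          A$x <- add_bell(A$x, t, fs, swb, 0.3, -0.6)
          A$x <- add_sine(A$x, t, fs, swb, swim_end, s, 0.85)
          A$y <- add_sine(A$y, t, fs, swb, swim_end, s, 0.1)
        } else { # breaststroke: lateral sweep modulates the norm
          A$z <- add_sine(A$z, t, fs, swb, swim_end, s, 1.5)
          A$y <- add_sine(A$y, t, fs, swb, swim_end, s, 0.1)
        }
        if (tech == "butterfly") {
          A$x <- add_sine(A$x, t, fs, swb, swim_end, s, dirg * 0.4)
        }
        A$y <- add_bell(A$y, t, fs, lp$turn_b, 0.15, 2.0)
        if (tech == "breaststroke") {
          G$y <- add_bell(G$y, t, fs, swb, 0.3, -300)
        }
        G$y <- add_sine(G$y, t, fs, swb, swim_end, s, 400)
      }

      if (kind == "shank") {
        G$x <- add_bell(G$x, t, fs, lp$push_b, 0.1, 300)
        G$x <- add_bell(G$x, t, fs, lp$glid_b, 0.15, 150)
        if (bas) A$y <- add_bell(A$y, t, fs, lp$stpr_b, 0.12, 0.8)
        kick_to <- if (tech %in% c("front_crawl", "backstroke"))
          swim_end else lp$swim_b
        A$x <- add_sine(A$x, t, fs, lp$stpr_b, kick_to, k,
                        dirg * config$shank_kick_amp)
        # slow swim-cycle component carrying the Swim_B trough/peak pattern
        ch_sw <- if (tech == "breaststroke") "y" else "x"
        i0 <- lp$swim_b - 1 / (4 * s)
        A[[ch_sw]] <- add_sine(A[[ch_sw]], t, fs, i0, swim_end, s, -2.4,
                               phase = pi / 2)   # -2.4*cos(.), trough at swim_b
        if (tech %in% c("breaststroke", "butterfly")) {
          A[[ch_sw]] <- add_sine(A[[ch_sw]], t, fs, lp$swim_b, swim_end, k,
                                 0.5)
        }
        # turns excite both channels; turn type decides which one the
        # micro detector reads
        G$z <- add_bell(G$z, t, fs, lp$turn_b, 0.15, 800)
        G$z <- add_bell(G$z, t, fs, wall, 0.15, 1000)
        A$z <- add_bell(A$z, t, fs, lp$turn_b, 0.12, 2.2)
        A$z <- add_bell(A$z, t, fs, wall, 0.15, 3.0)
        G$z <- add_sine(G$z, t, fs, lp$stpr_b, kick_to, k, 200)
        if (tech == "butterfly") {
          G$z <- add_sine(G$z, t, fs, lp$swim_b, swim_end, 2 * s, 250,
                          ramp = 0.2)
        }
        if (tech == "breaststroke") {
          G$y <- add_sine(G$y, t, fs, lp$swim_b, swim_end, s, 220, ramp = 0.2)
        }
      }
    }

    acc <- cbind(A$x, A$y, A$z) +
      matrix(stats::rnorm(3L * n, 0, config$noise_sd_acc), ncol = 3L)
    gyr <- cbind(G$x, G$y, G$z) +
      matrix(stats::rnorm(3L * n, 0, config$noise_sd_gyr), ncol = 3L)
    recs[[loc]] <- imu_recording(acc, gyr, fs = fs, location = loc,
                                 frame = "anatomical")
  }

  attr(laps, "names_wall") <- NULL
  truth_laps <- laps
  attributes(truth_laps) <- attributes(truth_laps)[c("names", "class",
                                                     "row.names")]
  list(session = session_recording(recs, swimmer_id = "simulated"),
       truth = ground_truth(bouts = bouts, turns = turns, laps = truth_laps))
}
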