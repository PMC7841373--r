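# shared fixtures: simulated sessions are cached so several test files can
# reuse them without re-synthesizing

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config, seed) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_session(config, seed = seed)
  }
  .sim_cache[[key]]
}

one_bout_sim <- function(tech, seed = 21) {
  cached_sim(paste0("bout1-", tech, "-", seed),
             sim_config(n_bouts = 1, techniques = tech), seed)
}

default_sim <- function(seed = 42) {
  cached_sim(paste0("default-", seed), default_study_config(), seed)
}

# SA macro pass -> list of lap contexts, each with its truth row attached
sa_lap_contexts <- function(sim, th = threshold_set()) {
  bouts <- detect_bouts(sim$session, "SA", th)
  out <- list()
  for (b in seq_len(nrow(bouts))) {
    turns <- detect_approximate_turn(sim$session, bouts[b, ], "SA", th)
    tl <- sim$truth$laps[sim$truth$laps$bout == b, ]
    laps <- build_lap_contexts(bouts[b, ], turns, tl$technique[1L])
    for (i in seq_along(laps)) {
      l <- laps[[i]]
      l$truth <- tl[i, ]
      out[[length(out) + 1L]] <- l
    }
  }
  out
}

# brute-force neighbor-comparison extremum scan (independent oracle)
brute_extrema_idx <- function(v, threshold, polarity) {
  s <- if (polarity == "peak") v else -v
  thr <- if (polarity == "peak") threshold else -threshold
  n <- length(v)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (i > 1L && i < n && s[i] > s[i - 1L] && s[i] > s[i + 1L] &&
        s[i] >= thr) {
      out <- c(out, i)
    }
  }
  out
}

expect_events_close <- function(detected, truth, tol_ms, label = "") {
  expect_equal(length(detected), length(truth), info = label)
  expect_true(all(abs(sort(detected) - sort(truth)) * 1000 <= tol_ms),
              info = sprintf("%s: errors %s ms, tol %s",
                             label,
                             paste(round((sort(detected) - sort(truth)) *
                                           1000), collapse = ","), tol_ms))
}
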