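th_default <- threshold_set()

test_that("sacrum bout detection brackets every bout and nothing else", {
  sim <- default_sim()
  b <- detect_bouts(sim$session, "SA", th_default)
  expect_equal(nrow(b), nrow(sim$truth$bouts))
  expect_true(all(abs(b$approx_start - sim$truth$bouts$start) < 0.5))
  expect_true(all(abs(b$approx_end - sim$truth$bouts$end) < 0.5))
  # intervals are ordered and disjoint
  expect_true(all(diff(as.vector(t(as.matrix(b[, 1:2])))) > 0))

  # head and shank use the same posture change
  for (loc in c("HE", "RS")) {
    bl <- detect_bouts(sim$session, loc, th_default)
    expect_equal(nrow(bl), nrow(sim$truth$bouts))
    expect_true(all(abs(bl$approx_start - sim$truth$bouts$start) < 0.5))
  }
})

test_that("an all-rest session yields no bouts", {
  rest <- cached_sim("rest", sim_config(n_bouts = 0, lead_in = 30), 5)
  expect_equal(nrow(detect_bouts(rest$session, "SA", th_default)), 0L)
  expect_equal(nrow(detect_bouts(rest$session, "RW", th_default)), 0L)
})

test_that("wrist bouts start at the first-lap swimming onset", {
  sim <- cached_sim("bouts3", sim_config(n_bouts = 3,
                                         techniques = c("front_crawl",
                                                        "breaststroke",
                                                        "butterfly")), 31)
  b <- detect_bouts(sim$session, "RW", th_default)
  expect_equal(nrow(b), 3L)
  first_swims <- sim$truth$laps$swim_b[sim$truth$laps$lap == 1]
  expect_true(all(abs(b$approx_start - first_swims) < 0.5))
})

test_that("bout detection commutes with time reversal (start/end roles swap)", {
  sim <- one_bout_sim("front_crawl")
  rec <- sim$session$recordings$SA
  n <- nrow(rec$acc)
  dur <- (n - 1) / rec$fs
  rev_session <- session_recording(list(
    SA = imu_recording(rec$acc[n:1, ], rec$gyr[n:1, ], fs = rec$fs,
                       location = "SA")))
  fwd <- detect_bouts(sim$session, "SA", th_default)
  bwd <- detect_bouts(rev_session, "SA", th_default)
  expect_equal(nrow(bwd), nrow(fwd))
  expect_equal(sort(dur - bwd$approx_end), sort(fwd$approx_start),
               tolerance = 0.05)
  expect_equal(sort(dur - bwd$approx_start), sort(fwd$approx_end),
               tolerance = 0.05)
})

test_that("approximate turns are found once per lap boundary, within tolerance", {
  sim <- default_sim()
  b <- detect_bouts(sim$session, "SA", th_default)
  for (i in seq_len(nrow(b))) {
    tu <- detect_approximate_turn(sim$session, b[i, ], "SA", th_default)
    expect_equal(length(tu), 1L)
    expect_lt(abs(tu - sim$truth$turns$time[i]), 0.5)
  }
  # one-to-one across the session: no duplicates, no misses
  all_turns <- unlist(lapply(seq_len(nrow(b)), function(i) {
    detect_approximate_turn(sim$session, b[i, ], "SA", th_default)
  }))
  sc <- detection_scores(all_turns, sim$truth$turns$time, tolerance = 0.5)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$precision, 1)
})

test_that("a single-lap bout has no turn", {
  sim <- cached_sim("onelap", sim_config(n_bouts = 1, laps_per_bout = 1,
                                         techniques = "front_crawl"), 12)
  b <- detect_bouts(sim$session, "SA", th_default)
  expect_equal(nrow(b), 1L)
  expect_length(detect_approximate_turn(sim$session, b[1, ], "SA",
                                        th_default), 0L)
})

test_that("wrist and shank turn detection locate the lap boundary region", {
  sim <- one_bout_sim("front_crawl")
  b <- detect_bouts(sim$session, "SA", th_default)
  tl <- sim$truth$laps

  # wrist: the low-|Gyr| interval midpoint falls in the arm-quiet span
  # between the first lap's turn begin and the second lap's swim begin
  tu_rw <- detect_approximate_turn(sim$session, b[1, ], "RW", th_default)
  expect_equal(length(tu_rw), 1L)
  expect_gt(tu_rw, tl$turn_b[1])
  expect_lt(tu_rw, tl$swim_b[2])

  # shank: runtime-threshold extrema select the turn complex
  tu_rs <- detect_approximate_turn(sim$session, b[1, ], "RS", th_default)
  expect_equal(length(tu_rs), 1L)
  expect_lt(abs(tu_rs - sim$truth$turns$time[1]), 1.5)
})

test_that("technique identification is correct on every location and technique", {
  sim <- default_sim()
  laps <- sa_lap_contexts(sim)
  for (loc in c("SA", "HE", "RS", "RW")) {
    got <- vapply(laps, function(l) {
      identify_technique(sim$session, l, loc, th_default)
    }, character(1))
    want <- vapply(laps, function(l) l$truth$technique, character(1))
    expect_equal(got, want, info = loc)
  }
})

test_that("technique labels are stable under sensor noise", {
  clean <- cached_sim("clean17",
                      sim_config(noise_sd_acc = 0, noise_sd_gyr = 0), 17)
  noisy <- cached_sim("noisy17", sim_config(), 17)
  for (sim in list(clean, noisy)) {
    laps <- sa_lap_contexts(sim)
    got <- vapply(laps, function(l) {
      identify_technique(sim$session, l, "SA", th_default)
    }, character(1))
    expect_equal(got, vapply(laps, function(l) l$truth$technique,
                             character(1)))
  }
})

test_that("the wrist mean-|Acc| rule labels a high-mean cyclic signal butterfly", {
  # direct rule application: mean |Acc| = 1.8 g (> 1.7 g), variance above
  # the front-crawl gate, no backstroke axis dominance
  fs <- 250
  n <- 20 * fs
  tt <- (seq_len(n) - 1) / fs
  acc <- cbind(-1.75 + 0.1 * sin(2 * pi * 0.6 * tt),
               1.0 * sin(2 * pi * 0.6 * tt + 1),
               0.02 * sin(2 * pi * 0.6 * tt))
  rec <- imu_recording(acc, matrix(0, n, 3), fs = fs, location = "RW")
  session <- session_recording(list(RW = rec))
  lap <- list(anchor_start = 2, anchor_turn = 18)
  expect_equal(identify_technique(session, lap, "RW", th_default),
               "butterfly")
})
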