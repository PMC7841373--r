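test_that("detection scores reproduce the definitional identities on all small count tables", {
  for (tp in 0:5) for (fp in 0:5) for (fn in 0:5) {
    truth <- c(seq_len(tp) * 10, 1000 + seq_len(fn) * 10)
    detected <- c(seq_len(tp) * 10 + 0.05, 2000 + seq_len(fp) * 10)
    sc <- detection_scores(detected, truth, tolerance = 0.3)
    expect_equal(sc$tp, tp)
    expect_equal(sc$fp, fp)
    expect_equal(sc$fn, fn)
    expect_equal(sc$tn, 0L)
    total <- tp + fp + fn
    expect_equal(sc$sensitivity, if (tp + fn == 0) 1 else tp / (tp + fn))
    expect_equal(sc$precision,
                 if (tp + fp == 0) (if (total == 0) 1 else 0)
                 else tp / (tp + fp))
    expect_equal(sc$accuracy, if (total == 0) 1 else tp / total)
  }
})

test_that("detection scores: worked example and vacuous cases", {
  truth <- seq_len(9) * 10
  detected <- c(truth + 0.01, 500)          # 9 matches + 1 spurious
  sc <- detection_scores(detected, truth, tolerance = 0.3)
  expect_equal(sc$sensitivity, 1.0)
  expect_equal(sc$precision, 0.9)
  expect_equal(sc$accuracy, 0.9)

  none <- detection_scores(numeric(0), seq_len(5), tolerance = 0.3)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$precision, 0)
  expect_equal(none$accuracy, 0)

  perfect <- detection_scores(1:4, 1:4 + 0.001, tolerance = 0.3)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$accuracy, 1)

  vac <- detection_scores(numeric(0), numeric(0), tolerance = 0.3)
  expect_equal(vac$sensitivity, 1)
  expect_equal(vac$precision, 1)
  expect_equal(vac$accuracy, 1)
})

test_that("detection scores swap sensitivity/precision when roles swap", {
  # (for nonempty lists; with zero detections precision is 0 by convention,
  # which intentionally breaks the symmetry in the vacuous corner)
  set.seed(5)
  for (rep in 1:50) {
    a <- sort(stats::runif(sample(1:8, 1), 0, 100))
    b <- sort(stats::runif(sample(1:8, 1), 0, 100))
    s1 <- detection_scores(a, b, tolerance = 1)
    s2 <- detection_scores(b, a, tolerance = 1)
    expect_equal(s1$tp, s2$tp)
    expect_equal(s1$fp, s2$fn)
    expect_equal(s1$sensitivity, s2$precision)
    expect_equal(s1$precision, s2$sensitivity)
  }
})

test_that("event error statistics are signed, in ms, with sample sd", {
  exact <- event_error_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(exact$mean, 0)
  expect_equal(exact$sd, 0)
  expect_equal(exact$n, 3L)

  st <- event_error_stats(c(0.99, 2.01), c(1, 2))
  expect_equal(st$mean, 0)
  expect_equal(st$sd, stats::sd(c(-10, 10)), tolerance = 1e-9)
  expect_equal(round(st$sd, 2), 14.14)

  early <- event_error_stats(c(0.95), c(1))
  expect_lt(early$mean, 0)              # early detection is negative

  expect_error(event_error_stats(c(1), c(50)), "no matched pairs")

  # determinism: identical inputs give identical results
  a <- stats::runif(10)
  expect_identical(event_error_stats(a + 0.01, a),
                   event_error_stats(a + 0.01, a))
})

test_that("phase duration errors follow the error and relative-error definitions", {
  r <- phase_duration_errors(c(push = 242), c(push = 218))
  expect_equal(r$error_ms, 24)
  expect_equal(round(r$relative_pct, 1), 11.0)

  r0 <- phase_duration_errors(c(push = 218), c(push = 218))
  expect_equal(r0$error_ms, 0)
  expect_equal(r0$relative_pct, 0)

  # the same absolute error is amplified on short phases
  short <- phase_duration_errors(c(push = 268), c(push = 218))
  long <- phase_duration_errors(c(swim = 12473), c(swim = 12423))
  expect_equal(round(short$relative_pct, 1), 22.9)
  expect_equal(round(long$relative_pct, 1), 0.4)

  z <- phase_duration_errors(c(push = 100), c(push = 0))
  expect_true(is.na(z$relative_pct))
})

test_that("Bland-Altman agreement: bias, limits, translation invariance", {
  a <- c(1, 2, 3, 4)
  ba <- bland_altman(a, a)
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), c(0, 0, 0))

  b2 <- bland_altman(c(0, 2), c(1, 1))     # differences -1, +1
  expect_equal(b2$bias, 0)
  expect_equal(b2$sd, sqrt(2))
  expect_equal(b2$loa_high, 1.96 * sqrt(2))
  expect_equal(b2$loa_low, -1.96 * sqrt(2))

  set.seed(2)
  x <- stats::rnorm(20)
  y <- stats::rnorm(20)
  base <- bland_altman(x, y)
  shifted <- bland_altman(x + 5, y)
  expect_equal(shifted$bias, base$bias + 5)
  expect_equal(shifted$loa_high - shifted$loa_low,
               base$loa_high - base$loa_low)

  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("threshold sensitivity sweeps every field in both directions", {
  th <- threshold_set()
  pipe <- function(session, truth, th) c(metric = th$TH_BW + th$TH_LW / 100)
  tab <- threshold_sensitivity(pipe, session = NULL, truth = NULL, th = th,
                               fields = c("TH_BW", "TH_LW", "TH_SPSA"))
  expect_equal(nrow(tab), 6L)
  expect_setequal(tab$direction, c("-", "+"))
  expect_equal(tab$delta_metric[tab$threshold == "TH_BW" &
                                  tab$direction == "+"], 0.16)
  expect_equal(tab$delta_metric[tab$threshold == "TH_SPSA"], c(0, 0))

  # pipeline failure under a perturbed value is a status row, not a crash
  pipe_bad <- function(session, truth, th) {
    if (th$TH_BW > 1.7) stop("boom")
    c(metric = 1)
  }
  tab2 <- threshold_sensitivity(pipe_bad, NULL, NULL, th,
                                fields = c("TH_BW"))
  expect_match(tab2$status[tab2$direction == "+"], "boom")
  expect_equal(tab2$status[tab2$direction == "-"], "ok")
})

test_that("a marginal head trough makes StPr_B sensitive to TH_SPHE only", {
  # head Acc_y with a first kick dip at -0.52 g (just beyond the -0.5 g
  # threshold) followed by deeper dips: +10% on TH_SPHE shifts the detected
  # strokes-preparation onset by a whole kick period
  fs <- 250
  n <- 30 * fs
  tt <- (seq_len(n) - 1) / fs
  bell <- function(c0, w, A) {
    out <- numeric(n)
    idx <- which(abs(tt - c0) <= w)
    out[idx] <- A * 0.5 * (1 + cos(pi * (tt[idx] - c0) / w))
    out
  }
  acc_y <- bell(10, 0.25, -0.53) + bell(10.5, 0.25, -0.8) +
    bell(11, 0.25, -0.8)
  rec <- imu_recording(cbind(-1, acc_y, 0), matrix(0, n, 3), fs = fs,
                       location = "HE")
  session <- session_recording(list(HE = rec))
  lap <- list(lap_index = 1L, technique = "front_crawl")
  pipe <- function(session, truth, th) {
    c(stpr = detect_stroke_prep_begin(session, lap, "HE", th, glid_b = 8))
  }
  tab <- threshold_sensitivity(pipe, session, NULL, threshold_set(),
                               fields = c("TH_SPHE", "TH_SPHEprom",
                                          "TH_SPSA", "TH_SPRS"))
  d_sphe <- tab$delta_stpr[tab$threshold == "TH_SPHE" & tab$direction == "+"]
  expect_gt(abs(d_sphe), 0.3)
  expect_equal(tab$delta_stpr[tab$threshold == "TH_SPSA"], c(0, 0))
  expect_equal(tab$delta_stpr[tab$threshold == "TH_SPRS"], c(0, 0))
})
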