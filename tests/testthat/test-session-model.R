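make_rec <- function(n = 1000, fs = 500, location = "SA",
                     frame = "anatomical", seed = 1) {
  set.seed(seed)
  imu_recording(matrix(stats::rnorm(3 * n), ncol = 3),
                matrix(stats::rnorm(3 * n, sd = 10), ncol = 3),
                fs = fs, location = location, frame = frame)
}

test_that("session CSV round-trip preserves samples and metadata", {
  dir <- withr::local_tempdir()
  session <- session_recording(list(SA = make_rec(seed = 1),
                                    RW = make_rec(location = "RW", seed = 2)))
  write_session(session, dir)
  back <- read_session(dir)
  expect_setequal(names(back$recordings), c("SA", "RW"))
  for (loc in c("SA", "RW")) {
    expect_equal(back$recordings[[loc]]$acc, session$recordings[[loc]]$acc,
                 tolerance = 1e-12)
    expect_equal(back$recordings[[loc]]$gyr, session$recordings[[loc]]$gyr,
                 tolerance = 1e-12)
    expect_equal(back$recordings[[loc]]$fs, 500)
  }
})

test_that("unit metadata is honored on read (m/s2 to g, rad/s to deg/s)", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "SA.csv")
  writeLines(c("# fs=100", "# units_acc=m/s2", "# units_gyr=rad/s",
               "# frame=anatomical",
               "t,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z",
               "0,9.81,0,-4.905,3.14159265358979,0,0",
               "0.01,0,19.62,0,0,1.5707963267949,0",
               "0.02,1,2,3,0.1,0.2,0.3"),
             path)
  s <- read_session(dir)
  acc <- s$recordings$SA$acc
  gyr <- s$recordings$SA$gyr
  expect_equal(acc[1, ], c(x = 1, y = 0, z = -0.5))
  expect_equal(acc[2, 2], 2, ignore_attr = TRUE)
  expect_equal(acc[3, ], c(x = 1, y = 2, z = 3) / 9.81)
  expect_equal(gyr[1, 1], 180, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(gyr[2, 2], 90, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("malformed session files raise format errors naming the field", {
  dir <- withr::local_tempdir()
  writeLines(c("# fs=100", "t,acc_x,acc_y,acc_z", "0,1,0,0"),
             file.path(dir, "SA.csv"))
  expect_error(read_session(dir), "gyr_x")
  expect_error(read_session(file.path(dir, "nope")), "not found")
})

test_that("session invariants: lengths, locations, frames", {
  expect_error(imu_recording(matrix(0, 10, 3), matrix(0, 9, 3), 500, "SA"),
               "equal length")
  expect_error(imu_recording(matrix(0, 10, 3), matrix(0, 10, 3), 500, "XX"),
               "unknown location")
  expect_error(session_recording(list(LS = make_rec(location = "LS"))),
               "at least one")
  # detectors refuse sensor-frame data
  s <- session_recording(list(SA = make_rec(frame = "sensor")))
  expect_error(detect_bouts(s, "SA"), "anatomical")
})

test_that("annotations round-trip through JSON and re-validate ordering", {
  gt <- ground_truth(
    bouts = data.frame(start = c(10, 60), end = c(45, 95)),
    turns = data.frame(time = c(27, 77), turn_type = c("tumble", "simple"),
                       bout = c(1L, 2L)),
    laps = data.frame(bout = c(1L, 1L), lap = c(1L, 2L),
                      technique = c("front_crawl", "front_crawl"),
                      turn_type = "tumble",
                      push_b = c(10, 28), glid_b = c(10.2, 28.2),
                      stpr_b = c(11, 29), swim_b = c(14, 32),
                      turn_b = c(26, 43), lap_end = c(27.5, 45)))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(gt, path)
  back <- read_annotations(path)
  expect_equal(back$bouts, gt$bouts)
  expect_equal(back$turns, gt$turns)
  expect_equal(back$laps, gt$laps)

  # ordering violation is rejected with the offending lap
  bad <- gt
  bad$laps$glid_b[2] <- bad$laps$push_b[2] - 1
  expect_error(validate_ground_truth(bad), "lap\\(s\\) 2")
  # ... also on read
  txt <- readLines(path)
  writeLines(gsub('"glid_b": 28.2', '"glid_b": 27.2', txt, fixed = TRUE),
             path)
  expect_error(read_annotations(path), "out of order")

  # empty ground truth is valid and round-trips
  empty <- ground_truth()
  p2 <- withr::local_tempfile(fileext = ".json")
  write_annotations(empty, p2)
  expect_equal(nrow(read_annotations(p2)$bouts), 0L)
})

test_that("functional calibration recovers a known sensor rotation", {
  fs <- 200
  n <- 3 * fs
  # anatomical-frame movements: standing (gravity on +y), squats (rotation
  # about +z)
  standing_acc <- cbind(0, rep(1, n), 0)
  squat_gyr <- cbind(0, 0, 60 + 40 * sin(2 * pi * 0.5 * (1:n) / fs))
  rot <- function(ax, ang) {
    c <- cos(ang); s <- sin(ang)
    switch(ax,
           x = matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, byrow = TRUE),
           y = matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, byrow = TRUE),
           z = matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, byrow = TRUE))
  }
  R_true <- rot("z", 0.4) %*% rot("x", -0.25) %*% rot("y", 0.7)
  to_sensor <- function(m) m %*% R_true           # rows v_A -> v_S = R^T v_A
  set.seed(8)
  standing <- imu_recording(to_sensor(standing_acc) +
                              matrix(stats::rnorm(3 * n, sd = 0.005), ncol = 3),
                            matrix(stats::rnorm(3 * n, sd = 0.5), ncol = 3),
                            fs = fs, location = "SA", frame = "sensor")
  squat <- imu_recording(to_sensor(standing_acc),
                         to_sensor(squat_gyr) +
                           matrix(stats::rnorm(3 * n, sd = 0.5), ncol = 3),
                         fs = fs, location = "SA", frame = "sensor")
  R_est <- estimate_calibration(standing, squat)
  # each estimated anatomical axis within 2 degrees of the true one
  for (k in 1:3) {
    cosang <- sum(R_est[k, ] * R_true[k, ])
    expect_gt(cosang, cos(2 * pi / 180))
  }
  expect_equal(det(R_est), 1, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(R_est) - diag(3))), 1e-9)

  # aligned sensor -> identity
  id_standing <- imu_recording(standing_acc +
                                 matrix(stats::rnorm(3 * n, sd = 0.004),
                                        ncol = 3),
                               matrix(0, n, 3), fs = fs, location = "SA",
                               frame = "sensor")
  id_squat <- imu_recording(standing_acc, squat_gyr, fs = fs,
                            location = "SA", frame = "sensor")
  R_id <- estimate_calibration(id_standing, id_squat)
  expect_lt(max(abs(R_id - diag(3))), 0.02)

  # a non-static standing segment is rejected
  shaky <- imu_recording(standing_acc +
                           matrix(stats::rnorm(3 * n, sd = 0.2), ncol = 3),
                         matrix(0, n, 3), fs = fs, location = "SA",
                         frame = "sensor")
  expect_error(estimate_calibration(shaky, id_squat), "not static")
})

test_that("applying a calibration preserves norms and is invertible", {
  n <- 500
  rec <- make_rec(n = n, frame = "sensor", seed = 4)
  theta <- 0.6
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, byrow = TRUE)
  cal <- calibration_transform(list(SA = R))
  s <- session_recording(list(SA = rec))
  rotated <- apply_calibration(s, cal)
  expect_equal(rotated$recordings$SA$frame, "anatomical")
  expect_equal(sqrt(rowSums(rotated$recordings$SA$acc^2)),
               sqrt(rowSums(rec$acc^2)), tolerance = 1e-9)

  # identity leaves data unchanged
  ident <- apply_calibration(s, calibration_transform(list(SA = diag(3))))
  expect_equal(ident$recordings$SA$acc, rec$acc, ignore_attr = TRUE)

  # rotating back with the transposed rotation restores the input
  undone <- apply_calibration(
    session_recording(list(SA = imu_recording(rotated$recordings$SA$acc,
                                              rotated$recordings$SA$gyr,
                                              fs = rec$fs, location = "SA",
                                              frame = "sensor"))),
    calibration_transform(list(SA = t(R))))
  expect_equal(undone$recordings$SA$acc, rec$acc, tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(apply_calibration(s, calibration_transform(list(HE = R))),
               "no transform")
  expect_error(calibration_transform(list(SA = matrix(1, 3, 3))),
               "not a proper rotation")
})
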