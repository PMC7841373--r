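#' Sensor locations
#'
#' The six body locations carrying an IMU: sacrum (SA), head (HE), right and
#' left wrist (RW/LW), right and left shank (RS/LS).
#'
#' @return character vector of the six location codes.
#' @export
sensor_locations <- function() c("SA", "HE", "RW", "LW", "RS", "LS")

#' Single-location IMU recording
#'
#' Holds synchronized 3D accelerometer (g) and gyroscope (deg/s) data for one
#' sensor. Axes follow the anatomical convention: x anterior-posterior
#' (forward), y longitudinal (up), z mediolateral (right). Data loaded in the
#' raw sensor frame carry `frame = "sensor"` and must be calibrated before
#' analysis.
#'
#' @param acc N x 3 numeric matrix of acceleration in g (columns x, y, z).
#' @param gyr N x 3 numeric matrix of angular velocity in deg/s.
#' @param fs sampling rate in Hz (default 500).
#' @param location one of [sensor_locations()].
#' @param frame `"anatomical"` or `"sensor"`.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(acc, gyr, fs = 500, location,
                          frame = c("anatomical", "sensor")) {
  frame <- match.arg(frame)
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  if (ncol(acc) != 3L || ncol(gyr) != 3L) {
    stop("imu_recording: acc and gyr must have 3 columns (x, y, z)",
         call. = FALSE)
  }
  if (nrow(acc) != nrow(gyr)) {
    stop("imu_recording: acc and gyr must have equal length", call. = FALSE)
  }
  if (!location %in% sensor_locations()) {
    stop("imu_recording: unknown location '", location, "'", call. = FALSE)
  }
  if (!is.finite(fs) || fs <= 0) {
    stop("imu_recording: fs must be positive", call. = FALSE)
  }
  if (!all(is.finite(acc)) || !all(is.finite(gyr))) {
    stop("imu_recording: non-finite samples", call. = FALSE)
  }
  colnames(acc) <- colnames(gyr) <- c("x", "y", "z")
  structure(list(acc = acc, gyr = gyr, fs = as.numeric(fs),
                 location = location, frame = frame),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s, %d samples @ %g Hz (%.1f s), frame=%s\n",
              x$location, nrow(x$acc), x$fs, nrow(x$acc) / x$fs, x$frame))
  invisible(x)
}

#' Whole-session multi-location recording
#'
#' @param recordings named list of [imu_recording()] objects keyed by
#'   location; all must share the sampling rate and length, and at least one
#'   of SA, HE, RW, RS must be present.
#' @param pool_length pool length in meters (default 25).
#' @param swimmer_id free-text identifier.
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(recordings, pool_length = 25, swimmer_id = "") {
  if (!length(recordings)) {
    stop("session_recording: no recordings", call. = FALSE)
  }
  locs <- names(recordings)
  if (is.null(locs) || !all(locs %in% sensor_locations())) {
    stop("session_recording: recordings must be named by location",
         call. = FALSE)
  }
  if (!any(c("SA", "HE", "RW", "RS") %in% locs)) {
    stop("session_recording: need at least one of SA, HE, RW, RS",
         call. = FALSE)
  }
  fs <- vapply(recordings, function(r) r$fs, numeric(1))
  n <- vapply(recordings, function(r) nrow(r$acc), numeric(1))
  if (length(unique(fs)) != 1L || length(unique(n)) != 1L) {
    stop("session_recording: all locations must share fs and length",
         call. = FALSE)
  }
  structure(list(recordings = recordings, pool_length = pool_length,
                 swimmer_id = swimmer_id, fs = fs[[1L]]),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s: %s; %.1f s @ %g Hz, pool %g m\n",
              if (nzchar(x$swimmer_id)) x$swimmer_id else "(unnamed)",
              paste(names(x$recordings), collapse = ", "),
              nrow(x$recordings[[1L]]$acc) / x$fs, x$fs, x$pool_length))
  invisible(x)
}

session_duration <- function(session) {
  nrow(session$recordings[[1L]]$acc) / session$fs
}

# channel accessors -----------------------------------------------------------

has_location <- function(session, location) {
  location %in% names(session$recordings)
}

get_recording <- function(session, location) {
  if (!has_location(session, location)) {
    stop("session has no recording for location '", location, "'",
         call. = FALSE)
  }
  session$recordings[[location]]
}

require_anatomical <- function(session, location) {
  rec <- get_recording(session, location)
  if (!identical(rec$frame, "anatomical")) {
    stop("detector requires anatomical-frame data for '", location,
         "'; run apply_calibration() first", call. = FALSE)
  }
  rec
}

#' Extract one channel (or norm) of a session as a time series
#'
#' `channel` is one of `acc_x|acc_y|acc_z|gyr_x|gyr_y|gyr_z` or a norm
#' `acc_norm`, `gyr_norm`, `acc_norm_xy`, `acc_norm_yz`.
#'
#' @param session a [session_recording()].
#' @param location a sensor location code.
#' @param channel channel name (see Details).
#' @return a [swim_ts()] starting at t = 0.
#' @export
session_channel <- function(session, location, channel) {
  rec <- get_recording(session, location)
  v <- switch(channel,
    acc_x = rec$acc[, 1L], acc_y = rec$acc[, 2L], acc_z = rec$acc[, 3L],
    gyr_x = rec$gyr[, 1L], gyr_y = rec$gyr[, 2L], gyr_z = rec$gyr[, 3L],
    acc_norm = sqrt(rowSums(rec$acc^2)),
    gyr_norm = sqrt(rowSums(rec$gyr^2)),
    acc_norm_xy = sqrt(rec$acc[, 1L]^2 + rec$acc[, 2L]^2),
    acc_norm_yz = sqrt(rec$acc[, 2L]^2 + rec$acc[, 3L]^2),
    stop("unknown channel '", channel, "'", call. = FALSE))
  swim_ts(v, fs = rec$fs, t0 = 0)
}

# low-passed channel; norms are computed after per-axis filtering so that a
# noise floor does not bias the norm near zero. `from`/`to` (s) restrict the
# filtering to the window of interest (with a 2-s padding against filter
# edge effects) so that short-window detectors stay cheap
session_channel_lp <- function(session, location, channel, th,
                               from = NULL, to = NULL) {
  rec <- get_recording(session, location)
  n_all <- nrow(rec$acc)
  if (!is.null(from) || !is.null(to)) {
    pad <- 2
    i0 <- max(1L, as.integer(floor(((if (is.null(from)) 0 else from) - pad) *
                                     rec$fs)) + 1L)
    i1 <- min(n_all, as.integer(ceiling(((if (is.null(to)) n_all / rec$fs
                                          else to) + pad) * rec$fs)) + 1L)
    rng <- i0:i1
    t0 <- (i0 - 1L) / rec$fs
  } else {
    rng <- seq_len(n_all)
    t0 <- 0
  }
  lp <- function(v) {
    bf <- signal::butter(th$filter_order, th$filter_fc / (rec$fs / 2), "low")
    filtfilt_padded(bf, v[rng], rec$fs, th$filter_fc)
  }
  v <- switch(channel,
    acc_x = lp(rec$acc[, 1L]), acc_y = lp(rec$acc[, 2L]),
    acc_z = lp(rec$acc[, 3L]),
    gyr_x = lp(rec$gyr[, 1L]), gyr_y = lp(rec$gyr[, 2L]),
    gyr_z = lp(rec$gyr[, 3L]),
    acc_norm = sqrt(lp(rec$acc[, 1L])^2 + lp(rec$acc[, 2L])^2 +
                      lp(rec$acc[, 3L])^2),
    gyr_norm = sqrt(lp(rec$gyr[, 1L])^2 + lp(rec$gyr[, 2L])^2 +
                      lp(rec$gyr[, 3L])^2),
    acc_norm_xy = sqrt(lp(rec$acc[, 1L])^2 + lp(rec$acc[, 2L])^2),
    acc_norm_yz = sqrt(lp(rec$acc[, 2L])^2 + lp(rec$acc[, 3L])^2),
    stop("unknown channel '", channel, "'", call. = FALSE))
  out <- swim_ts(v, fs = rec$fs, t0 = t0)
  if (!is.null(from) || !is.null(to)) {
    out <- ts_window(out, if (is.null(from)) t0 else from,
                     if (is.null(to)) t0 + (length(v) - 1L) / rec$fs else to)
  }
  out
}

# session CSV I/O --------------------------------------------------------------

#' Write a session as per-location CSV files
#'
#' One file `<LOC>.csv` per location with columns
#' `t,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z` and comment headers
#' `# fs=`, `# units_acc=`, `# units_gyr=`, `# frame=`.
#'
#' @param session a [session_recording()].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (loc in names(session$recordings)) {
    rec <- session$recordings[[loc]]
    path <- file.path(dir, paste0(loc, ".csv"))
    con <- file(path, "w")
    writeLines(c(sprintf("# fs=%.10g", rec$fs),
                 "# units_acc=g", "# units_gyr=dps",
                 paste0("# frame=", rec$frame)), con)
    tt <- (seq_len(nrow(rec$acc)) - 1L) / rec$fs
    df <- data.frame(t = tt,
                     acc_x = rec$acc[, 1L], acc_y = rec$acc[, 2L],
                     acc_z = rec$acc[, 3L],
                     gyr_x = rec$gyr[, 1L], gyr_y = rec$gyr[, 2L],
                     gyr_z = rec$gyr[, 3L])
    utils::write.table(format(df, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

parse_csv_header <- function(path) {
  meta <- list(fs = NA_real_, units_acc = "g", units_gyr = "dps",
               frame = "anatomical")
  lines <- readLines(path, n = 16L)
  for (ln in lines[startsWith(lines, "#")]) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) {
      key <- trimws(kv[1L]); val <- trimws(kv[2L])
      if (key == "fs") meta$fs <- as.numeric(val) else meta[[key]] <- val
    }
  }
  meta
}

#' Read a session from a directory of per-location CSV files
#'
#' Reads every `<LOC>.csv` matching a known location code. Unit metadata in
#' the comment header is honored: acceleration in `m/s2` is converted to g
#' (divided by 9.81) and angular velocity in `rad/s` to deg/s.
#'
#' @param path directory containing the CSV files.
#' @param pool_length,swimmer_id passed to [session_recording()].
#' @return a validated [session_recording()].
#' @export
read_session <- function(path, pool_length = 25, swimmer_id = "") {
  if (!dir.exists(path)) {
    stop("read_session: directory not found: ", path, call. = FALSE)
  }
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  locs <- toupper(sub("\\.csv$", "", basename(files)))
  keep <- locs %in% sensor_locations()
  if (!any(keep)) {
    stop("read_session: no per-location CSV files (SA.csv, HE.csv, ...) in ",
         path, call. = FALSE)
  }
  recs <- list()
  for (k in which(keep)) {
    meta <- parse_csv_header(files[k])
    df <- utils::read.csv(files[k], comment.char = "#")
    need <- c("t", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(sprintf("read_session: %s is missing column(s): %s",
                   basename(files[k]), paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    fs <- meta$fs
    if (!is.finite(fs)) {
      dt <- stats::median(diff(df$t))
      if (!is.finite(dt) || dt <= 0) {
        stop("read_session: cannot determine fs for ", basename(files[k]),
             call. = FALSE)
      }
      fs <- 1 / dt
    }
    acc <- as.matrix(df[, c("acc_x", "acc_y", "acc_z")])
    gyr <- as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")])
    if (identical(meta$units_acc, "m/s2")) acc <- acc / 9.81
    if (identical(meta$units_gyr, "rad/s")) gyr <- gyr * 180 / pi
    frame <- if (identical(meta$frame, "sensor")) "sensor" else "anatomical"
    recs[[locs[k]]] <- imu_recording(acc, gyr, fs = fs, location = locs[k],
                                     frame = frame)
  }
  session_recording(recs, pool_length = pool_length, swimmer_id = swimmer_id)
}
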