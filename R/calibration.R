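#' Sensor-to-anatomical calibration transform
#'
#' One rotation matrix per location mapping sensor-frame vectors into the
#' anatomical frame (y longitudinal up, x anterior-posterior forward,
#' z mediolateral right).
#'
#' @param rotations named list of orthonormal 3 x 3 matrices (det = +1)
#'   keyed by location.
#' @return an object of class `calibration_transform`.
#' @export
calibration_transform <- function(rotations) {
  for (loc in names(rotations)) {
    R <- rotations[[loc]]
    if (!is.matrix(R) || any(dim(R) != 3L)) {
      stop("calibration_transform: rotation for ", loc, " must be 3 x 3",
           call. = FALSE)
    }
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0) {
      stop("calibration_transform: rotation for ", loc,
           " is not a proper rotation", call. = FALSE)
    }
  }
  structure(list(rotations = rotations), class = "calibration_transform")
}

normalize3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Estimate a simplified functional calibration
#'
#' Recovers the sensor-to-anatomical rotation for one sensor from three
#' short functional movements performed on land: quiet upright standing
#' (gravity defines the longitudinal axis y), squats (for trunk/shank
#' sensors) or arm rotation (for wrist sensors) whose dominant rotation axis
#' defines the mediolateral axis z, with x completing the right-handed
#' triad. This is a simplified stand-in for a full functional calibration
#' protocol; sessions recorded directly in the anatomical frame can skip it.
#'
#' @param standing an [imu_recording()] segment of quiet upright standing
#'   (>= 2 s, quasi-static).
#' @param squat an [imu_recording()] segment of squats (or any rotation
#'   about the mediolateral axis); used when `use` is `"squat"`.
#' @param arm_rotation segment of arm rotation; used when `use` is
#'   `"arm_rotation"` (wrist sensors).
#' @param use which movement defines the rotation axis.
#' @param static_tol maximal acceptable sd of the standing |Acc| in g.
#' @return a 3 x 3 rotation matrix mapping sensor to anatomical coordinates.
#' @export
estimate_calibration <- function(standing, squat = NULL, arm_rotation = NULL,
                                 use = c("squat", "arm_rotation"),
                                 static_tol = 0.05) {
  use <- match.arg(use)
  if (nrow(standing$acc) < 2 * standing$fs) {
    stop("estimate_calibration: standing segment must cover >= 2 s",
         call. = FALSE)
  }
  norms <- sqrt(rowSums(standing$acc^2))
  if (stats::sd(norms) > static_tol) {
    stop("estimate_calibration: standing segment is not static (sd(|Acc|) = ",
         signif(stats::sd(norms), 3), " g)", call. = FALSE)
  }
  y <- normalize3(colMeans(standing$acc))   # reaction to gravity points up
  rot_seg <- if (use == "squat") squat else arm_rotation
  if (is.null(rot_seg)) {
    stop("estimate_calibration: missing ", use, " segment", call. = FALSE)
  }
  pc <- principal_components(rot_seg$gyr)
  z <- pc$components[, 1L]
  # orient z so the dominant rotation is positive about it
  if (mean(rot_seg$gyr %*% z) < 0) z <- -z
  z <- normalize3(z - sum(z * y) * y)       # orthogonalize against y
  x <- cross3(y, z)
  R <- rbind(x = x, y = y, z = z)           # rows: anatomical axes in sensor frame
  if (det(R) < 0) {
    z <- -z
    x <- cross3(y, z)
    R <- rbind(x = x, y = y, z = z)
  }
  R
}

#' Apply a calibration transform to a sensor-frame session
#'
#' Rotates every accelerometer and gyroscope sample into the anatomical
#' frame; vector norms are preserved. The session must currently be in the
#' sensor frame and every present location must have a rotation.
#'
#' @param session a [session_recording()] with `frame = "sensor"` recordings.
#' @param cal a [calibration_transform()].
#' @return the calibrated [session_recording()] (`frame = "anatomical"`).
#' @export
apply_calibration <- function(session, cal) {
  stopifnot(inherits(cal, "calibration_transform"))
  recs <- session$recordings
  for (loc in names(recs)) {
    rec <- recs[[loc]]
    if (!identical(rec$frame, "sensor")) {
      stop("apply_calibration: recording for ", loc,
           " is not in the sensor frame", call. = FALSE)
    }
    R <- cal$rotations[[loc]]
    if (is.null(R)) {
      stop("apply_calibration: no transform for present location ", loc,
           call. = FALSE)
    }
    recs[[loc]] <- imu_recording(rec$acc %*% t(R), rec$gyr %*% t(R),
                                 fs = rec$fs, location = loc,
                                 frame = "anatomical")
  }
  session_recording(recs, pool_length = session$pool_length,
                    swimmer_id = session$swimmer_id)
}
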