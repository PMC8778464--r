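# Recording container and per-test CSV I/O.
#
# One CSV file per TUG test, header `t,ax,ay,az,gx,gy,gz`, acceleration in g
# and angular velocity in deg/s (the units the sensor datasheet uses). Axis
# convention of the thigh mount: standing, the y axis is the inverse gravity
# vector (median alpha_y ~ +1 g) and x lies in the frontal plane, so rotation
# about x is the thigh pitch during straight walking.

#' Construct and validate an IMU recording
#'
#' @param subject_id Subject identifier string.
#' @param condition Pharmacological state, `"ON"` or `"OFF"`.
#' @param sample_rate Sampling rate in Hz.
#' @param t Sample timestamps in seconds, strictly increasing and uniform to
#'   within 1% of `1/sample_rate`.
#' @param accel n x 3 matrix of acceleration in g (columns ax, ay, az).
#' @param gyro n x 3 matrix of angular velocity in deg/s (columns gx, gy, gz).
#' @param frame_note Free-text note on the axis convention.
#' @return Object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, condition = c("ON", "OFF"), sample_rate,
                          t, accel, gyro,
                          frame_note = "thigh mount: y = inverse gravity when standing, x in frontal plane") {
  condition <- match.arg(condition)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (ncol(accel) != 3 || ncol(gyro) != 3) stop("accel and gyro must have 3 columns")
  n <- length(t)
  if (nrow(accel) != n || nrow(gyro) != n) stop("channel lengths differ from timestamp length")
  if (n < 2) stop("recording needs at least 2 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (any(abs(dt - 1 / sample_rate) > 0.01 / sample_rate)) {
    stop("timestamps not uniform to within 1% of 1/sample_rate")
  }
  if (!all(is.finite(accel)) || !all(is.finite(gyro))) stop("non-finite sample values")
  structure(list(subject_id = as.character(subject_id), condition = condition,
                 sample_rate = sample_rate, t = as.numeric(t),
                 accel = unname(accel), gyro = unname(gyro),
                 frame_note = frame_note),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s [%s], %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, length(x$t), x$sample_rate,
              x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

#' Write a recording to the per-test CSV dialect
#'
#' Columns `t,ax,ay,az,gx,gy,gz`; one file per test. Values are written with
#' full precision (15 significant digits) so that write/read round-trips are
#' numerically faithful.
#'
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(t = rec$t,
                   ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
                   gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3])
  df[] <- lapply(df, function(v) sprintf("%.15g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-test CSV recording
#'
#' @param path CSV file with header `t,ax,ay,az,gx,gy,gz`.
#' @param subject_id,condition Metadata attached to the recording (the CSV
#'   dialect stores samples only, mirroring a one-file-per-test layout where
#'   identity lives in the file name / subject table).
#' @param sample_rate Sampling rate in Hz; if `NULL`, inferred from the median
#'   timestamp increment.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, subject_id = "unknown", condition = "ON",
                         sample_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty recording file: ", path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  for (cn in need) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s' of %s (data line %d)", cn, path, bad))
    }
  }
  if (any(diff(df$t) <= 0)) {
    bad <- which(diff(df$t) <= 0)[1] + 1
    stop(sprintf("non-monotone timestamps in %s (data line %d)", path, bad))
  }
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(diff(df$t))
  imu_recording(subject_id, condition, sample_rate, df$t,
                as.matrix(df[, c("ax", "ay", "az")]),
                as.matrix(df[, c("gx", "gy", "gz")]))
}

#' Apply a stored frame-alignment rotation
#'
#' Rotates both vector channels sample-by-sample with an orthonormal 3x3
#' matrix (the rotation obtained from the device's table calibration; its
#' estimation is a hardware procedure outside this package).
#'
#' @param rec An [imu_recording()].
#' @param rotation 3x3 orthonormal matrix (checked to 1e-6).
#' @return A new [imu_recording()] with rotated `accel` and `gyro`.
#' @export
apply_frame_alignment <- function(rec, rotation) {
  stopifnot(inherits(rec, "imu_recording"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be a 3x3 orthonormal matrix (tolerance 1e-6)")
  }
  out <- rec
  out$accel <- rec$accel %*% t(rotation)
  out$gyro <- rec$gyro %*% t(rotation)
  class(out) <- class(rec)
  out
}

#' Read / write the subject table
#'
#' CSV with columns `subject_id,condition,pigd,updrs3,fog_status`; one row per
#' subject per pharmacological condition. `pigd` is the regression target
#' (sum of five 0-4 items, range 0-20).
#'
#' @param path CSV file path.
#' @return `read_subject_table`: a data.frame with the columns above.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "pigd", "updrs3", "fog_status")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("subject table missing columns: ", paste(missing, collapse = ", "))
  if (any(df$pigd < 0)) stop("pigd must be non-negative")
  if (anyDuplicated(df[, c("subject_id", "condition")])) {
    stop("subject table must have one row per subject per condition")
  }
  df
}

#' @rdname read_subject_table
#' @param table Subject table data.frame.
#' @export
write_subject_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
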