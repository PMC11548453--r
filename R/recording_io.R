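# Recording I/O and fusion: CSV readers/writers with validation, heel-strike
# clock synchronization, 200 Hz / 60 fps label alignment, and the 11-column
# enriched dataset used by the classifier.

.IMU_COLS <- c("time_s", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
.ACC_RANGE_G <- 16
.GYRO_RANGE_DPS <- 2000

#' Construct and validate an IMU recording
#'
#' A uniformly sampled six-axis inertial trace: time in seconds (strictly
#' increasing), accelerations in g within +/- 16 g, angular rates in deg/s
#' within +/- 2000 deg/s.
#'
#' @param df Data frame with columns `time_s`, `acc_x`, `acc_y`, `acc_z`,
#'   `gyro_x`, `gyro_y`, `gyro_z`.
#' @return An `imu_recording` tibble.
#' @export
imu_recording <- function(df) {
  missing_cols <- setdiff(.IMU_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing IMU columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)[, union(.IMU_COLS, names(df))]
  if (nrow(df) > 1L && any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1L] + 1L
    stop("time_s is not strictly increasing at row ", bad, call. = FALSE)
  }
  for (col in c("acc_x", "acc_y", "acc_z")) {
    if (any(abs(df[[col]]) > .ACC_RANGE_G + 1e-9)) {
      stop("column ", col, " outside the +/-16 g sensor range (row ",
           which(abs(df[[col]]) > .ACC_RANGE_G + 1e-9)[1L], ")", call. = FALSE)
    }
  }
  for (col in c("gyro_x", "gyro_y", "gyro_z")) {
    if (any(abs(df[[col]]) > .GYRO_RANGE_DPS + 1e-6)) {
      stop("column ", col, " outside the +/-2000 deg/s sensor range (row ",
           which(abs(df[[col]]) > .GYRO_RANGE_DPS + 1e-6)[1L], ")",
           call. = FALSE)
    }
  }
  class(df) <- c("imu_recording", class(df))
  df
}

#' Construct and validate an annotation table
#'
#' Frame-rate foot-status labels: status 0 = foot moving, 1 = foot flat
#' (stationary relative to the ground), 2 = undetermined (occluded), plus the
#' activity category.
#'
#' @param df Data frame with columns `time_s`, `foot_status`, `activity`.
#' @return An `annotation_table` tibble.
#' @export
annotation_table <- function(df) {
  need <- c("time_s", "foot_status", "activity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing annotation columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)[, need]
  if (!all(df$foot_status %in% c(0L, 1L, 2L))) {
    stop("foot_status must be 0, 1 or 2", call. = FALSE)
  }
  if (nrow(df) > 1L && any(diff(df$time_s) < 0)) {
    stop("annotation time_s must be non-decreasing", call. = FALSE)
  }
  df$foot_status <- as.integer(df$foot_status)
  df$activity <- as.integer(df$activity)
  class(df) <- c("annotation_table", class(df))
  df
}

#' Read / write IMU recordings as CSV
#'
#' Values are written with 6 decimal places, so a write/read round trip
#' preserves them to that precision. Reading validates column presence, time
#' monotonicity and sensor ranges.
#'
#' @param path CSV file path.
#' @return `read_imu_csv` returns an `imu_recording`.
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  imu_recording(df)
}

#' @rdname read_imu_csv
#' @param rec An `imu_recording`.
#' @export
write_imu_csv <- function(rec, path) {
  out <- as.data.frame(rec)[, .IMU_COLS]
  out[] <- lapply(out, function(x) formatC(x, digits = 6, format = "f"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_imu_csv
#' @export
read_annotation_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  annotation_table(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_imu_csv
#' @param ann An `annotation_table`.
#' @export
write_annotation_csv <- function(ann, path) {
  out <- as.data.frame(ann)
  out$time_s <- formatC(out$time_s, digits = 6, format = "f")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive acceleration and gyroscope norms
#'
#' Appends `acc_norm` and `gyro_norm`, the per-sample Euclidean norms of the
#' three acceleration and angular-rate components.
#'
#' @param rec An `imu_recording`.
#' @return The recording with `acc_norm` and `gyro_norm` columns.
#' @export
compute_norms <- function(rec) {
  rec$acc_norm <- sqrt(rec$acc_x^2 + rec$acc_y^2 + rec$acc_z^2)
  rec$gyro_norm <- sqrt(rec$gyro_x^2 + rec$gyro_y^2 + rec$gyro_z^2)
  rec
}

#' Locate the third synchronization heel strike
#'
#' The protocol opens with three clear heel strikes; the third impact defines
#' trial time 0 shared with the video annotation. Candidate samples are those
#' whose acceleration norm exceeds `min_peak_g`; candidates closer together
#' than `min_separation_ms` are merged into one strike (keeping its largest
#' sample).
#'
#' @param rec An `imu_recording` (norms are derived if absent).
#' @param min_peak_g Detection threshold on the acceleration norm (g).
#' @param min_separation_ms Minimum separation between distinct strikes.
#' @return Time `t0` (s, device clock) of the third strike.
#' @export
detect_sync_strikes <- function(rec, min_peak_g = 2, min_separation_ms = 200) {
  if (!"acc_norm" %in% names(rec)) rec <- compute_norms(rec)
  cand <- which(rec$acc_norm >= min_peak_g)
  if (length(cand) > 0L) {
    tt <- rec$time_s[cand]
    grp <- cumsum(c(TRUE, diff(tt) > min_separation_ms / 1000))
    peaks <- vapply(split(cand, grp), function(ii) {
      ii[which.max(rec$acc_norm[ii])]
    }, integer(1))
  } else {
    peaks <- integer(0)
  }
  if (length(peaks) < 3L) {
    stop("synchronization failed: found ", length(peaks),
         " qualifying heel strikes, need at least 3", call. = FALSE)
  }
  rec$time_s[peaks[3L]]
}

#' Re-base a recording to the synchronization origin
#'
#' @param rec An `imu_recording`.
#' @param t0 Device time (s) to map to trial time 0.
#' @return The recording with `time_s` shifted so `t0` becomes 0.
#' @export
rebase_time <- function(rec, t0) {
  rec$time_s <- rec$time_s - t0
  rec
}

#' Fuse an IMU recording with its annotation into the enriched dataset
#'
#' Both inputs must share the trial clock (0 = third sync strike). Each IMU
#' sample takes the foot status and activity of the latest annotation frame
#' at or before it (sample-and-hold); samples before the first frame or after
#' the last are dropped. The result has the 11 canonical columns: time,
#' 3-axis accelerations, 3-axis gyroscopes, the two norms, foot status and
#' activity.
#'
#' @param rec An `imu_recording` re-based to trial time (norms derived if
#'   absent).
#' @param ann An `annotation_table` in trial time.
#' @return An `enriched_recording` tibble (11 columns).
#' @export
align_annotations <- function(rec, ann) {
  if (nrow(ann) == 0L) stop("annotation table is empty", call. = FALSE)
  if (!"acc_norm" %in% names(rec)) rec <- compute_norms(rec)
  keep <- rec$time_s >= ann$time_s[1L] - 1e-9 &
    rec$time_s <= ann$time_s[nrow(ann)] + 1e-9
  rec <- rec[keep, ]
  idx <- findInterval(rec$time_s + 1e-9, ann$time_s)
  idx[idx < 1L] <- 1L
  out <- tibble::tibble(
    time_s = rec$time_s,
    acc_x = rec$acc_x, acc_y = rec$acc_y, acc_z = rec$acc_z,
    gyro_x = rec$gyro_x, gyro_y = rec$gyro_y, gyro_z = rec$gyro_z,
    acc_norm = rec$acc_norm, gyro_norm = rec$gyro_norm,
    foot_status = ann$foot_status[idx],
    activity = ann$activity[idx]
  )
  class(out) <- c("enriched_recording", class(out))
  out
}

#' Remove undetermined samples
#'
#' Drops rows whose foot status is 2 (undetermined), the samples excluded
#' from training and metrics. The logical keep-mask over the original rows is
#' attached as attribute `mask` so window construction can still respect the
#' original timeline.
#'
#' @param enr An `enriched_recording`.
#' @return The filtered `enriched_recording` with attribute `mask`.
#' @export
drop_undetermined <- function(enr) {
  keep <- enr$foot_status != 2L
  if (!any(keep)) {
    warning("all samples have undetermined foot status; result is empty")
  }
  out <- enr[keep, ]
  class(out) <- class(enr)
  attr(out, "mask") <- keep
  out
}

#' Preprocess one subject: synchronize, fuse, enrich
#'
#' Full preprocessing of a raw recording/annotation pair: derive norms,
#' locate the third sync heel strike, re-base the IMU clock, and fuse with
#' the annotation into the 11-column enriched dataset.
#'
#' @param rec Raw `imu_recording` (device clock).
#' @param ann `annotation_table` (trial clock).
#' @param min_peak_g,min_separation_ms Sync detection parameters, see
#'   [detect_sync_strikes()].
#' @return An `enriched_recording`.
#' @export
enrich_recording <- function(rec, ann, min_peak_g = 2, min_separation_ms = 200) {
  rec <- compute_norms(rec)
  t0 <- detect_sync_strikes(rec, min_peak_g, min_separation_ms)
  align_annotations(rebase_time(rec, t0), ann)
}

#' Preprocess every subject of a cohort
#'
#' @param cohort A `gait_cohort` from [simulate_cohort()].
#' @return List of `enriched_recording`s, one per subject.
#' @export
enrich_cohort <- function(cohort) {
  lapply(cohort, function(s) enrich_recording(s$recording, s$annotation))
}
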