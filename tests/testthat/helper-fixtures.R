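# Shared fixtures, built in code at test time.

# tiny deterministic IMU recording with three strong spikes on acc_z
spiky_recording <- function(spike_times_s, fs = 200, dur_s = 5, amp = 8) {
  n <- dur_s * fs
  t <- (seq_len(n) - 1) / fs
  acc_z <- rep(1, n)
  for (ts in spike_times_s) acc_z[round(ts * fs) + 1] <- amp
  imu_recording(tibble::tibble(
    time_s = t, acc_x = 0, acc_y = 0, acc_z = acc_z,
    gyro_x = 0, gyro_y = 0, gyro_z = 0
  ))
}

# separable toy windows: label = 1 iff channel-1 window mean < 0.5
toy_windows <- function(n, w = 10L, seed = 1L) {
  withr::with_seed(seed, {
    x <- array(0, dim = c(n, 2L, w))
    y <- stats::rbinom(n, 1, 0.5)
    for (i in seq_len(n)) {
      x[i, 1, ] <- stats::rnorm(w, if (y[i] == 1) 0 else 1, 0.2)
      x[i, 2, ] <- stats::rnorm(w, 0.5, 1)
    }
    structure(list(x = x, y = y, end_times = seq_len(n) / 200,
                   channels = c("a", "b"), window_ms = w * 5, fs = 200),
              class = "windowed_dataset")
  })
}

# small enriched recording with a known status pattern, for window tests
tiny_enriched <- function(n = 100L, status = NULL) {
  if (!is.null(status)) n <- length(status)
  df <- tibble::tibble(
    time_s = (seq_len(n) - 1) / 200,
    acc_x = 0, acc_y = 0, acc_z = 1,
    gyro_x = 0, gyro_y = 0, gyro_z = 0,
    acc_norm = 1, gyro_norm = seq_len(n) / n,
    foot_status = if (is.null(status)) rep(c(0L, 1L), length.out = n) else status,
    activity = 1L
  )
  class(df) <- c("enriched_recording", class(df))
  df
}

# miniature cohort for cross-validation plumbing tests: few subjects, short
# scripts -- exercises the full pipeline quickly
mini_cohort <- function(n_subjects = 4L, seed = 31L, und_frac = 0.097) {
  withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      subj <- subject_spec(subject_id = i, seed = sample.int(1e6, 1),
                           mounting_yaw_rad = runif(1, 0, 2 * pi))
      script <- structure(list(
        activity_spec("moderate_walk", n_steps = 6L),
        activity_spec("standing", duration_s = 1),
        activity_spec("run", n_steps = 6L)
      ), class = "track_script")
      sim <- simulate_subject(subj, script)
      ann <- make_annotation_table(sim$truth, seed = sample.int(1e6, 1),
                                   undetermined_fraction = und_frac)
      list(recording = sim$recording, annotation = ann, truth = sim$truth)
    })
  })
}

# independent brute-force step counter: walks the stream sample by sample
oracle_count_steps <- function(status, fs, rd_ms, times = NULL) {
  if (is.null(times)) times <- (seq_along(status) - 1) / fs
  prev <- 0L
  last_time <- -Inf
  n <- 0L
  for (i in seq_along(status)) {
    if (prev == 0L && status[i] == 1L && times[i] - last_time >= rd_ms / 1000) {
      n <- n + 1L
      last_time <- times[i]
    }
    prev <- status[i]
  }
  n
}
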