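# Synthetic multi-activity gait generator: emits 200 Hz six-axis IMU traces
# from a sole-embedded sensor, the foot pitch-angle series a video analyst
# would measure, and ground-truth step events / foot-flat intervals.

#' Catalogue of simulated activities
#'
#' Per-activity waveform parameters of the synthetic gait generator. Cadence
#' is for the instrumented foot only (half the whole-body stepping rate);
#' `flat_fraction` is the fraction of one step period during which the foot is
#' flat on the ground; amplitudes are peaks before subject-level scaling.
#'
#' @return A tibble with one row per activity category: `category_id`, `name`,
#'   `cadence` (steps/min), `flat_fraction`, `gyro_swing_amp` (deg/s),
#'   `acc_impact_amp` (g), `angle_peak` (deg), `acc_swing_amp` (g),
#'   `az_dip` (g).
#' @export
activity_params <- function() {
  tibble::tribble(
    ~category_id, ~name,            ~cadence, ~flat_fraction, ~gyro_swing_amp,
    ~acc_impact_amp, ~angle_peak, ~acc_swing_amp, ~az_dip,
    0L, "standing",       NA_real_, NA_real_,  0,    0,   0,   0,    0,
    1L, "slow_walk",      40,       0.55,      170,  1.5, 35,  0.95, 0.13,
    2L, "moderate_walk",  50,       0.50,      270,  2.0, 45,  1.15, 0.15,
    3L, "fast_walk",      60,       0.45,      390,  2.5, 50,  1.40, 0.19,
    4L, "run",            85,       0.25,      980,  5.0, 60,  2.50, 0.31,
    5L, "stomping",       60,       0.50,      240,  4.0, 30,  1.60, 0.25,
    6L, "high_knees",     80,       0.30,      540,  3.0, 50,  1.85, 0.25,
    7L, "butt_kicks",     80,       0.30,      690,  2.5, 55,  1.70, 0.19,
    8L, "stair_descent",  50,       0.50,      240,  2.5, 40,  1.25, 0.19
  )
}

#' Specify one activity segment of a track
#'
#' @param activity Activity name or integer category code (see
#'   [activity_params()]).
#' @param n_steps Number of steps taken by the instrumented foot (0 for
#'   standing).
#' @param duration_s Segment duration in seconds; required for standing,
#'   derived from cadence otherwise.
#' @param ... Overrides for any [activity_params()] column.
#' @return An `activity_spec` list.
#' @export
activity_spec <- function(activity, n_steps = 0L, duration_s = NULL, ...) {
  cat_tbl <- activity_params()
  if (is.character(activity)) {
    row <- cat_tbl[cat_tbl$name == activity, ]
  } else {
    row <- cat_tbl[cat_tbl$category_id == as.integer(activity), ]
  }
  if (nrow(row) != 1L) {
    stop("unknown activity: ", activity, call. = FALSE)
  }
  spec <- as.list(row)
  overrides <- list(...)
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
  spec$n_steps <- as.integer(n_steps)
  if (spec$n_steps > 0L) {
    if (!is.finite(spec$cadence) || spec$cadence <= 0) {
      stop("cadence must be > 0 for stepping activities", call. = FALSE)
    }
    if (!is.finite(spec$flat_fraction) ||
        spec$flat_fraction <= 0 || spec$flat_fraction >= 1) {
      stop("flat_fraction must lie strictly in (0, 1)", call. = FALSE)
    }
    spec$duration_s <- spec$n_steps * 60 / spec$cadence
  } else {
    if (is.null(duration_s) || duration_s <= 0) {
      stop("standing segments need a positive duration_s", call. = FALSE)
    }
    spec$duration_s <- duration_s
  }
  structure(spec, class = "activity_spec")
}

#' Specify a simulated subject
#'
#' Subject-level heterogeneity of the generator: cadence and amplitude
#' multipliers, sensor noise scales, and the yaw angle at which the sensor
#' happens to be mounted in the sole (rotating the horizontal axes; norms are
#' unaffected).
#'
#' @param subject_id Integer identifier.
#' @param cadence_multiplier,amplitude_multiplier Positive unitless scalings.
#' @param noise_acc_g Accelerometer noise standard deviation (g).
#' @param noise_gyro_dps Gyroscope noise standard deviation (deg/s).
#' @param mounting_yaw_rad Sensor yaw in radians.
#' @param seed RNG seed; a fixed seed yields bit-identical recordings.
#' @return A `subject_spec` list.
#' @export
subject_spec <- function(subject_id = 1L, cadence_multiplier = 1,
                         amplitude_multiplier = 1, noise_acc_g = 0.03,
                         noise_gyro_dps = 2, mounting_yaw_rad = 0,
                         seed = 1L) {
  stopifnot(cadence_multiplier > 0, amplitude_multiplier > 0,
            noise_acc_g >= 0, noise_gyro_dps >= 0)
  structure(list(
    subject_id = as.integer(subject_id),
    cadence_multiplier = cadence_multiplier,
    amplitude_multiplier = amplitude_multiplier,
    noise_acc_g = noise_acc_g,
    noise_gyro_dps = noise_gyro_dps,
    mounting_yaw_rad = mounting_yaw_rad,
    seed = as.integer(seed)
  ), class = "subject_spec")
}

#' Default multi-activity track script
#'
#' The standard course: stair descent, slow/moderate/fast walking, running,
#' stomping, high knees and butt kicks, with short standing pauses and a few
#' transition (walking) steps between blocks. Totals 191 steps, of which 40
#' are walking and 40 running. A 3-heel-strike synchronization prelude is
#' always prepended by [simulate_subject()].
#'
#' @param n_stomp,n_high_knees,n_butt_kicks Step counts of the free-count
#'   activities (the walking/running/stair counts are fixed by the protocol).
#' @return A `track_script`: list of [activity_spec()] segments.
#' @export
default_track_script <- function(n_stomp = 30L, n_high_knees = 30L,
                                 n_butt_kicks = 30L) {
  segs <- list(
    activity_spec("moderate_walk", n_steps = 5L),  # transition to track start
    activity_spec("standing", duration_s = 4),
    activity_spec("stair_descent", n_steps = 11L),
    activity_spec("standing", duration_s = 2),
    activity_spec("slow_walk", n_steps = 14L),
    activity_spec("moderate_walk", n_steps = 13L),
    activity_spec("fast_walk", n_steps = 13L),
    activity_spec("moderate_walk", n_steps = 5L),  # transition to run start
    activity_spec("run", n_steps = 40L),
    activity_spec("standing", duration_s = 3),
    activity_spec("stomping", n_steps = n_stomp),
    activity_spec("high_knees", n_steps = n_high_knees),
    activity_spec("butt_kicks", n_steps = n_butt_kicks),
    activity_spec("standing", duration_s = 3)
  )
  structure(segs, class = "track_script")
}

#' Total planned step count of a track script
#' @param script A `track_script`.
#' @return Integer number of steps.
#' @export
script_step_count <- function(script) {
  sum(vapply(script, function(s) s$n_steps, integer(1)))
}

# Internal: damped 40 Hz heel-strike transient sampled on `t` seconds after
# onset, peak `amp` g.
.impact_wave <- function(t, amp) {
  amp * exp(-t / 0.012) * cos(2 * pi * 40 * t)
}

#' Simulate one subject's instrumented-shoe recording
#'
#' Synthesizes the 6-axis IMU trace of the instrumented (right) foot over the
#' full track, including the synchronization prelude of three strong heel
#' strikes (the third strike defines trial time 0). Each step is one gyro
#' swing burst plus a heel-strike acceleration transient, followed by a
#' quiescent foot-flat interval (gyro near 0, acceleration norm near 1 g).
#' Signals are clipped to the sensor ranges (+/- 16 g, +/- 2000 deg/s).
#'
#' @param subject A [subject_spec()].
#' @param script A `track_script` (default [default_track_script()]).
#' @param fs Sampling rate in Hz (default 200).
#' @return A list with elements `recording` (an `imu_recording`, device clock
#'   starting at 0) and `truth` (a `gait_truth`: `t0_s` device time of the
#'   third sync strike, `step_event_times` / `flat_intervals` in trial time,
#'   `foot_angle` deg and `activity` per sample, `n_steps`).
#' @export
simulate_subject <- function(subject = subject_spec(),
                             script = default_track_script(), fs = 200) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive sampling rate", call. = FALSE)
  }
  if (length(script) == 0L) stop("script must be non-empty", call. = FALSE)

  withr::with_seed(subject$seed, {
    gap_s <- 0.6                       # standing pause between segments
    prelude_stand <- 1.5
    strike_gap <- 0.5
    trial_start_pad <- 0.7             # stand after 3rd strike before moving

    # total duration (device clock)
    dur <- prelude_stand + 3 * strike_gap + trial_start_pad
    for (seg in script) dur <- dur +
      seg$duration_s / (if (seg$n_steps > 0) subject$cadence_multiplier else 1) +
      gap_s
    n <- ceiling(dur * fs) + as.integer(fs)  # 1 s tail margin
    t <- (seq_len(n) - 1L) / fs

    pitch_rate <- numeric(n)   # deg/s, sagittal swing burst
    yaw_rate <- numeric(n)
    acc_h <- numeric(n)        # horizontal swing acceleration, g
    acc_v <- numeric(n)        # vertical deviation from gravity, g
    angle <- numeric(n)        # foot pitch angle, deg
    activity <- integer(n)     # category code per sample

    idx_range <- function(from_s, to_s) {
      i0 <- max(1L, floor(from_s * fs) + 1L)
      i1 <- min(n, ceiling(to_s * fs))
      if (i1 < i0) integer(0) else i0:i1
    }

    # one stamp/step swing: fills the synthesis buffers over [t_on, t_on + s).
    # Each step draws a lognormal amplitude jitter (step-to-step variability).
    amp_mult <- subject$amplitude_multiplier
    add_swing <- function(t_on, s, p) {
      step_amp <- amp_mult * exp(stats::rnorm(1, 0, 0.25))
      ii <- idx_range(t_on, t_on + s)
      tau <- (t[ii] - t_on) / s
      pitch_rate[ii] <<- pitch_rate[ii] + p$gyro_swing_amp * step_amp * sinpi(tau)
      yaw_rate[ii] <<- yaw_rate[ii] + 0.25 * p$gyro_swing_amp * step_amp * sinpi(2 * tau)
      acc_h[ii] <<- acc_h[ii] + p$acc_swing_amp * step_amp * sinpi(2 * tau)
      acc_v[ii] <<- acc_v[ii] - p$az_dip * step_amp * sinpi(tau) +
        0.4 * p$acc_swing_amp * step_amp * sinpi(2 * tau + 0.5)
      angle[ii] <<- angle[ii] + p$angle_peak * sinpi(tau)
      # heel-strike transient just before foot-flat onset
      t_imp <- t_on + s - 0.04
      jj <- idx_range(t_imp, t_imp + 0.06)
      acc_v[jj] <<- acc_v[jj] +
        .impact_wave(t[jj] - t_imp, p$acc_impact_amp * step_amp)
      invisible(NULL)
    }

    # --- synchronization prelude: 3 clear heel strikes, third = trial t0 ---
    stamp <- list(gyro_swing_amp = 200, acc_swing_amp = 0.4, az_dip = 0.2,
                  angle_peak = 20, acc_impact_amp = 9)
    cur <- prelude_stand
    for (k in 1:3) {
      add_swing(cur, 0.3, stamp)   # lift + stamp ending at cur + 0.3
      cur <- cur + strike_gap
    }
    t0 <- prelude_stand + 2 * strike_gap + 0.3 - 0.04  # impact peak of strike 3
    cur <- t0 + trial_start_pad
    # after the third strike the foot rolls forward into the first transition
    # step without settling flat, so the first foot-flat onset inside the
    # annotated span is a genuine step; the rolling foot keeps a visible
    # angular rate so the signal is consistent with its non-flat label
    ii <- idx_range(t0 + 0.02, cur)
    angle[ii] <- angle[ii] + 8
    pitch_rate[ii] <- pitch_rate[ii] + 120 * sinpi(8 * (t[ii] - t0))
    acc_h[ii] <- acc_h[ii] + 0.3 * sinpi(6 * (t[ii] - t0))
    jj <- idx_range(cur, cur + 0.12)
    angle[jj] <- angle[jj] + 8 * (1 - (t[jj] - cur) / 0.12)

    # --- scripted segments ---
    step_events <- numeric(0)
    flat_start <- numeric(0)
    flat_end <- numeric(0)
    for (seg in script) {
      if (seg$n_steps > 0L) {
        period <- 60 / (seg$cadence * subject$cadence_multiplier)
        s <- (1 - seg$flat_fraction) * period
        for (k in seq_len(seg$n_steps)) {
          t_on <- cur + (k - 1) * period
          add_swing(t_on, s, seg)
          step_events <- c(step_events, t_on + s)
          flat_start <- c(flat_start, t_on + s)
          flat_end <- c(flat_end, t_on + period)
        }
        ii <- idx_range(cur, cur + seg$n_steps * period)
        activity[ii] <- seg$category_id
        cur <- cur + seg$n_steps * period
      } else {
        ii <- idx_range(cur, cur + seg$duration_s)
        activity[ii] <- seg$category_id
        cur <- cur + seg$duration_s
      }
      cur <- cur + gap_s   # standing pause between blocks
    }

    # --- assemble sensor channels: mounting yaw mixes horizontal axes ---
    cy <- cos(subject$mounting_yaw_rad)
    sy <- sin(subject$mounting_yaw_rad)
    ng <- subject$noise_gyro_dps
    na <- subject$noise_acc_g
    gyro_x <- pitch_rate * cy + stats::rnorm(n, 0, ng)
    gyro_y <- pitch_rate * sy + stats::rnorm(n, 0, ng)
    gyro_z <- yaw_rate + stats::rnorm(n, 0, ng)
    acc_x <- acc_h * cy + stats::rnorm(n, 0, na)
    acc_y <- acc_h * sy + stats::rnorm(n, 0, na)
    acc_z <- 1 + acc_v + stats::rnorm(n, 0, na)
    # marker-tracking jitter is temporally smooth: moving-average-filtered
    # noise (sd 0.3 deg) avoids unphysical chatter at the 3 deg threshold
    ang_noise <- stats::filter(stats::rnorm(n, 0, 0.3 * sqrt(7)),
                               rep(1 / 7, 7), sides = 2)
    ang_noise[is.na(ang_noise)] <- 0
    angle <- angle + as.numeric(ang_noise)

    clip <- function(x, lim) pmin(pmax(x, -lim), lim)
    rec <- imu_recording(tibble::tibble(
      time_s = t,
      acc_x = clip(acc_x, 16), acc_y = clip(acc_y, 16), acc_z = clip(acc_z, 16),
      gyro_x = clip(gyro_x, 2000), gyro_y = clip(gyro_y, 2000),
      gyro_z = clip(gyro_z, 2000)
    ))

    truth <- structure(list(
      subject_id = subject$subject_id,
      t0_s = t0,
      fs = fs,
      step_event_times = step_events - t0,
      flat_intervals = cbind(start = flat_start - t0, end = flat_end - t0),
      foot_angle = angle,
      activity = activity,
      time_s = t,                      # device clock, parallel to foot_angle
      n_steps = length(step_events),
      trial_end_s = cur - t0
    ), class = "gait_truth")

    list(recording = rec, truth = truth)
  })
}

#' Convert a foot pitch-angle series to a binary foot status
#'
#' Emulates the video analysis rule: the foot is considered flat (status 1)
#' while the absolute sole angle is strictly below the transition threshold,
#' and moving (status 0) otherwise.
#'
#' @param angle Numeric vector of foot angles in degrees.
#' @param threshold_deg Transition threshold in degrees (default 3).
#' @return Integer vector of 0/1 statuses, same length as `angle`.
#' @export
foot_angle_to_status <- function(angle, threshold_deg = 3) {
  if (length(angle) == 0L) return(integer(0))
  if (any(!is.finite(angle))) stop("angle must be finite", call. = FALSE)
  as.integer(abs(angle) < threshold_deg)
}

#' Relabel contiguous runs of a status vector as undetermined
#'
#' Emulates video frames in which the foot is occluded: contiguous runs are
#' relabeled 2 (undetermined) until approximately `fraction` of the samples
#' are undetermined. Occlusion being temporally contiguous, runs (geometric
#' lengths, mean `mean_run`) are used rather than i.i.d. samples.
#'
#' @param status Integer vector of 0/1 statuses.
#' @param fraction Target undetermined fraction in `[0, 1)`. The default
#'   0.097 matches a cohort in which roughly one frame in ten is occluded.
#' @param seed RNG seed.
#' @param mean_run Mean run length in samples.
#' @return Status vector over `{0, 1, 2}`.
#' @export
inject_undetermined <- function(status, fraction = 0.097, seed = 1L,
                                mean_run = 30) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  if (fraction == 0 || length(status) == 0L) return(status)
  n <- length(status)
  target <- round(fraction * n)
  withr::with_seed(seed, {
    out <- as.integer(status)
    n2 <- 0L
    while (n2 < target) {
      len <- 1L + stats::rgeom(1L, 1 / mean_run)
      start <- sample.int(n, 1L)
      ii <- start:min(n, start + len - 1L)
      n2 <- n2 + sum(out[ii] != 2L)
      out[ii] <- 2L
    }
    out
  })
}

#' Build a frame-rate annotation table from ground truth
#'
#' Samples the foot angle at the video frame rate (sample-and-hold from the
#' 200 Hz series), thresholds it into a 0/1 foot status, and injects
#' undetermined (occluded) frames. Frame times are in trial time (0 = third
#' sync heel strike).
#'
#' @param truth A `gait_truth` from [simulate_subject()].
#' @param fps Video frame rate (default 60).
#' @param undetermined_fraction Fraction of occluded frames (see
#'   [inject_undetermined()]).
#' @param threshold_deg Flatness threshold in degrees.
#' @param seed RNG seed for the occlusion runs.
#' @return An `annotation_table` tibble: `time_s`, `foot_status`, `activity`.
#' @export
make_annotation_table <- function(truth, fps = 60,
                                  undetermined_fraction = 0.097,
                                  threshold_deg = 3, seed = 1L) {
  frame_t <- seq(0, truth$trial_end_s, by = 1 / fps)
  dev_t <- frame_t + truth$t0_s
  idx <- findInterval(dev_t + 1e-9, truth$time_s)
  idx[idx < 1L] <- 1L
  status <- foot_angle_to_status(truth$foot_angle[idx], threshold_deg)
  status <- inject_undetermined(status, undetermined_fraction, seed = seed)
  annotation_table(tibble::tibble(
    time_s = frame_t,
    foot_status = status,
    activity = truth$activity[idx]
  ))
}

#' Simulate a cohort of subjects over the multi-activity track
#'
#' Draws per-subject characteristics (cadence and amplitude multipliers,
#' noise scales, sensor mounting yaw spread evenly over the circle) and
#' per-subject step counts for the free-count activities, then simulates each
#' subject and produces the frame-rate annotation table.
#'
#' @param n_subjects Number of subjects (default 21).
#' @param seed Cohort RNG seed; all per-subject seeds derive from it.
#' @param fs IMU sampling rate (Hz).
#' @param fps Annotation frame rate.
#' @param undetermined_fraction Occluded-frame fraction.
#' @return A `gait_cohort`: list of per-subject lists with elements
#'   `recording`, `annotation`, `truth`, `subject`.
#' @export
simulate_cohort <- function(n_subjects = 21L, seed = 1L, fs = 200, fps = 60,
                            undetermined_fraction = 0.097) {
  if (!is.numeric(n_subjects) || n_subjects < 1L) {
    stop("n_subjects must be >= 1", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  cohort <- withr::with_seed(seed, {
    yaw <- 2 * pi * (seq_len(n_subjects) - 1L) / n_subjects +
      stats::runif(n_subjects, -0.15, 0.15)
    lapply(seq_len(n_subjects), function(i) {
      subj <- subject_spec(
        subject_id = i,
        cadence_multiplier = exp(stats::rnorm(1, 0, 0.07)),
        amplitude_multiplier = exp(stats::rnorm(1, 0, 0.15)),
        noise_acc_g = stats::runif(1, 0.02, 0.05),
        noise_gyro_dps = stats::runif(1, 1, 3),
        mounting_yaw_rad = yaw[i],
        seed = sample.int(2^30, 1L)
      )
      script <- default_track_script(
        n_stomp = 30L + sample(-8:8, 1L),
        n_high_knees = 30L + sample(-8:8, 1L),
        n_butt_kicks = 30L + sample(-8:8, 1L)
      )
      ann_seed <- sample.int(2^30, 1L)
      list(subject = subj, script = script, ann_seed = ann_seed)
    })
  })
  lapply(cohort, function(s) {
    sim <- simulate_subject(s$subject, s$script, fs = fs)
    ann <- make_annotation_table(sim$truth, fps = fps,
                                 undetermined_fraction = undetermined_fraction,
                                 seed = s$ann_seed)
    list(recording = sim$recording, annotation = ann, truth = sim$truth,
         subject = s$subject)
  }) |> structure(class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  steps <- vapply(x, function(s) s$truth$n_steps, numeric(1))
  cat("<gait_cohort> ", length(x), " subjects, ",
      sum(steps), " ground-truth steps (",
      paste(range(steps), collapse = "-"), " per subject)\n", sep = "")
  invisible(x)
}
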