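test_that("simulation conserves the scripted step count", {
  script <- structure(list(activity_spec("moderate_walk", n_steps = 10L)),
                      class = "track_script")
  sim <- simulate_subject(subject_spec(seed = 5L), script)
  expect_equal(sim$truth$n_steps, 10L)
  expect_length(sim$truth$step_event_times, 10L)
  expect_equal(nrow(sim$truth$flat_intervals), 10L)
})

test_that("the default track totals 191 steps with 40 walking and 40 running", {
  script <- default_track_script()
  expect_equal(script_step_count(script), 191L)
  walk <- sum(vapply(script, function(s)
    if (s$name %in% c("slow_walk", "moderate_walk", "fast_walk")) s$n_steps
    else 0L, integer(1)))
  run <- sum(vapply(script, function(s)
    if (s$name == "run") s$n_steps else 0L, integer(1)))
  expect_equal(walk, 50L)  # 40 scripted walking + 10 walking transition steps
  expect_equal(run, 40L)
  sim <- simulate_subject(subject_spec(seed = 2L))
  expect_equal(sim$truth$n_steps, 191L)
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_subject(subject_spec(seed = 11L))
  s2 <- simulate_subject(subject_spec(seed = 11L))
  expect_identical(s1$recording, s2$recording)
  expect_identical(s1$truth$step_event_times, s2$truth$step_event_times)
})

test_that("simulated signals respect sensor ranges and flat-phase morphology", {
  sim <- simulate_subject(subject_spec(seed = 3L))
  rec <- compute_norms(sim$recording)
  expect_true(all(abs(rec$acc_z) <= 16))
  expect_true(all(abs(rec$gyro_x) <= 2000))
  # inside ground-truth flat intervals the gyro is quiescent and acc ~ 1 g
  iv <- sim$truth$flat_intervals
  mid <- (iv[, 1] + iv[, 2]) / 2 + sim$truth$t0_s
  idx <- findInterval(mid, rec$time_s)
  expect_lt(stats::median(rec$gyro_norm[idx]), 20)
  expect_lt(abs(stats::median(rec$acc_norm[idx]) - 1), 0.15)
})

test_that("flat intervals are disjoint, sorted, and non-empty at 200 Hz", {
  sim <- simulate_subject(subject_spec(seed = 7L))
  iv <- sim$truth$flat_intervals
  expect_true(all(diff(iv[, 1]) > 0))
  expect_true(all(iv[, 2] > iv[, 1] + 1 / 200))
  expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2] - 1e-9))
})

test_that("foot_angle_to_status applies the strict 3-degree threshold", {
  expect_equal(foot_angle_to_status(rep(0, 5)), rep(1L, 5))
  expect_equal(foot_angle_to_status(rep(10, 5)), rep(0L, 5))
  expect_equal(foot_angle_to_status(numeric(0)), integer(0))
  expect_equal(foot_angle_to_status(c(-2.9, 2.9, 3, -3)), c(1L, 1L, 0L, 0L))
  ramp <- 6 * (seq_len(100) - 1) / 99
  status <- foot_angle_to_status(ramp)
  flip <- which(status == 0L)[1]
  expect_equal(flip, which(ramp >= 3)[1])
  expect_true(all(status[seq_len(flip - 1)] == 1L))
  expect_true(all(status[flip:100] == 0L))
  expect_error(foot_angle_to_status(c(1, NA)), "finite")
})

test_that("inject_undetermined hits the target fraction with contiguous runs", {
  status <- rep(c(0L, 1L), 50000)
  out <- inject_undetermined(status, 0.097, seed = 4L)
  expect_true(abs(sum(out == 2L) - 9700) < 200)  # run granularity
  expect_identical(inject_undetermined(status, 0), status)
  expect_identical(out, inject_undetermined(status, 0.097, seed = 4L))
  expect_error(inject_undetermined(status, 1), "fraction")
  # unchanged samples keep their original label
  expect_identical(out[out != 2L], status[out != 2L])
})

test_that("cohort simulation emits per-subject variability around 191 steps", {
  co <- simulate_cohort(6, seed = 9)
  expect_length(co, 6L)
  steps <- vapply(co, function(s) s$truth$n_steps, numeric(1))
  expect_true(all(steps >= 150 & steps <= 230))
  expect_length(simulate_cohort(1, seed = 1), 1L)
  expect_error(simulate_cohort(0), "n_subjects")
})

test_that("annotation tables are frame-rate sampled with occluded runs", {
  sim <- simulate_subject(subject_spec(seed = 13L))
  ann <- make_annotation_table(sim$truth, fps = 60, seed = 2L)
  expect_s3_class(ann, "annotation_table")
  expect_equal(stats::median(diff(ann$time_s)), 1 / 60, tolerance = 1e-9)
  frac2 <- mean(ann$foot_status == 2L)
  expect_true(abs(frac2 - 0.097) < 0.03)
  expect_true(all(ann$foot_status %in% 0:2))
})
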