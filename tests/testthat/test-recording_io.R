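test_that("IMU CSV round trip preserves values to 6 decimals", {
  withr::with_seed(1, {
    rec <- imu_recording(tibble::tibble(
      time_s = (0:999) / 200,
      acc_x = runif(1000, -15, 15), acc_y = runif(1000, -15, 15),
      acc_z = runif(1000, -15, 15),
      gyro_x = runif(1000, -1999, 1999), gyro_y = runif(1000, -1999, 1999),
      gyro_z = runif(1000, -1999, 1999)
    ))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(rec, path)
  back <- read_imu_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-6)
  ann <- annotation_table(tibble::tibble(
    time_s = (0:59) / 60, foot_status = rep(0:2, 20), activity = 3L))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(ann, path2)
  expect_equal(as.data.frame(read_annotation_csv(path2)), as.data.frame(ann),
               tolerance = 1e-6)
})

test_that("readers reject malformed recordings with named errors", {
  df <- tibble::tibble(
    time_s = (0:9) / 200, acc_x = 0, acc_y = 0, acc_z = 1,
    gyro_x = 0, gyro_y = 0, gyro_z = 0
  )
  bad_range <- df
  bad_range$gyro_y[3] <- 3000
  expect_error(imu_recording(bad_range), "gyro_y")
  bad_time <- df
  bad_time$time_s <- sample(bad_time$time_s)
  expect_error(imu_recording(bad_time), "increasing")
  expect_error(imu_recording(df[, -2]), "acc_x")
  expect_error(annotation_table(tibble::tibble(
    time_s = 0, foot_status = 5L, activity = 0L)), "foot_status")
  expect_error(read_imu_csv("no/such/file.csv"), "not found")
})

test_that("norms match an elementwise square/sum/sqrt oracle", {
  expect_equal(compute_norms(imu_recording(tibble::tibble(
    time_s = 0, acc_x = 3, acc_y = 4, acc_z = 0,
    gyro_x = 0, gyro_y = 0, gyro_z = 0)))$acc_norm, 5)
  withr::with_seed(42, {
    m <- matrix(rnorm(600), ncol = 6)
    rec <- imu_recording(tibble::tibble(
      time_s = (0:99) / 200,
      acc_x = m[, 1], acc_y = m[, 2], acc_z = m[, 3],
      gyro_x = m[, 4], gyro_y = m[, 5], gyro_z = m[, 6]
    ))
  })
  rec <- compute_norms(rec)
  oracle_acc <- vapply(seq_len(100), function(i)
    sqrt(sum(c(m[i, 1]^2, m[i, 2]^2, m[i, 3]^2))), numeric(1))
  oracle_gyro <- vapply(seq_len(100), function(i)
    sqrt(sum(c(m[i, 4]^2, m[i, 5]^2, m[i, 6]^2))), numeric(1))
  expect_equal(rec$acc_norm, oracle_acc, tolerance = 1e-12)
  expect_equal(rec$gyro_norm, oracle_gyro, tolerance = 1e-12)
  expect_equal(compute_norms(imu_recording(tibble::tibble(
    time_s = 0, acc_x = 0, acc_y = 0, acc_z = 0,
    gyro_x = 0, gyro_y = 0, gyro_z = 0)))$gyro_norm, 0)
})

test_that("sync detection returns the third qualifying strike", {
  rec <- spiky_recording(c(1, 2, 3))
  expect_equal(detect_sync_strikes(rec), 3)
  expect_error(detect_sync_strikes(spiky_recording(c(1, 2))), "3")
  # close spikes merge under the separation rule
  rec2 <- spiky_recording(c(1, 1.02, 2, 3))
  expect_equal(detect_sync_strikes(rec2, min_separation_ms = 200), 3)
  # without merging, the 1.02 s spike would count and shift the result
  expect_equal(detect_sync_strikes(rec2, min_separation_ms = 10), 2)
})

test_that("alignment holds each frame's status for 200/60 ~ 3.3 samples", {
  rec <- compute_norms(imu_recording(tibble::tibble(
    time_s = (0:199) / 200, acc_x = 0, acc_y = 0, acc_z = 1,
    gyro_x = 0, gyro_y = 0, gyro_z = 0
  )))
  ann <- annotation_table(tibble::tibble(
    time_s = (0:59) / 60,
    foot_status = rep(c(0L, 1L), 30),
    activity = 1L
  ))
  enr <- align_annotations(rec, ann)
  expect_equal(ncol(enr), 11L)
  runs <- rle(enr$foot_status)$lengths
  expect_true(all(runs[-length(runs)] %in% c(3L, 4L)))
  # a sample exactly at a frame time takes that frame's status
  expect_equal(enr$foot_status[enr$time_s == 0.05][1],
               ann$foot_status[ann$time_s == 0.05][1])
  # single frame spanning everything -> constant status
  one <- align_annotations(rec, annotation_table(tibble::tibble(
    time_s = 0, foot_status = 1L, activity = 0L)))
  expect_true(all(one$foot_status == 1L))
  expect_error(align_annotations(rec, annotation_table(tibble::tibble(
    time_s = numeric(0), foot_status = integer(0), activity = integer(0)))),
    "empty")
})

test_that("alignment drops samples outside the annotated span", {
  rec <- compute_norms(imu_recording(tibble::tibble(
    time_s = seq(-0.5, 1.5, by = 1 / 200), acc_x = 0, acc_y = 0, acc_z = 1,
    gyro_x = 0, gyro_y = 0, gyro_z = 0
  )))
  ann <- annotation_table(tibble::tibble(
    time_s = c(0, 0.5), foot_status = c(0L, 1L), activity = 0L))
  enr <- align_annotations(rec, ann)
  expect_true(all(enr$time_s >= 0 - 1e-9 & enr$time_s <= 0.5 + 1e-9))
  expect_lte(nrow(enr), nrow(rec))
})

test_that("drop_undetermined removes status-2 rows and keeps a mask", {
  enr <- tiny_enriched(status = c(0L, 1L, 2L, 1L))
  out <- drop_undetermined(enr)
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "mask"), c(TRUE, TRUE, FALSE, TRUE))
  no2 <- tiny_enriched(status = c(0L, 1L, 0L, 1L))
  expect_equal(nrow(drop_undetermined(no2)), 4L)
  expect_warning(drop_undetermined(tiny_enriched(status = rep(2L, 4))),
                 "undetermined")
})

test_that("end-to-end enrichment recovers the sync origin", {
  sim <- simulate_subject(subject_spec(seed = 21L))
  ann <- make_annotation_table(sim$truth)
  enr <- enrich_recording(sim$recording, ann)
  expect_equal(ncol(enr), 11L)
  expect_true(abs(enr$time_s[1]) < 1 / 60)
  # status column only contains values present in the annotation
  expect_true(all(enr$foot_status %in% unique(ann$foot_status)))
})
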