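test_that("window construction counts and sizes follow the sliding rule", {
  enr <- tiny_enriched(n = 100, status = rep(0:1, 50))
  ds <- make_windows(enr, "gyro_norm", window_ms = 125, fs = 200)
  expect_equal(dim(ds$x)[3], 25L)            # 0.125 s x 200 Hz
  expect_equal(dim(ds$x)[1], 76L)            # N - w + 1
  ds4 <- make_windows(enr, "gyro_norm", window_ms = 125, fs = 200, stride = 4)
  expect_equal(dim(ds4$x)[1], 19L)           # floor(75/4) + 1
  expect_error(make_windows(enr, "gyro_norm", window_ms = 1000), "exceeds")
  expect_error(make_windows(enr, "nope", window_ms = 125), "nope")
  # labels are the endpoint statuses
  expect_equal(ds$y, enr$foot_status[25:100])
  # window content is the trailing w samples of the channel
  expect_equal(ds$x[1, 1, ], enr$gyro_norm[1:25])
  expect_equal(ds$x[76, 1, ], enr$gyro_norm[76:100])
})

test_that("undetermined endpoints are excluded unless explicitly kept", {
  status <- rep(0:1, 50)
  status[c(30, 40, 50)] <- 2L
  enr <- tiny_enriched(n = 100, status = status)
  ds <- make_windows(enr, "gyro_norm", window_ms = 125, fs = 200)
  expect_equal(dim(ds$x)[1], 73L)
  expect_true(all(ds$y %in% 0:1))
  full <- make_windows(enr, "gyro_norm", window_ms = 125, fs = 200,
                       keep_undetermined = TRUE)
  expect_equal(dim(full$x)[1], 76L)
  expect_true(any(full$y == 2L))
})

test_that("the normalizer z-scores with training statistics only", {
  tr <- toy_windows(200, seed = 2)
  st <- fit_normalizer(tr)
  tr_n <- apply_normalizer(tr, st)
  for (ci in 1:2) {
    expect_lt(abs(mean(tr_n$x[, ci, ])), 1e-9)
    expect_equal(stats::sd(as.numeric(tr_n$x[, ci, ])), 1, tolerance = 1e-2)
  }
  # held-out data normalized with train stats differs from its own z-score
  te <- toy_windows(100, seed = 3)
  te_tr <- apply_normalizer(te, st)
  te_own <- apply_normalizer(te, fit_normalizer(te))
  expect_false(isTRUE(all.equal(te_tr$x, te_own$x)))
  # constant channel -> zeros with a warning
  const <- tr
  const$x[, 2, ] <- 5
  expect_warning(stc <- fit_normalizer(const), "zero-variance")
  expect_true(all(apply_normalizer(const, stc)$x[, 2, ] == 0))
})

test_that("parameter counts match the analytic LSTM formula", {
  lstm_params <- function(units, channels, layers) {
    total <- 0
    d <- channels
    for (l in seq_len(layers)) {
      total <- total + 4 * (units * (d + units) + units)
      d <- units
    }
    total
  }
  # optimized architecture on 3 channels
  cfg <- model_config(n_lstm_units = 32, n_lstm_layers = 2)
  m <- build_model(cfg, 3)
  expect_equal(n_parameters(m), lstm_params(32, 3, 2) + 32 + 1)
  # single layer, no dense
  m1 <- build_model(model_config(n_lstm_units = 8, n_lstm_layers = 1), 2)
  expect_length(m1$weights$layers, 1L)
  expect_equal(n_parameters(m1), lstm_params(8, 2, 1) + 8 + 1)
  # dense layer adds its own stack
  md <- build_model(model_config(n_lstm_units = 8, n_lstm_layers = 1,
                                 dense_layer_active = TRUE, n_dense_units = 8), 2)
  expect_equal(dim(md$weights$dense$W), c(8L, 8L))
  expect_equal(n_parameters(md), lstm_params(8, 2, 1) + (8 * 8 + 8) + 8 + 1)
  expect_error(model_config(lstm_activation = "selu"), "lstm_activation")
})

test_that("training solves a separable toy and predictions match the oracle", {
  tr <- toy_windows(1500, seed = 4)
  va <- toy_windows(400, seed = 5)
  st <- fit_normalizer(tr)
  tr <- apply_normalizer(tr, st)
  va <- apply_normalizer(va, st)
  cfg <- model_config(n_lstm_units = 8, n_lstm_layers = 1,
                      input_window_ms = 50, batch_size = 64,
                      learning_rate = 5e-3, dropout = 0.1, seed = 6)
  m <- train_model(build_model(cfg, 2), tr, va, epochs = 15)
  expect_gt(mean(predict_status(m, va) == va$y), 0.99)
  p <- predict_proba(m, va)
  expect_true(all(p >= 0 & p <= 1))
  # the restored best checkpoint is the minimum of the recorded history
  expect_equal(m$best_val_loss, min(m$history$val_loss))
})

test_that("training is reproducible under fixed seeds", {
  tr <- toy_windows(300, seed = 7)
  va <- toy_windows(100, seed = 8)
  cfg <- model_config(n_lstm_units = 4, n_lstm_layers = 1,
                      input_window_ms = 50, batch_size = 64, seed = 9)
  m1 <- train_model(build_model(cfg, 2), tr, va, epochs = 3)
  m2 <- train_model(build_model(cfg, 2), tr, va, epochs = 3)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$weights$layers[[1]]$W, m2$weights$layers[[1]]$W)
})

test_that("decision thresholding uses >= and respects extreme thresholds", {
  tr <- toy_windows(300, seed = 10)
  cfg <- model_config(n_lstm_units = 4, n_lstm_layers = 1,
                      input_window_ms = 50, batch_size = 64, seed = 11)
  m <- train_model(build_model(cfg, 2), tr, tr, epochs = 2)
  p <- predict_proba(m, tr)
  expect_equal(predict_status(m, tr, decision_threshold = 1.0),
               as.integer(p >= 1.0))
  expect_true(all(predict_status(m, tr, decision_threshold = 1 + 1e-9) == 0L))
  expect_equal(predict_status(m, tr, decision_threshold = 0.5),
               as.integer(p >= 0.5))
  # channel mismatch is refused
  bad <- tr
  bad$x <- bad$x[, 1, , drop = FALSE]
  expect_error(predict_status(m, bad), "channel mismatch")
})

test_that("early stopping halts after patience epochs without improvement", {
  # almost-empty model on random labels: validation loss mostly worsens/stalls
  tr <- toy_windows(200, seed = 12)
  withr::with_seed(13, tr$y <- rbinom(200, 1, 0.5))
  va <- toy_windows(100, seed = 14)
  withr::with_seed(15, va$y <- rbinom(100, 1, 0.5))
  cfg <- model_config(n_lstm_units = 2, n_lstm_layers = 1,
                      input_window_ms = 50, batch_size = 32,
                      learning_rate = 0.05, seed = 16)
  m <- train_model(build_model(cfg, 2), tr, va, epochs = 100, patience = 3)
  if (m$stop_reason == "patience") {
    expect_lte(nrow(m$history), 100)
    tail_losses <- utils::tail(m$history$val_loss, 3)
    expect_true(all(tail_losses >= m$best_val_loss))
  }
  expect_true(m$stop_reason %in% c("patience", "epochs"))
})
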