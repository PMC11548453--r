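test_that("the design space enumerates 3,150,000 combinations", {
  expect_equal(count_combinations(search_space()), 3150000)
  expect_equal(count_combinations(structure(list(a = 1:5), class = "search_space")), 5)
  expect_warning(n0 <- count_combinations(
    structure(list(a = 1:5, b = numeric(0)), class = "search_space")), "empty")
  expect_equal(n0, 0)
  # grids contain the published optimum configuration
  sp <- search_space()
  expect_true(32 %in% sp$n_lstm_units)
  expect_true(125 %in% sp$input_window_ms)
  expect_true(0.2 %in% sp$dropout)
  expect_true(1024 %in% sp$batch_size)
  expect_true(any(abs(sp$learning_rate - 1e-2) < 1e-12))
})

test_that("window subsampling is exact, seeded, and bounded", {
  ds <- toy_windows(1000, seed = 20)
  sub <- subsample_windows(ds, 0.25, seed = 1)
  expect_equal(length(sub$y), 250L)
  expect_identical(subsample_windows(ds, 0.25, seed = 1)$y, sub$y)
  expect_identical(subsample_windows(ds, 1)$y, ds$y)
  expect_error(subsample_windows(ds, 0), "fraction")
  expect_error(subsample_windows(ds, 1.2), "fraction")
})

test_that("two-stage search splits the budget and stays on the grids", {
  sp <- search_space()
  seen <- list()
  obj <- function(cfg) {
    seen[[length(seen) + 1L]] <<- cfg
    stats::runif(1)
  }
  res <- two_stage_search(sp, obj, budget_trials = 8, frac_random = 0.25,
                          seed = 5)
  expect_equal(sum(res$trials$stage == "random"), 2L)
  expect_equal(sum(res$trials$stage == "local"), 6L)
  expect_equal(nrow(res$trials), 8L)
  for (cfg in seen) {
    expect_true(cfg$n_lstm_units %in% sp$n_lstm_units)
    expect_true(cfg$input_window_ms %in% sp$input_window_ms)
    expect_true(any(abs(sp$learning_rate - cfg$learning_rate) < 1e-15))
    expect_true(cfg$batch_size %in% sp$batch_size)
  }
  expect_error(two_stage_search(sp, obj, budget_trials = 1), "budget")
})

test_that("the search trial sequence is reproducible under a fixed seed", {
  sp <- search_space()
  obj <- function(cfg) cfg$dropout + cfg$learning_rate
  r1 <- two_stage_search(sp, obj, budget_trials = 12, seed = 7)
  r2 <- two_stage_search(sp, obj, budget_trials = 12, seed = 7)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$best_config, r2$best_config)
})

test_that("best recorded loss is the running minimum of the trial log", {
  sp <- search_space()
  obj <- function(cfg) cfg$dropout * cfg$n_lstm_layers
  res <- two_stage_search(sp, obj, budget_trials = 20, seed = 9)
  expect_equal(res$best_loss, min(res$trials$loss))
})

test_that("the search recovers a stub objective's known optimum", {
  # separable stub: index distance to a fixed target configuration
  sp <- search_space()
  target <- list(n_lstm_units = 2L, n_lstm_layers = 2L,
                 dense_layer_active = 1L, n_dense_units = 3L,
                 input_window_ms = 5L, dropout = 2L, lstm_activation = 3L,
                 learning_rate = 18L, batch_size = 6L)
  make_obj <- function() {
    function(cfg) {
      idx <- list(
        n_lstm_units = match(cfg$n_lstm_units, sp$n_lstm_units),
        n_lstm_layers = match(cfg$n_lstm_layers, sp$n_lstm_layers),
        dense_layer_active = match(cfg$dense_layer_active, sp$dense_layer_active),
        n_dense_units = match(cfg$n_dense_units, sp$n_dense_units),
        input_window_ms = match(cfg$input_window_ms, sp$input_window_ms),
        dropout = match(cfg$dropout, sp$dropout),
        lstm_activation = match(cfg$lstm_activation, sp$lstm_activation),
        learning_rate = which.min(abs(sp$learning_rate - cfg$learning_rate)),
        batch_size = match(cfg$batch_size, sp$batch_size)
      )
      sum(abs(unlist(idx) - unlist(target)))
    }
  }
  hits <- vapply(1:20, function(s) {
    res <- two_stage_search(sp, make_obj(), budget_trials = 50, seed = s)
    res$best_loss == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the real objective trains on a subsample and returns its loss", {
  tr <- toy_windows(600, seed = 22)
  va <- toy_windows(200, seed = 23)
  obj <- make_tune_objective(tr, va, fraction = 0.5, epochs = 2,
                             max_minutes = 0.5)
  cfg <- model_config(n_lstm_units = 4, n_lstm_layers = 1,
                      input_window_ms = 25, batch_size = 128, seed = 2)
  loss <- obj(cfg)
  expect_true(is.finite(loss) && loss > 0)
})

test_that("finalize runs a full cross-validation with the winning config", {
  co <- mini_cohort(2, seed = 55L)
  enr <- lapply(co, function(s) enrich_recording(s$recording, s$annotation))
  truth_steps <- vapply(co, function(s) s$truth$n_steps, numeric(1))
  best <- model_config(n_lstm_units = 2, n_lstm_layers = 1,
                       input_window_ms = 50, batch_size = 512, seed = 1)
  plan <- make_folds(1:2, k = 2, fold_size = 1, seed = 1)
  rep <- finalize_search(best, enr, truth_steps, plan,
                         train_stride = 8L, epochs = 1, max_minutes = 0.5)
  expect_s3_class(rep, "eval_report")
  expect_identical(rep$cfg, best)
  expect_equal(nrow(rep$rd_curve), 40L)
  expect_equal(nrow(rep$per_fold), 2L)
})
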