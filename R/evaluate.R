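# Subject-wise k-fold cross-validation of the full detection + counting
# pipeline, with aggregate reporting.

#' Partition subjects into folds
#'
#' Uniformly random disjoint partition of the subject ids into `k` folds of
#' `fold_size` subjects each (default 7 folds of 3), reproducible per seed.
#' Cross-validation is subject-wise: no individual ever contributes to both
#' training and evaluation of the same model.
#'
#' @param subject_ids Vector of subject identifiers; its length must equal
#'   `k * fold_size`.
#' @param k Number of folds.
#' @param fold_size Subjects per fold.
#' @param seed RNG seed.
#' @return A `fold_plan`: list of `k` id vectors.
#' @export
make_folds <- function(subject_ids, k = 7L, fold_size = 3L, seed = 1L) {
  if (length(subject_ids) != k * fold_size) {
    stop("need exactly ", k * fold_size, " subjects for ", k, " folds of ",
         fold_size, "; got ", length(subject_ids), call. = FALSE)
  }
  withr::with_seed(seed, {
    shuffled <- sample(subject_ids)
    folds <- split(shuffled, rep(seq_len(k), each = fold_size))
    structure(unname(folds), class = "fold_plan", seed = seed)
  })
}

# Internal: train on `train_ids`, predict per-sample status streams for
# `test_ids`. Returns per-subject predictions plus the leakage assertion.
.fit_and_predict <- function(enriched, cfg, train_ids, test_ids,
                             channels, fs, train_stride, epochs, patience,
                             max_minutes, val_stride = 4L) {
  stopifnot(length(intersect(train_ids, test_ids)) == 0L)  # leakage guard
  train_ds <- make_windows(enriched[train_ids], channels,
                           cfg$input_window_ms, fs, stride = train_stride)
  val_ds <- make_windows(enriched[test_ids], channels,
                         cfg$input_window_ms, fs, stride = val_stride)
  norm <- fit_normalizer(train_ds)
  train_ds <- apply_normalizer(train_ds, norm)
  val_ds <- apply_normalizer(val_ds, norm)
  model <- build_model(cfg, length(channels))
  model <- train_model(model, train_ds, val_ds, epochs = epochs,
                       patience = patience, max_minutes = max_minutes)
  # deployment-style prediction: the counting stream covers every sample
  # (the fielded device has no video, hence no undetermined gaps); label
  # metrics use only the determined samples
  preds <- lapply(test_ids, function(id) {
    ds <- make_windows(enriched[[id]], channels, cfg$input_window_ms, fs,
                       stride = 1L, keep_undetermined = TRUE)
    ds <- apply_normalizer(ds, norm)
    status <- predict_status(model, ds)
    labeled <- ds$y != 2L
    list(id = id,
         status = status,
         times = ds$end_times,
         status_labeled = status[labeled],
         obs = ds$y[labeled])
  })
  list(model = model, predictions = preds, normalizer = norm)
}

#' Subject-wise cross-validation of the step-counting pipeline
#'
#' For each fold, trains the classifier on the other folds' subjects and
#' predicts per-sample foot status for the held-out subjects (which also
#' serve as the early-stopping validation set, mirroring the study design).
#' The rest delay is then selected once by sweeping the grid on the pooled
#' held-out predictions, and per-fold step-count errors are reported at that
#' rest delay.
#'
#' @param enriched List of `enriched_recording`s indexed by subject.
#' @param truth_steps Named/indexed vector of ground-truth step counts.
#' @param cfg A [model_config()].
#' @param plan A [make_folds()] plan.
#' @param channels Channels used as model input.
#' @param fs Sampling rate (Hz).
#' @param train_stride Window stride for training examples.
#' @param epochs,patience,max_minutes Training stopping rules.
#' @param rd_grid_ms Rest-delay grid for the sweep.
#' @return An `eval_report`: per-fold tibble (`fold`, `mape_dl`, `mape_g`),
#'   means/sds, `rd_ms` chosen, the sweep `rd_curve`, and per-subject
#'   predictions.
#' @export
cross_validate <- function(enriched, truth_steps, cfg, plan,
                           channels = c("gyro_norm", "acc_norm", "acc_z"),
                           fs = 200, train_stride = 4L, epochs = 100L,
                           patience = 10L, max_minutes = 5,
                           rd_grid_ms = seq(25, 1000, by = 25)) {
  all_preds <- list()
  fold_of <- integer(0)
  for (f in seq_along(plan)) {
    test_ids <- plan[[f]]
    train_ids <- setdiff(unlist(plan), test_ids)
    fit <- .fit_and_predict(enriched, cfg, train_ids, test_ids, channels,
                            fs, train_stride, epochs, patience, max_minutes)
    for (p in fit$predictions) {
      all_preds[[length(all_preds) + 1L]] <- p
      fold_of <- c(fold_of, f)
    }
  }
  # one rest delay for the whole study, swept on pooled predictions
  sweep <- sweep_rd(lapply(all_preds, `[[`, "status"), fs = fs,
                    true_step_count = vapply(all_preds, function(p)
                      truth_steps[[p$id]], numeric(1)),
                    rd_grid_ms = rd_grid_ms,
                    times = lapply(all_preds, `[[`, "times"))
  per_fold <- lapply(seq_along(plan), function(f) {
    ps <- all_preds[fold_of == f]
    dl <- mean(vapply(ps, function(p) mape_dl(p$status_labeled, p$obs), numeric(1)))
    g <- mean(vapply(ps, function(p) {
      n <- count_steps(p$status, fs = fs, rd_ms = sweep$best_rd_ms,
                       times = p$times)$n_steps
      mape_g(n, truth_steps[[p$id]])
    }, numeric(1)))
    tibble::tibble(fold = f, mape_dl = dl, mape_g = g)
  })
  per_fold <- do.call(rbind, per_fold)
  structure(list(
    per_fold = per_fold,
    mean_mape_dl = mean(per_fold$mape_dl),
    sd_mape_dl = stats::sd(per_fold$mape_dl),
    mean_mape_g = mean(per_fold$mape_g),
    sd_mape_g = stats::sd(per_fold$mape_g),
    rd_ms = sweep$best_rd_ms,
    rd_curve = sweep$curve,
    predictions = all_preds,
    cfg = cfg
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", nrow(x$per_fold), " folds\n", sep = "")
  cat(sprintf("  MAPE_DL: %.2f%% +/- %.2f%%\n",
              100 * x$mean_mape_dl, 100 * x$sd_mape_dl))
  cat(sprintf("  MAPE_G:  %.2f%% +/- %.2f%% at rest delay %d ms\n",
              100 * x$mean_mape_g, 100 * x$sd_mape_g, as.integer(x$rd_ms)))
  invisible(x)
}

#' Single subject-wise train/test evaluation
#'
#' One split (e.g. 18 train / 3 test): trains, predicts per-sample on the
#' held-out subjects, sweeps the rest delay, and reports both MAPEs.
#'
#' @inheritParams cross_validate
#' @param train_ids,test_ids Disjoint subject index vectors.
#' @return List with `mape_dl`, `mape_g` (at best rd), `rd_ms`, `rd_curve`,
#'   `model`, `predictions`.
#' @export
evaluate_split <- function(enriched, truth_steps, cfg, train_ids, test_ids,
                           channels = c("gyro_norm", "acc_norm", "acc_z"),
                           fs = 200, train_stride = 4L, epochs = 100L,
                           patience = 10L, max_minutes = 5,
                           rd_grid_ms = seq(25, 1000, by = 25)) {
  fit <- .fit_and_predict(enriched, cfg, train_ids, test_ids, channels, fs,
                          train_stride, epochs, patience, max_minutes)
  preds <- fit$predictions
  sweep <- sweep_rd(lapply(preds, `[[`, "status"), fs = fs,
                    true_step_count = vapply(preds, function(p)
                      truth_steps[[p$id]], numeric(1)),
                    rd_grid_ms = rd_grid_ms,
                    times = lapply(preds, `[[`, "times"))
  list(
    mape_dl = mean(vapply(preds, function(p) mape_dl(p$status_labeled, p$obs),
                          numeric(1))),
    mape_g = sweep$best_mape_g,
    rd_ms = sweep$best_rd_ms,
    rd_curve = sweep$curve,
    model = fit$model,
    predictions = preds
  )
}
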