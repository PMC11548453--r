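# End-to-end orchestration: simulate -> preprocess -> select channels ->
# train -> evaluate -> count, with a provenance manifest.

#' Default run configuration
#'
#' Bundles every knob of an end-to-end run. The `profile` switch trades
#' fidelity for speed: `"full"` uses the 21-subject cohort with 7-fold
#' cross-validation; `"fast"` uses a single 18/3 subject-wise split with
#' training stride 4.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_subjects Cohort size.
#' @param fs IMU sampling rate (Hz).
#' @param correlation_threshold Channel retention threshold on |r|.
#' @param model [model_config()] to train.
#' @param rd_grid_ms Rest-delay sweep grid.
#' @param k,fold_size Fold plan (full profile).
#' @param train_stride Training window stride.
#' @param epochs,patience,max_minutes Training stopping rules.
#' @param profile `"fast"` or `"full"`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_subjects = 21L, fs = 200,
                       correlation_threshold = 0.1,
                       model = model_config(seed = seed),
                       rd_grid_ms = seq(25, 1000, by = 25),
                       k = 7L, fold_size = 3L, train_stride = 4L,
                       epochs = 100L, patience = 10L, max_minutes = 5,
                       profile = c("fast", "full")) {
  profile <- match.arg(profile)
  structure(list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects), fs = fs,
    correlation_threshold = correlation_threshold, model = model,
    rd_grid_ms = rd_grid_ms, k = as.integer(k),
    fold_size = as.integer(fold_size), train_stride = as.integer(train_stride),
    epochs = as.integer(epochs), patience = as.integer(patience),
    max_minutes = max_minutes,
    profile = profile
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file; keys mirror the [run_config()] and [model_config()]
#'   arguments (model parameters under a `model:` block).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  model_args <- raw$model %||% list()
  raw$model <- NULL
  raw$model <- do.call(model_config, model_args)
  do.call(run_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full step-counting pipeline
#'
#' Simulates the cohort, preprocesses every subject, selects channels by
#' correlation with foot status, trains and evaluates the classifier
#' (cross-validated or single split depending on the profile), and sweeps
#' the rest delay. Intermediates and a provenance manifest (config, seeds,
#' package version) are written under `out_dir` when given.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return A list: `ranking` (channel ranking), `channels`, `report`
#'   (eval results), `cohort_steps` (ground-truth step counts), `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  message("stage simulate: ", cfg$n_subjects, " subjects")
  cohort <- simulate_cohort(cfg$n_subjects, seed = cfg$seed, fs = cfg$fs)
  message("stage preprocess")
  enriched <- enrich_cohort(cohort)
  truth_steps <- vapply(cohort, function(s) s$truth$n_steps, numeric(1))

  message("stage select")
  ranking <- select_channels(enriched, threshold = cfg$correlation_threshold)
  channels <- retained_channels(ranking)

  message("stage train/evaluate (profile: ", cfg$profile, ")")
  if (cfg$profile == "full") {
    plan <- make_folds(seq_len(cfg$n_subjects), k = cfg$k,
                       fold_size = cfg$fold_size, seed = cfg$seed)
    report <- cross_validate(enriched, truth_steps, cfg$model, plan,
                             channels = channels, fs = cfg$fs,
                             train_stride = cfg$train_stride,
                             epochs = cfg$epochs, patience = cfg$patience,
                             max_minutes = cfg$max_minutes,
                             rd_grid_ms = cfg$rd_grid_ms)
  } else {
    ids <- withr::with_seed(cfg$seed, sample(seq_len(cfg$n_subjects)))
    n_test <- max(1L, round(cfg$n_subjects / 7))
    report <- evaluate_split(enriched, truth_steps, cfg$model,
                             train_ids = ids[-seq_len(n_test)],
                             test_ids = ids[seq_len(n_test)],
                             channels = channels, fs = cfg$fs,
                             train_stride = cfg$train_stride,
                             epochs = cfg$epochs, patience = cfg$patience,
                             max_minutes = cfg$max_minutes,
                             rd_grid_ms = cfg$rd_grid_ms)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("solestep")),
    seed = cfg$seed, n_subjects = cfg$n_subjects, fs = cfg$fs,
    profile = cfg$profile, channels = channels,
    model = unclass(cfg$model), train_stride = cfg$train_stride,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  result <- list(ranking = ranking, channels = channels, report = report,
                 cohort_steps = truth_steps, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(
      list(ranking = as.data.frame(ranking)[, c("channel", "r", "abs_r",
                                                "retained")]),
      file.path(out_dir, "ranking.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    rep_out <- if (inherits(report, "eval_report")) {
      list(per_fold = as.data.frame(report$per_fold),
           mean_mape_dl = report$mean_mape_dl,
           mean_mape_g = report$mean_mape_g, rd_ms = report$rd_ms,
           rd_curve = as.data.frame(report$rd_curve))
    } else {
      list(mape_dl = report$mape_dl, mape_g = report$mape_g,
           rd_ms = report$rd_ms, rd_curve = as.data.frame(report$rd_curve))
    }
    jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' Write ground truth as JSON
#' @param truth A `gait_truth`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    subject_id = truth$subject_id,
    n_steps = truth$n_steps,
    step_event_times = truth$step_event_times,
    flat_intervals = as.data.frame(truth$flat_intervals)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
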