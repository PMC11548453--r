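# Two-stage hyperparameter search over the model design space: a random
# exploration stage followed by local perturbation of the incumbent best
# under a decaying temperature, each trial trained on a data subsample with
# the standard early-stopping rules.

#' The model design space
#'
#' Candidate grids for the 9 tunable parameters. The printed design space
#' gives only ranges and grid sizes; the realized grid points are explicit
#' here and overridable. Learning rates are log-spaced; batch sizes follow
#' a doubling ladder (with 192 inserted) so the grid has 7 values.
#'
#' @param ... Named grid overrides, e.g. `dropout = c(0.1, 0.3)`.
#' @return A `search_space`: named list of candidate vectors.
#' @export
search_space <- function(...) {
  space <- list(
    n_lstm_units = c(16L, 32L, 64L, 96L, 128L),
    n_lstm_layers = 1:3,
    dense_layer_active = c(FALSE, TRUE),
    n_dense_units = c(8L, 22L, 36L, 50L, 64L),
    input_window_ms = seq(25, 250, by = 25),
    dropout = seq(0.1, 0.5, by = 0.1),
    lstm_activation = c("relu", "sigmoid", "tanh"),
    learning_rate = 10^seq(-4, -2, length.out = 20),
    batch_size = c(64L, 128L, 192L, 256L, 512L, 1024L, 2048L)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(space)) stop("unknown parameter: ", nm, call. = FALSE)
    space[[nm]] <- overrides[[nm]]
  }
  structure(space, class = "search_space")
}

#' Cardinality of the design space
#'
#' Product of the per-parameter grid sizes; the default space enumerates
#' 3,150,000 combinations.
#'
#' @param space A [search_space()].
#' @return Number of distinct configurations.
#' @export
count_combinations <- function(space) {
  sizes <- vapply(space, length, numeric(1))
  if (any(sizes == 0)) {
    warning("empty grid for: ", paste(names(space)[sizes == 0], collapse = ", "))
    return(0)
  }
  prod(sizes)
}

#' Random subsample of a windowed dataset
#'
#' Uniform random subset of `round(fraction * N)` windows, reproducible per
#' seed; used to speed up search trials.
#'
#' @param ds A `windowed_dataset`.
#' @param fraction Fraction in (0, 1].
#' @param seed RNG seed.
#' @return The subsampled `windowed_dataset`.
#' @export
subsample_windows <- function(ds, fraction = 0.25, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (fraction == 1) return(ds)
  n <- length(ds$y)
  withr::with_seed(seed, {
    idx <- sort(sample.int(n, round(fraction * n)))
  })
  subset_windows(ds, idx)
}

# Internal: config from grid indices
.cfg_from_idx <- function(space, idx, seed = 1L) {
  vals <- lapply(names(space), function(nm) space[[nm]][idx[[nm]]])
  names(vals) <- names(space)
  do.call(model_config, c(vals, list(seed = seed)))
}

#' Two-stage hyperparameter search
#'
#' Stage 1 draws `ceiling(frac_random * budget)` configurations uniformly at
#' random from the grids. Stage 2 refines the incumbent best locally: single
#' parameters are stepped to adjacent grid values, a direction that improves
#' the objective being pursued until exhausted (stochastic coordinate
#' descent), interleaved with exploratory random jumps whose probability and
#' magnitude are governed by a temperature decaying linearly from 1 to
#' `temp_floor` over the stage. The best configuration by objective value is
#' returned.
#'
#' @param space A [search_space()].
#' @param objective Function `f(model_config) -> numeric` to minimize
#'   (typically a validation loss; see [make_tune_objective()]).
#' @param budget_trials Total number of trials (>= 2).
#' @param frac_random Fraction of the budget given to random search.
#' @param seed RNG seed; the trial sequence is reproducible.
#' @param temp_floor Final temperature.
#' @return A `tune_result`: `best_config`, `best_loss`, `trials` tibble
#'   (per-trial grid indices, loss, stage).
#' @export
two_stage_search <- function(space, objective, budget_trials = 40L,
                             frac_random = 0.25, seed = 1L, temp_floor = 0.2) {
  if (budget_trials < 2L) stop("budget_trials must be >= 2", call. = FALSE)
  n_random <- ceiling(frac_random * budget_trials)
  n_local <- budget_trials - n_random
  p_names <- names(space)
  sizes <- vapply(space, length, integer(1))

  withr::with_seed(seed, {
    trials <- vector("list", budget_trials)
    best_idx <- NULL
    best_loss <- Inf
    movable <- p_names[sizes > 1L]
    record <- function(tr, stage, idx, loss) {
      trials[[tr]] <<- do.call(tibble::tibble, c(
        list(trial = tr, stage = stage, loss = loss),
        stats::setNames(lapply(p_names, function(nm) idx[[nm]]), p_names)
      ))
      if (loss < best_loss) {
        best_loss <<- loss
        best_idx <<- idx
        TRUE
      } else FALSE
    }

    # stage 1: uniform random exploration of the grids
    for (tr in seq_len(n_random)) {
      idx <- stats::setNames(
        lapply(p_names, function(nm) sample.int(sizes[[nm]], 1L)), p_names)
      record(tr, "random", idx, objective(.cfg_from_idx(space, idx, seed = seed)))
    }

    # stage 2: coordinate refinement around the incumbent, with exploratory
    # jumps whose rate/magnitude shrink with the temperature
    ord <- sample(movable)
    pos <- 1L
    cur <- NULL
    dir <- 1L
    tried_flip <- FALSE
    for (tr in n_random + seq_len(n_local)) {
      temp <- 1 - (1 - temp_floor) * (tr - n_random - 1L) / max(1L, n_local - 1L)
      if (is.null(cur) && stats::runif(1) < 0.15 * temp) {
        idx <- best_idx
        nm <- sample(movable, 1L)
        mag <- max(1L, round(abs(stats::rnorm(1)) * temp * (sizes[[nm]] - 1L) / 2))
        prop <- idx[[nm]] + sample(c(-1L, 1L), 1L) * mag
        idx[[nm]] <- min(max(prop, 1L), sizes[[nm]])
        record(tr, "local", idx,
               objective(.cfg_from_idx(space, idx, seed = seed)))
        next
      }
      if (is.null(cur)) {
        cur <- ord[pos]
        pos <- pos + 1L
        if (pos > length(ord)) {
          ord <- sample(movable)
          pos <- 1L
        }
        dir <- sample(c(-1L, 1L), 1L)
        tried_flip <- FALSE
      }
      prop <- best_idx[[cur]] + dir
      if (prop < 1L || prop > sizes[[cur]]) {
        if (!tried_flip) {
          dir <- -dir
          tried_flip <- TRUE
          prop <- best_idx[[cur]] + dir
        }
        if (prop < 1L || prop > sizes[[cur]]) {
          cur <- NULL
          # spend the trial re-evaluating a fresh random probe near the best
          idx <- best_idx
          nm <- sample(movable, 1L)
          idx[[nm]] <- min(max(idx[[nm]] + sample(c(-1L, 1L), 1L), 1L),
                           sizes[[nm]])
          record(tr, "local", idx,
                 objective(.cfg_from_idx(space, idx, seed = seed)))
          next
        }
      }
      idx <- best_idx
      idx[[cur]] <- prop
      improved <- record(tr, "local", idx,
                         objective(.cfg_from_idx(space, idx, seed = seed)))
      if (!improved) {
        if (!tried_flip) {
          dir <- -dir
          tried_flip <- TRUE
        } else {
          cur <- NULL
        }
      }
    }
    structure(list(
      best_config = .cfg_from_idx(space, best_idx, seed = seed),
      best_idx = best_idx,
      best_loss = best_loss,
      trials = do.call(rbind, trials)
    ), class = "tune_result")
  })
}

#' Build the real search objective: validation loss on a data subsample
#'
#' Returns a function mapping a [model_config()] to the best validation loss
#' reached when training on a random 25% subsample of the training windows,
#' under the standard stopping rules.
#'
#' @param train,val Normalized `windowed_dataset`s.
#' @param fraction Subsample fraction of the training windows.
#' @param epochs,patience,max_minutes Stopping rules per trial.
#' @param seed Subsample seed.
#' @return Function `f(cfg) -> validation loss`.
#' @export
make_tune_objective <- function(train, val, fraction = 0.25, epochs = 100L,
                                patience = 10L, max_minutes = 5, seed = 1L) {
  sub <- subsample_windows(train, fraction, seed = seed)
  w_built <- dim(sub$x)[3L]
  truncate_to <- function(ds, w) {
    if (w >= dim(ds$x)[3L]) return(ds)
    ds$x <- ds$x[, , (dim(ds$x)[3L] - w + 1L):dim(ds$x)[3L], drop = FALSE]
    ds
  }
  function(cfg) {
    # windows are pre-built at the space's maximum length; a trial with a
    # shorter input window keeps the most recent w samples of each window
    w <- min(w_built, round(cfg$input_window_ms * sub$fs / 1000))
    tr_ds <- truncate_to(sub, w)
    va_ds <- truncate_to(val, w)
    model <- build_model(cfg, dim(tr_ds$x)[2L])
    model <- train_model(model, tr_ds, va_ds, epochs = epochs,
                         patience = patience, max_minutes = max_minutes)
    model$best_val_loss
  }
}

#' Finalize a search: full-data cross-validation with the best configuration
#'
#' @param best_cfg The winning [model_config()].
#' @param enriched,truth_steps,plan As in [cross_validate()].
#' @param ... Passed on to [cross_validate()].
#' @return An `eval_report` whose `cfg` is `best_cfg`.
#' @export
finalize_search <- function(best_cfg, enriched, truth_steps, plan, ...) {
  cross_validate(enriched, truth_steps, best_cfg, plan, ...)
}
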