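# Windowed many-to-one LSTM foot-flat classifier: configuration, window
# construction, normalization, model building, training and prediction.
# The numerical core (BPTT + Adam) lives in src/lstm.cpp.

.ACTIVATIONS <- c(tanh = 0L, sigmoid = 1L, relu = 2L)

#' Model configuration
#'
#' Hyperparameters of the foot-flat classifier. Defaults are the optimized
#' configuration: 32 units, 2 LSTM layers, no intermediate dense layer,
#' 125 ms input window, dropout 0.2, tanh activation, learning rate 1e-2,
#' batch size 1024.
#'
#' @param n_lstm_units Units per LSTM layer.
#' @param n_lstm_layers Number of stacked LSTM layers (intermediate layers
#'   emit full sequences, the last emits its final state).
#' @param dense_layer_active Insert a relu dense layer before the output?
#' @param n_dense_units Units of that dense layer.
#' @param input_window_ms Length of the window of anterior data (ms).
#' @param dropout Dropout rate applied to the final LSTM state in training.
#' @param lstm_activation One of `"tanh"`, `"sigmoid"`, `"relu"` (cell input
#'   and state activation; gates are always sigmoid).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param decision_threshold Probability threshold for calling foot-flat.
#' @param clipnorm Global gradient-norm clip (0 disables).
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(n_lstm_units = 32L, n_lstm_layers = 2L,
                         dense_layer_active = FALSE, n_dense_units = 8L,
                         input_window_ms = 125, dropout = 0.2,
                         lstm_activation = "tanh", learning_rate = 1e-2,
                         batch_size = 1024L, decision_threshold = 0.5,
                         clipnorm = 10, seed = 1L) {
  if (!lstm_activation %in% names(.ACTIVATIONS)) {
    stop("lstm_activation must be one of ",
         paste(names(.ACTIVATIONS), collapse = ", "), call. = FALSE)
  }
  stopifnot(n_lstm_units >= 1, n_lstm_layers >= 1, input_window_ms > 0,
            dropout >= 0, dropout < 1, learning_rate > 0, batch_size >= 1)
  structure(list(
    n_lstm_units = as.integer(n_lstm_units),
    n_lstm_layers = as.integer(n_lstm_layers),
    dense_layer_active = isTRUE(dense_layer_active),
    n_dense_units = as.integer(n_dense_units),
    input_window_ms = input_window_ms,
    dropout = dropout,
    lstm_activation = lstm_activation,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    decision_threshold = decision_threshold,
    clipnorm = clipnorm,
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Build sliding windows over an enriched recording
#'
#' Cuts the retained channels into windows of `w = round(window_ms * fs /
#' 1000)` samples ending at each labeled sample (every `stride`-th candidate
#' endpoint); the label of a window is the foot status of its final sample.
#' Windows whose final sample is undetermined (status 2) are excluded, but
#' undetermined samples may still appear inside a window whose endpoint is
#' determined.
#'
#' @param enr An `enriched_recording` (with its undetermined rows still
#'   present), or a list of them; windows never span recordings.
#' @param channels Character vector of channel columns to use.
#' @param window_ms Window length in ms.
#' @param fs Sampling rate (Hz).
#' @param stride Endpoint stride in samples (thins training examples only).
#' @param keep_undetermined Keep windows whose final sample is undetermined
#'   (label stays 2)? Used for deployment-style prediction streams that must
#'   cover every sample; training and label metrics always exclude them.
#' @return A `windowed_dataset`: list with `x` (array `n x channels x w`),
#'   `y` (0/1 labels, or 2 where kept), `end_times` (s), `channels`,
#'   `window_ms`, `fs`.
#' @export
make_windows <- function(enr, channels, window_ms, fs = 200, stride = 1L,
                         keep_undetermined = FALSE) {
  if (!is.data.frame(enr)) {
    parts <- lapply(enr, make_windows, channels = channels,
                    window_ms = window_ms, fs = fs, stride = stride,
                    keep_undetermined = keep_undetermined)
    return(bind_windows(parts))
  }
  w <- round(window_ms * fs / 1000)
  if (w < 1L) stop("window shorter than one sample", call. = FALSE)
  n <- nrow(enr)
  if (w > n) stop("window length ", w, " exceeds recording length ", n,
                  call. = FALSE)
  missing_ch <- setdiff(channels, names(enr))
  if (length(missing_ch) > 0L) {
    stop("channels not in recording: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  ends <- seq.int(w, n, by = stride)
  if (!keep_undetermined) ends <- ends[enr$foot_status[ends] != 2L]
  x <- array(0, dim = c(length(ends), length(channels), w))
  for (ci in seq_along(channels)) {
    series <- enr[[channels[ci]]]
    for (t in seq_len(w)) {
      x[, ci, t] <- series[ends - w + t]
    }
  }
  structure(list(
    x = x,
    y = as.integer(enr$foot_status[ends]),
    end_times = enr$time_s[ends],
    channels = channels, window_ms = window_ms, fs = fs
  ), class = "windowed_dataset")
}

#' Concatenate windowed datasets
#' @param parts List of `windowed_dataset`s with identical channels/window.
#' @return One combined `windowed_dataset`.
#' @export
bind_windows <- function(parts) {
  stopifnot(length(parts) >= 1L)
  x0 <- parts[[1L]]
  ns <- vapply(parts, function(p) dim(p$x)[1L], numeric(1))
  x <- array(0, dim = c(sum(ns), dim(x0$x)[2L], dim(x0$x)[3L]))
  at <- 0L
  for (p in parts) {
    n <- dim(p$x)[1L]
    if (n > 0L) x[at + seq_len(n), , ] <- p$x
    at <- at + n
  }
  structure(list(
    x = x, y = unlist(lapply(parts, `[[`, "y")),
    end_times = unlist(lapply(parts, `[[`, "end_times")),
    channels = x0$channels, window_ms = x0$window_ms, fs = x0$fs
  ), class = "windowed_dataset")
}

#' Subset a windowed dataset by window index
#' @param ds A `windowed_dataset`.
#' @param idx Integer indices of the windows to keep.
#' @return The subsetted `windowed_dataset`.
#' @export
subset_windows <- function(ds, idx) {
  structure(list(
    x = ds$x[idx, , , drop = FALSE], y = ds$y[idx],
    end_times = ds$end_times[idx],
    channels = ds$channels, window_ms = ds$window_ms, fs = ds$fs
  ), class = "windowed_dataset")
}

#' Fit / apply a per-channel z-score normalizer
#'
#' Statistics must come from training folds only; the held-out data is then
#' scaled with the training statistics. A zero-variance channel has its sd
#' clamped to 1 (with a warning), so a constant channel maps to zeros.
#'
#' @param train A `windowed_dataset` of training windows.
#' @return `fit_normalizer` returns a list with per-channel `mean` and `sd`.
#' @export
fit_normalizer <- function(train) {
  nc <- dim(train$x)[2L]
  mu <- sdv <- numeric(nc)
  for (ci in seq_len(nc)) {
    v <- as.numeric(train$x[, ci, ])
    mu[ci] <- mean(v)
    sdv[ci] <- stats::sd(v)
  }
  if (any(sdv == 0)) {
    warning("zero-variance channel(s): sd clamped to 1")
    sdv[sdv == 0] <- 1
  }
  list(mean = mu, sd = sdv)
}

#' @rdname fit_normalizer
#' @param ds Dataset to normalize.
#' @param stats Output of `fit_normalizer`.
#' @export
apply_normalizer <- function(ds, stats) {
  for (ci in seq_len(dim(ds$x)[2L])) {
    ds$x[, ci, ] <- (ds$x[, ci, ] - stats$mean[ci]) / stats$sd[ci]
  }
  ds
}

# Glorot-uniform matrix
.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build an untrained foot-flat classifier
#'
#' Stacks `n_lstm_layers` LSTM layers (intermediate layers emit full
#' sequences, the last its final state), dropout on the final state, an
#' optional relu dense layer, and a single sigmoid output unit producing
#' P(foot flat). Weights are Glorot-uniform, forget-gate biases start at 1.
#'
#' @param cfg A [model_config()].
#' @param n_channels Number of input channels.
#' @return A `footflat_model` (untrained).
#' @export
build_model <- function(cfg, n_channels) {
  u <- cfg$n_lstm_units
  withr::with_seed(cfg$seed, {
    layers <- vector("list", cfg$n_lstm_layers)
    d_in <- n_channels
    for (l in seq_len(cfg$n_lstm_layers)) {
      b <- matrix(0, 1, 4 * u)
      b[1, (u + 1):(2 * u)] <- 1        # forget-gate bias
      layers[[l]] <- list(W = .glorot(d_in, 4 * u), U = .glorot(u, 4 * u), b = b)
      d_in <- u
    }
    dense <- NULL
    if (cfg$dense_layer_active) {
      dense <- list(W = .glorot(u, cfg$n_dense_units),
                    b = matrix(0, 1, cfg$n_dense_units))
      d_in <- cfg$n_dense_units
    }
    out <- list(w = matrix(stats::runif(d_in, -0.1, 0.1), d_in, 1),
                b = matrix(0, 1, 1))
    structure(list(
      cfg = cfg, n_channels = n_channels,
      weights = list(layers = layers, dense = dense, out = out),
      trained = FALSE, history = NULL
    ), class = "footflat_model")
  })
}

#' Number of trainable parameters
#' @param model A `footflat_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  cnt <- function(x) if (is.null(x)) 0L else sum(vapply(x, length, integer(1)))
  sum(vapply(model$weights$layers, cnt, integer(1))) +
    cnt(model$weights$dense) + cnt(model$weights$out)
}

#' Train the foot-flat classifier
#'
#' Minimizes binary cross-entropy with Adam at the configured learning rate
#' and batch size. Training halts at `epochs` epochs, or after `patience`
#' epochs without validation-loss improvement, or at the wall-clock budget
#' `max_minutes`, whichever comes first; the weights with the best validation
#' loss are restored.
#'
#' @param model An untrained or trained `footflat_model`.
#' @param train,val Normalized `windowed_dataset`s from disjoint window
#'   sources.
#' @param epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param max_minutes Wall-clock training budget in minutes (default 5).
#' @return The trained model with `history` (per-epoch losses), `best_epoch`
#'   and `stop_reason` (`"epochs"`, `"patience"` or `"time"`).
#' @export
train_model <- function(model, train, val, epochs = 100L, patience = 10L,
                        max_minutes = 5) {
  if (length(train$y) == 0L || length(val$y) == 0L) {
    stop("training and validation datasets must be non-empty", call. = FALSE)
  }
  if (dim(train$x)[2L] != model$n_channels) {
    stop("channel mismatch: model expects ", model$n_channels,
         " channels, data has ", dim(train$x)[2L], call. = FALSE)
  }
  cfg <- model$cfg
  ctl <- list(
    activation = .ACTIVATIONS[[cfg$lstm_activation]],
    dropout = cfg$dropout,
    learning_rate = cfg$learning_rate,
    batch_size = min(cfg$batch_size, length(train$y)),
    epochs = as.integer(epochs),
    patience = as.integer(patience),
    max_seconds = max_minutes * 60,
    clipnorm = cfg$clipnorm,
    seed = cfg$seed
  )
  fit <- cpp_lstm_fit(train$x, as.numeric(train$y), val$x, as.numeric(val$y),
                      model$weights, ctl)
  model$weights <- fit$weights
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$best_val_loss <- fit$best_val_loss
  model$stop_reason <- fit$stop_reason
  model$trained <- TRUE
  model
}

#' Predict foot-flat probabilities
#' @param model A trained `footflat_model`.
#' @param ds A normalized `windowed_dataset`.
#' @return Numeric vector of P(foot flat), one per window.
#' @export
predict_proba <- function(model, ds) {
  if (dim(ds$x)[2L] != model$n_channels) {
    stop("channel mismatch: model expects ", model$n_channels,
         " channels, data has ", dim(ds$x)[2L], call. = FALSE)
  }
  as.numeric(cpp_lstm_predict(ds$x, model$weights,
                              .ACTIVATIONS[[model$cfg$lstm_activation]]))
}

#' Predict a binary foot-status stream
#'
#' Thresholds the predicted probabilities: status 1 (foot flat) where
#' P(flat) >= `decision_threshold`. The stream is aligned to the windows'
#' end times.
#'
#' @param model A trained `footflat_model`.
#' @param ds A normalized `windowed_dataset`.
#' @param decision_threshold Threshold (default from the model config).
#' @return Integer 0/1 vector aligned with `ds$end_times`.
#' @export
predict_status <- function(model, ds,
                           decision_threshold = model$cfg$decision_threshold) {
  p <- predict_proba(model, ds)
  as.integer(p >= decision_threshold)
}

#' @export
print.footflat_model <- function(x, ...) {
  cfg <- x$cfg
  cat("<footflat_model> ", cfg$n_lstm_layers, " LSTM layer(s) x ",
      cfg$n_lstm_units, " units, window ", cfg$input_window_ms, " ms, ",
      format(n_parameters(x), big.mark = ","), " parameters, ",
      if (isTRUE(x$trained)) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}
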