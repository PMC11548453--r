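# Step extraction from a binary foot-status stream via the rest-delay
# refractory rule, plus the two MAPE performance criteria.

#' Count steps in a binary foot-status stream
#'
#' Scans the stream left to right; a step is registered at each 0-to-1
#' transition (the stream start counts as a preceding 0). After a
#' registration, further onsets within the rest delay `rd_ms` — the minimum
#' time after a foot-flat detection before another foot-flat phase can be
#' considered — are suppressed. The refractory clock starts at the registered
#' onset.
#'
#' @param status Integer/logical vector of 0/1 foot statuses.
#' @param fs Sampling rate of the stream in Hz.
#' @param rd_ms Rest delay in milliseconds (>= 0).
#' @param times Optional sample times in seconds (defaults to a uniform grid
#'   at `fs`); used when the stream has gaps (e.g. undetermined samples
#'   removed).
#' @return A `step_count_result`: list with `n_steps`, `event_times` (s),
#'   `rd_ms`.
#' @export
count_steps <- function(status, fs = 200, rd_ms = 0, times = NULL) {
  stopifnot(rd_ms >= 0, fs > 0)
  status <- as.integer(status)
  if (is.null(times)) times <- (seq_along(status) - 1L) / fs
  onsets <- which(diff(c(0L, status)) == 1L)
  rd_s <- rd_ms / 1000
  kept <- numeric(0)
  last <- -Inf
  for (i in onsets) {
    if (times[i] - last >= rd_s) {
      kept <- c(kept, times[i])
      last <- times[i]
    }
  }
  structure(list(n_steps = length(kept), event_times = kept, rd_ms = rd_ms),
            class = "step_count_result")
}

#' Global step-count mean absolute percentage error
#'
#' `MAPE_G = |n_predicted - n_observed| / n_observed`, the error between the
#' number of steps estimated by the algorithm and the number actually taken.
#'
#' @param n_pred Predicted step count.
#' @param n_obs Observed (ground-truth) step count, > 0.
#' @return The error as a fraction (multiply by 100 for percent).
#' @export
mape_g <- function(n_pred, n_obs) {
  if (any(n_obs <= 0)) stop("observed step count must be positive", call. = FALSE)
  abs(n_pred - n_obs) / n_obs
}

#' Foot-status (classifier output) mean absolute percentage error
#'
#' `MAPE_DL = |#flat_predicted - #flat_observed| / #flat_observed`, comparing
#' the number of samples labeled foot-flat in the predicted and observed
#' status streams (undetermined samples must already be excluded).
#'
#' @param pred_status,obs_status Aligned binary status vectors.
#' @return The error as a fraction.
#' @export
mape_dl <- function(pred_status, obs_status) {
  if (length(pred_status) != length(obs_status)) {
    stop("status streams must be aligned (equal length)", call. = FALSE)
  }
  n_obs <- sum(obs_status == 1L)
  if (n_obs == 0L) stop("no observed foot-flat samples: MAPE_DL undefined",
                        call. = FALSE)
  abs(sum(pred_status == 1L) - n_obs) / n_obs
}

#' Sweep the rest delay over a grid and pick the best value
#'
#' Evaluates the mean step-count error `MAPE_G` at each rest-delay grid point
#' (default 25 to 1000 ms in 25 ms steps, i.e. 40 points) over one or more
#' status streams, and returns the grid point minimizing the mean error, ties
#' broken toward the smaller rest delay.
#'
#' @param status A binary status vector, or a list of them (one per subject).
#' @param fs Sampling rate (Hz).
#' @param true_step_count Ground-truth step count(s), one per stream.
#' @param rd_grid_ms Rest-delay grid in ms.
#' @param times Optional list of sample-time vectors matching `status`.
#' @return An `rd_sweep`: list with `best_rd_ms`, `best_mape_g`, and `curve`
#'   (tibble `rd_ms`, `mape_g`).
#' @export
sweep_rd <- function(status, fs = 200, true_step_count,
                     rd_grid_ms = seq(25, 1000, by = 25), times = NULL) {
  if (length(rd_grid_ms) == 0L) stop("rd grid must be non-empty", call. = FALSE)
  if (!is.list(status)) status <- list(status)
  if (!is.null(times) && !is.list(times)) times <- list(times)
  stopifnot(length(true_step_count) == length(status))
  curve <- vapply(rd_grid_ms, function(rd) {
    errs <- vapply(seq_along(status), function(i) {
      n <- count_steps(status[[i]], fs = fs, rd_ms = rd,
                       times = if (is.null(times)) NULL else times[[i]])$n_steps
      mape_g(n, true_step_count[i])
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which(curve == min(curve))[1L]   # ties -> smaller rd (grid is sorted)
  structure(list(
    best_rd_ms = rd_grid_ms[best],
    best_mape_g = curve[best],
    curve = tibble::tibble(rd_ms = rd_grid_ms, mape_g = curve)
  ), class = "rd_sweep")
}
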