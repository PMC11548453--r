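# Channel selection: Pearson correlation of each candidate channel with the
# binary foot status, retaining channels at or above the 0.1 threshold.

.CANDIDATE_CHANNELS <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y",
                         "gyro_z", "acc_norm", "gyro_norm")

#' Pearson product-moment correlation
#'
#' Plain Pearson r, with the degenerate zero-variance case mapped to `NA`
#' (the channel is then reported as not computable and excluded from
#' selection) rather than an error.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return Correlation in `[-1, 1]`, or `NA` if either input has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input: correlation not computable")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Rank channels by correlation with foot status and select
#'
#' Pools samples across the supplied enriched recordings (undetermined rows
#' are dropped first), computes the Pearson correlation of each of the 8
#' candidate channels (3 acceleration axes, 3 gyroscope axes, 2 norms) with
#' the binary foot status, and retains channels whose correlation magnitude
#' is at least `threshold`. Selection is on |r|: a strongly negative channel
#' is as informative as a positive one.
#'
#' @param enr An `enriched_recording` or list of them (the cohort).
#' @param threshold Retention threshold on |r| (default 0.1).
#' @return A `channel_ranking`: tibble with `channel`, `r`, `abs_r`,
#'   `retained`, sorted by |r| descending; attribute `retained` holds the
#'   retained channel names.
#' @export
select_channels <- function(enr, threshold = 0.1) {
  if (!is.data.frame(enr)) {
    if (length(enr) == 0L) stop("no recordings supplied", call. = FALSE)
    enr <- do.call(rbind, lapply(enr, as.data.frame))
  }
  if (nrow(enr) == 0L) stop("no samples supplied", call. = FALSE)
  enr <- drop_undetermined(enr)
  y <- as.numeric(enr$foot_status)
  r <- vapply(.CANDIDATE_CHANNELS, function(ch) {
    suppressWarnings(pearson_r(enr[[ch]], y))
  }, numeric(1))
  if (any(is.na(r))) {
    warning("channels not computable (zero variance): ",
            paste(.CANDIDATE_CHANNELS[is.na(r)], collapse = ", "))
  }
  ranking <- tibble::tibble(
    channel = .CANDIDATE_CHANNELS,
    r = unname(r),
    abs_r = abs(unname(r))
  )
  ranking <- ranking[order(-ranking$abs_r, ranking$channel, na.last = TRUE), ]
  ranking$retained <- !is.na(ranking$abs_r) & ranking$abs_r >= threshold
  if (!any(ranking$retained)) {
    warning("no channel reaches the correlation threshold ", threshold)
  }
  structure(ranking, class = c("channel_ranking", class(ranking)),
            retained = ranking$channel[ranking$retained],
            threshold = threshold)
}

#' Retained channels of a ranking
#' @param ranking A `channel_ranking`.
#' @return Character vector of retained channel names (by decreasing |r|).
#' @export
retained_channels <- function(ranking) {
  attr(ranking, "retained")
}
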