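# Per-second feature extraction and sliding-window epoching.
#
# Each complete one-second bin of a trace is reduced to eight parameters: the
# mean and coefficient of variation of the three axes and of the resultant
# force. Bins are half-open [k, k+1) seconds anchored at the trace start; a
# trailing partial second is dropped. Epochs are L consecutive feature rows
# (default L = 9), advanced with a 1-s stride.

#' Resultant force of a three-axis acceleration sample
#'
#' Euclidean magnitude `sqrt(ax^2 + ay^2 + az^2)`; vectorised over samples.
#'
#' @param ax,ay,az axis accelerations in g.
#' @return non-negative magnitude(s) in g.
#' @examples
#' resultant_force(3, 4, 0) # 5
#' @export
resultant_force <- function(ax, ay, az) {
  if (any(!is.finite(ax)) || any(!is.finite(ay)) || any(!is.finite(az)))
    stop("non-finite acceleration input", call. = FALSE)
  sqrt(ax^2 + ay^2 + az^2)
}

#' Coefficient of variation with a near-zero-mean guard
#'
#' Population standard deviation (divide by n) over the absolute mean, with the
#' denominator floored at `mean_floor` so that axes hovering around 0 g (X and
#' Y at rest) yield a bounded, monotone variability measure instead of an
#' exploding ratio.
#'
#' @param values numeric vector, length >= 2.
#' @param mean_floor denominator floor in the units of `values` (default 0.05 g).
#' @return non-negative dimensionless ratio.
#' @export
coefficient_of_variation <- function(values, mean_floor = 0.05) {
  if (length(values) < 2L)
    stop("coefficient of variation requires at least 2 values", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite input", call. = FALSE)
  stopifnot_scalar_number(mean_floor, "mean_floor", positive = TRUE)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  s / max(abs(m), mean_floor)
}

#' Per-second eight-parameter feature series
#'
#' Cuts the trace into complete, non-overlapping 1-s bins and computes, for
#' each bin, the mean and coefficient of variation of X, Y, Z and the
#' resultant force (`floor(duration)` rows; any trailing partial second is
#' dropped). Standard deviations are population form; CV denominators are
#' floored at `mean_floor` (see [coefficient_of_variation()]).
#'
#' @param trace an [accel_trace()] of duration >= 1 s.
#' @param mean_floor CV denominator floor in g.
#' @return data.frame with columns `second` (0-based) and
#'   `mean_x, mean_y, mean_z, mean_r, cv_x, cv_y, cv_z, cv_r`.
#' @export
per_second_features <- function(trace, mean_floor = 0.05) {
  stopifnot(inherits(trace, "accel_trace"))
  stopifnot_scalar_number(mean_floor, "mean_floor", positive = TRUE)
  rate <- trace$sampling_rate_hz
  n <- nrow(trace$samples)
  nb <- floor(n / rate)
  if (nb < 1L)
    stop(sprintf("trace duration %.3f s is shorter than one second", n / rate),
         call. = FALSE)
  idx <- floor((seq_len(n) - 1L) / rate)
  keep <- idx < nb
  grp <- idx[keep] + 1L
  s <- trace$samples[keep, , drop = FALSE]
  x <- cbind(s, r = sqrt(rowSums(s^2)))
  cnt <- tabulate(grp, nbins = nb)
  mu <- rowsum(x, grp, reorder = TRUE) / cnt
  ex2 <- rowsum(x^2, grp, reorder = TRUE) / cnt
  sd_ <- sqrt(pmax(ex2 - mu^2, 0))
  cv <- sd_ / pmax(abs(mu), mean_floor)
  out <- data.frame(second = 0:(nb - 1L),
                    mean_x = mu[, 1L], mean_y = mu[, 2L], mean_z = mu[, 3L],
                    mean_r = mu[, 4L],
                    cv_x = cv[, 1L], cv_y = cv[, 2L], cv_z = cv[, 3L],
                    cv_r = cv[, 4L])
  rownames(out) <- NULL
  attr(out, "mean_floor") <- mean_floor
  out
}

#' Cut a feature series into fixed-length epochs
#'
#' Windows of `length_s` consecutive per-second feature rows, starting at
#' 0, `stride_s`, `2*stride_s`, ... while a full window fits:
#' `floor((T - length_s)/stride_s) + 1` epochs for `T >= length_s`, else none.
#' Returns a compact `epoch_set`; individual epochs (a `length_s` x 8 feature
#' matrix with a `start_second` attribute) are materialised with `[[`.
#'
#' @param features per-second feature data.frame from [per_second_features()].
#' @param length_s epoch length in seconds (the classification unit; default 9).
#' @param stride_s window advance in seconds (default 1).
#' @return an `epoch_set` supporting `length()`, `[[` and `epoch_starts()`.
#' @examples
#' tr <- accel_trace(matrix(rnorm(50 * 12 * 3, sd = 0.1), ncol = 3))
#' ep <- make_epochs(per_second_features(tr))
#' length(ep) # 4
#' @export
make_epochs <- function(features, length_s = 9, stride_s = 1) {
  stopifnot_scalar_number(length_s, "length_s", positive = TRUE, integer = TRUE)
  stopifnot_scalar_number(stride_s, "stride_s", positive = TRUE, integer = TRUE)
  m <- feature_matrix(features)
  secs <- feature_seconds(features)
  n <- nrow(m)
  starts <- if (n >= length_s) seq.int(0L, n - length_s, by = stride_s)
            else integer(0)
  structure(
    list(features = m, seconds = secs, starts = as.integer(starts),
         length_s = as.integer(length_s), stride_s = as.integer(stride_s)),
    class = "epoch_set")
}

#' @export
length.epoch_set <- function(x) length(x$starts)

#' Start seconds of each epoch in an epoch set
#' @param x an `epoch_set`.
#' @return integer vector of epoch start seconds.
#' @export
epoch_starts <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  x$seconds[x$starts + 1L]
}

#' @export
`[[.epoch_set` <- function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > length(x$starts)) stop("epoch index out of range", call. = FALSE)
  rows <- (x$starts[i] + 1L):(x$starts[i] + x$length_s)
  ep <- x$features[rows, , drop = FALSE]
  attr(ep, "start_second") <- x$seconds[x$starts[i] + 1L]
  ep
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epoch(s) of %d s (stride %d s) over %d feature rows\n",
              length(x$starts), x$length_s, x$stride_s, nrow(x$features)))
  invisible(x)
}

#' Write a per-second feature series to CSV
#' @param features data.frame from [per_second_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features[, c("second", FEATURE_COLS)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-second feature series from CSV
#' @param path CSV written by [write_features_csv()].
#' @return feature data.frame.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("second", FEATURE_COLS), names(df))
  if (length(missing) > 0L)
    stop("feature CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}
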