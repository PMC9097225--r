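# Reading, writing and validating accelerometer traces and label tracks.
#
# CSV dialect: header `time,ax,ay,az`, one `# start=<ISO8601>` comment line,
# time in seconds from recording start, axis values in g, '.' decimal point,
# LF line endings. Label CSV: header `label,start_s,end_s`.

#' Construct a three-axis acceleration trace
#'
#' An `accel_trace` holds a uniformly sampled three-axis acceleration series in
#' sensor units of g, together with its sampling-rate and device-range
#' metadata. The axis convention follows an interscapular mount: X
#' craniocaudal, Y lateral, Z dorsoventral. Samples outside the device range
#' are clipped to the range with a warning, mirroring how a real sensor
#' saturates rather than rejecting the recording.
#'
#' @param samples numeric matrix with `n` rows and 3 columns (ax, ay, az), in g.
#' @param sampling_rate_hz sampling frequency in Hz (nominal 50).
#' @param start_time recording start as `POSIXct`, or `NULL` for unknown.
#' @param device_range_g symmetric sensor range in g (nominal 8).
#' @return an object of class `accel_trace`.
#' @examples
#' tr <- accel_trace(matrix(c(0, 0, 1), 100, 3, byrow = TRUE))
#' trace_duration(tr)
#' @export
accel_trace <- function(samples, sampling_rate_hz = 50, start_time = NULL,
                        device_range_g = 8) {
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  stopifnot_scalar_number(device_range_g, "device_range_g", positive = TRUE)
  if (is.null(samples)) samples <- matrix(numeric(0), 0L, 3L)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("'samples' must have exactly 3 columns (ax, ay, az)", call. = FALSE)
  storage.mode(samples) <- "double"
  colnames(samples) <- c("ax", "ay", "az")
  if (nrow(samples) > 0L && any(!is.finite(samples)))
    stop("non-finite acceleration samples", call. = FALSE)
  over <- abs(samples) > device_range_g
  if (any(over)) {
    warning(sprintf("%d sample value(s) outside +/-%g g clipped to device range",
                    sum(over), device_range_g), call. = FALSE)
    samples[samples > device_range_g] <- device_range_g
    samples[samples < -device_range_g] <- -device_range_g
  }
  if (!is.null(start_time)) start_time <- as.POSIXct(start_time, tz = "UTC")
  structure(
    list(samples = samples, sampling_rate_hz = sampling_rate_hz,
         start_time = start_time, device_range_g = device_range_g),
    class = "accel_trace")
}

#' Trace duration in seconds
#'
#' Duration is defined as `n_samples / sampling_rate_hz` exactly.
#'
#' @param trace an [accel_trace()].
#' @return duration in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  nrow(trace$samples) / trace$sampling_rate_hz
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.2f s), range +/-%g g\n",
              nrow(x$samples), x$sampling_rate_hz, trace_duration(x),
              x$device_range_g))
  if (!is.null(x$start_time))
    cat("  start:", format(x$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), "\n")
  invisible(x)
}

#' Read an accelerometer CSV recording
#'
#' Parses the package CSV dialect (columns `time, ax, ay, az`; time in seconds
#' from start; an optional `# start=<ISO8601>` comment). Timestamp spacing is
#' checked against the expected rate: any step deviating from `1/rate` by more
#' than `tol/rate` is a sampling-rate error naming the offending row, never a
#' silent resample.
#'
#' @param path CSV file path.
#' @param expected_rate_hz nominal sampling rate in Hz.
#' @param device_range_g sensor range metadata attached to the trace.
#' @param tol relative spacing tolerance (fraction of the sample interval).
#' @return an [accel_trace()].
#' @export
read_accel_csv <- function(path, expected_rate_hz = 50, device_range_g = 8,
                           tol = 0.2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot_scalar_number(expected_rate_hz, "expected_rate_hz", positive = TRUE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty accelerometer file: ", path, call. = FALSE)
  start_time <- NULL
  header <- readLines(path, n = 5L)
  start_line <- grep("^# *start=", header, value = TRUE)
  if (length(start_line) > 0L) {
    iso <- sub("^# *start=", "", start_line[1L])
    start_time <- as.POSIXct(iso, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time", "ax", "ay", "az")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("accelerometer CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty accelerometer file: ", path, call. = FALSE)
  for (col in need) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' is not numeric", col), call. = FALSE)
  }
  dt_nom <- 1 / expected_rate_hz
  if (nrow(df) > 1L) {
    dt <- diff(df$time)
    bad <- which(abs(dt - dt_nom) > tol * dt_nom)
    if (length(bad) > 0L)
      stop(sprintf(
        "sampling-rate error: gap of %.6g s between rows %d and %d (expected %.6g s)",
        dt[bad[1L]], bad[1L], bad[1L] + 1L, dt_nom), call. = FALSE)
  }
  accel_trace(as.matrix(df[, c("ax", "ay", "az")]),
              sampling_rate_hz = expected_rate_hz,
              start_time = start_time, device_range_g = device_range_g)
}

#' Write an accelerometer trace to CSV
#'
#' Deterministic formatting (`%.17g`, full double precision) so that
#' `read_accel_csv(write_accel_csv(x))` reproduces the samples exactly.
#'
#' @param trace an [accel_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  start <- if (is.null(trace$start_time)) as.POSIXct(0, origin = "1970-01-01", tz = "UTC")
           else trace$start_time
  writeLines(sprintf("# start=%s", format(start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
             con, sep = "\n")
  writeLines("time,ax,ay,az", con, sep = "\n")
  n <- nrow(trace$samples)
  if (n > 0L) {
    t <- (seq_len(n) - 1L) / trace$sampling_rate_hz
    lines <- sprintf("%.17g,%.17g,%.17g,%.17g", t,
                     trace$samples[, 1L], trace$samples[, 2L], trace$samples[, 3L])
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read labelled movement/seizure intervals
#'
#' @param path CSV with columns `label, start_s, end_s`.
#' @return data.frame sorted by `start_s`, class `label_intervals`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(c("label", "start_s", "end_s"), names(df))
  if (length(missing) > 0L)
    stop("label CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  label_intervals(df$label, df$start_s, df$end_s)
}

#' Construct and validate a label-interval track
#'
#' Intervals carrying the same label must not overlap; every interval must
#' satisfy `end_s > start_s >= 0`.
#'
#' @param label character vector of class names.
#' @param start_s,end_s interval bounds in seconds from trace start.
#' @return data.frame sorted by `start_s`, class `label_intervals`.
#' @export
label_intervals <- function(label, start_s, end_s) {
  df <- data.frame(label = as.character(label),
                   start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    if (any(!is.finite(df$start_s)) || any(!is.finite(df$end_s)))
      stop("non-finite interval bound", call. = FALSE)
    if (any(df$start_s < 0))
      stop("interval start_s must be >= 0", call. = FALSE)
    bad <- which(df$end_s <= df$start_s)
    if (length(bad) > 0L)
      stop(sprintf("interval %d ('%s') has end_s <= start_s", bad[1L],
                   df$label[bad[1L]]), call. = FALSE)
    df <- df[order(df$start_s, df$end_s), , drop = FALSE]
    for (lb in unique(df$label)) {
      sub <- df[df$label == lb, , drop = FALSE]
      if (nrow(sub) > 1L && any(sub$start_s[-1L] < sub$end_s[-nrow(sub)]))
        stop(sprintf("overlapping intervals in label track '%s'", lb),
             call. = FALSE)
    }
    rownames(df) <- NULL
  }
  class(df) <- c("label_intervals", "data.frame")
  df
}

#' Write a label track to CSV
#'
#' @param labels a `label_intervals` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(as.data.frame(labels)[, c("label", "start_s", "end_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
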