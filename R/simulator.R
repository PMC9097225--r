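# Seeded synthetic canine accelerometry.
#
# Signal model per axis: gravity/posture offset + a single sinusoid (class
# frequency and amplitude, random phase) + white Gaussian noise. This is
# deliberately simple -- enough to exercise every algorithmic path and give
# well-separated classes, not a biomechanical claim. Gravity is +1 g on the
# dorsoventral Z axis for upright postures and rotated onto Y for lying on the
# side, matching an interscapular mount.

#' Default movement parameter table
#'
#' One row per simulated class: the fifteen canine daily activities used to
#' build the non-seizure reference (with the number of dogs contributing each
#' movement to that reference), plus the two seizure phases `gtcs_tonic`
#' (sustained postural shift with a low-amplitude 8-Hz tremor) and
#' `gtcs_clonic` (large-amplitude 3-Hz rhythmic jerking on all axes). All
#' values are editable artifact defaults, not measured canine parameters.
#'
#' @return data.frame with columns `name, n_dogs, off_x, off_y, off_z,
#'   osc_freq_hz, amp_x, amp_y, amp_z, noise_sd_g`.
#' @export
movement_params <- function() {
  tab <- rbind(
    # name                 dogs offx offy offz  freq ampx ampy ampz noise
    c("walking",             23, 0.0, 0.0, 1.0, 1.8, 0.35, 0.15, 0.45, 0.05),
    c("standing",            15, 0.0, 0.0, 1.0, 0.0, 0.00, 0.00, 0.00, 0.02),
    c("shaking",             24, 0.0, 0.0, 1.0, 5.0, 0.30, 1.00, 0.40, 0.08),
    c("drinking",             7, 0.2, 0.0, 0.95, 2.0, 0.10, 0.10, 0.15, 0.03),
    c("running",              4, 0.0, 0.0, 1.0, 3.0, 0.70, 0.30, 0.90, 0.08),
    c("jumping_on_sofa",      3, 0.0, 0.0, 1.0, 1.2, 0.60, 0.20, 1.00, 0.08),
    c("jumping_off_sofa",     3, 0.0, 0.0, 1.0, 1.2, 0.70, 0.20, 1.10, 0.08),
    c("lying_on_stomach",    12, 0.0, 0.0, 1.0, 0.0, 0.00, 0.00, 0.00, 0.01),
    c("lying_on_side",        5, 0.0, 1.0, 0.0, 0.0, 0.00, 0.00, 0.00, 0.01),
    c("scratching",           4, 0.0, 0.2, 0.95, 4.0, 0.20, 0.50, 0.30, 0.05),
    c("playing_with_toy",     3, 0.0, 0.0, 1.0, 2.5, 0.50, 0.50, 0.40, 0.07),
    c("being_stroked",        8, 0.0, 0.0, 1.0, 1.0, 0.05, 0.10, 0.08, 0.03),
    c("sitting",             14, 0.3, 0.0, 0.95, 0.0, 0.00, 0.00, 0.00, 0.02),
    c("turning_to_side",      5, 0.0, 0.5, 0.85, 0.5, 0.20, 0.50, 0.30, 0.04),
    c("turning_to_stomach",   5, 0.0, 0.5, 0.85, 0.5, 0.20, 0.50, 0.30, 0.04),
    c("gtcs_tonic",          NA, 0.5, 0.3, 0.80, 8.0, 0.25, 0.25, 0.25, 0.05),
    c("gtcs_clonic",         NA, 0.0, 0.2, 0.70, 3.0, 1.80, 1.80, 1.80, 0.20))
  df <- data.frame(name = tab[, 1L], stringsAsFactors = FALSE)
  num <- apply(tab[, -1L], 2L, as.numeric)
  colnames(num) <- c("n_dogs", "off_x", "off_y", "off_z", "osc_freq_hz",
                     "amp_x", "amp_y", "amp_z", "noise_sd_g")
  cbind(df, as.data.frame(num))
}

#' Names of the fifteen daily-activity classes
#' @return character vector of length 15.
#' @export
daily_activity_names <- function() {
  p <- movement_params()
  p$name[!is.na(p$n_dogs)]
}

#' Build a movement specification
#'
#' Parameters default to the [movement_params()] row matching `name`; any field
#' can be overridden.
#'
#' @param name class name (one of [movement_params()]`$name`).
#' @param duration_s segment duration in seconds.
#' @param base_offset_g length-3 gravity/posture offset in g.
#' @param osc_freq_hz oscillation frequency in Hz (0 for static postures).
#' @param osc_amp_g length-3 oscillation amplitude in g.
#' @param noise_sd_g white-noise standard deviation in g.
#' @return a `movement_spec` list.
#' @export
movement_spec <- function(name, duration_s = 9, base_offset_g = NULL,
                          osc_freq_hz = NULL, osc_amp_g = NULL,
                          noise_sd_g = NULL) {
  params <- movement_params()
  row <- params[params$name == name, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("unknown movement class '", name, "'", call. = FALSE)
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  spec <- list(
    name = name,
    duration_s = duration_s,
    base_offset_g = if (is.null(base_offset_g))
      c(row$off_x, row$off_y, row$off_z) else as.numeric(base_offset_g),
    osc_freq_hz = if (is.null(osc_freq_hz)) row$osc_freq_hz
                  else as.numeric(osc_freq_hz),
    osc_amp_g = if (is.null(osc_amp_g)) c(row$amp_x, row$amp_y, row$amp_z)
                else as.numeric(osc_amp_g),
    noise_sd_g = if (is.null(noise_sd_g)) row$noise_sd_g
                 else as.numeric(noise_sd_g))
  if (length(spec$base_offset_g) != 3L || length(spec$osc_amp_g) != 3L)
    stop("base_offset_g and osc_amp_g must have length 3", call. = FALSE)
  if (any(spec$osc_amp_g < 0) || spec$noise_sd_g < 0 || spec$osc_freq_hz < 0)
    stop("amplitudes, noise and frequency must be >= 0", call. = FALSE)
  structure(spec, class = "movement_spec")
}

#' Simulate one movement segment
#'
#' Per axis: `offset + amp * sin(2*pi*f*t + phase) + N(0, noise_sd)`, with an
#' independent uniform random phase per axis. Seeded calls are bit-for-bit
#' reproducible and leave the session RNG untouched.
#'
#' @param spec a [movement_spec()].
#' @param rate_hz sampling rate in Hz (default 50).
#' @param seed integer seed or `NULL` to draw from the current RNG stream.
#' @param device_range_g sensor clipping range in g.
#' @return an [accel_trace()].
#' @export
simulate_segment <- function(spec, rate_hz = 50, seed = NULL,
                             device_range_g = 8) {
  stopifnot(inherits(spec, "movement_spec"))
  stopifnot_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  if (spec$osc_freq_hz >= rate_hz / 2)
    stop(sprintf("oscillation frequency %g Hz is at or above Nyquist (%g Hz)",
                 spec$osc_freq_hz, rate_hz / 2), call. = FALSE)
  n <- round(spec$duration_s * rate_hz)
  with_seed(seed, {
    t <- (seq_len(n) - 1L) / rate_hz
    phases <- stats::runif(3L, 0, 2 * pi)
    s <- vapply(1:3, function(k) {
      spec$base_offset_g[k] +
        spec$osc_amp_g[k] * sin(2 * pi * spec$osc_freq_hz * t + phases[k]) +
        stats::rnorm(n, 0, spec$noise_sd_g)
    }, numeric(n))
    accel_trace(matrix(s, ncol = 3L), sampling_rate_hz = rate_hz,
                device_range_g = device_range_g)
  })
}

#' Simulate a tonic-clonic seizure burst
#'
#' A tonic segment (sustained posture shift with low-amplitude 8-Hz tremor)
#' followed by a clonic segment (large-amplitude 3-Hz rhythmic jerking), with
#' ground-truth intervals labelled `gtcs_tonic` / `gtcs_clonic`.
#'
#' @param tonic_s tonic-phase duration, seconds (0 for pure clonic).
#' @param clonic_s clonic-phase duration, seconds.
#' @param rate_hz sampling rate in Hz.
#' @param seed integer seed or `NULL`.
#' @return list with elements `trace` ([accel_trace()]) and `labels`
#'   ([label_intervals()]).
#' @export
simulate_gtcs <- function(tonic_s = 5, clonic_s = 25, rate_hz = 50,
                          seed = NULL) {
  stopifnot_scalar_number(tonic_s, "tonic_s", nonnegative = TRUE)
  stopifnot_scalar_number(clonic_s, "clonic_s", nonnegative = TRUE)
  if (tonic_s + clonic_s < 1)
    stop("total seizure duration must be at least 1 s", call. = FALSE)
  with_seed(seed, {
    parts <- list()
    labels <- list()
    at <- 0
    if (tonic_s > 0) {
      parts[[length(parts) + 1L]] <-
        simulate_segment(movement_spec("gtcs_tonic", duration_s = tonic_s),
                         rate_hz = rate_hz)
      labels[[length(labels) + 1L]] <- c("gtcs_tonic", at, at + tonic_s)
      at <- at + tonic_s
    }
    if (clonic_s > 0) {
      parts[[length(parts) + 1L]] <-
        simulate_segment(movement_spec("gtcs_clonic", duration_s = clonic_s),
                         rate_hz = rate_hz)
      labels[[length(labels) + 1L]] <- c("gtcs_clonic", at, at + clonic_s)
    }
    samples <- do.call(rbind, lapply(parts, function(p) p$samples))
    lab <- do.call(rbind, labels)
    list(trace = accel_trace(samples, sampling_rate_hz = rate_hz),
         labels = label_intervals(lab[, 1L], as.numeric(lab[, 2L]),
                                  as.numeric(lab[, 3L])))
  })
}

#' Build a daily-activity schedule
#'
#' @param names character vector of movement class names, in order.
#' @param durations_s segment durations in seconds (recycled if length 1).
#' @return data.frame `name, duration_s, start_s` with contiguous segments,
#'   class `sim_schedule`.
#' @export
sim_schedule <- function(names, durations_s = 9) {
  durations_s <- rep_len(as.numeric(durations_s), length(names))
  if (any(durations_s <= 0)) stop("durations must be > 0", call. = FALSE)
  known <- movement_params()$name
  bad <- setdiff(names, known)
  if (length(bad) > 0L)
    stop("unknown movement class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df <- data.frame(name = names, duration_s = durations_s,
                   start_s = cumsum(c(0, durations_s[-length(durations_s)])),
                   stringsAsFactors = FALSE)
  class(df) <- c("sim_schedule", "data.frame")
  df
}

#' Reference-building schedule for the fifteen daily activities
#'
#' One 9-s segment per dog per movement, following the dog counts of the
#' default parameter table (135 segments, 1,215 s in total) -- the arithmetic
#' used to assemble the non-seizure reference.
#'
#' @param segment_s seconds per dog-movement segment (default 9).
#' @return a [sim_schedule()].
#' @export
rdne_schedule <- function(segment_s = 9) {
  p <- movement_params()
  p <- p[!is.na(p$n_dogs), , drop = FALSE]
  names <- rep(p$name, times = p$n_dogs)
  sim_schedule(names, segment_s)
}

#' Simulate a full labelled recording from a schedule
#'
#' Concatenates seeded segments with continuous timestamps; the label track
#' follows the segment boundaries.
#'
#' @param schedule a [sim_schedule()].
#' @param rate_hz sampling rate in Hz.
#' @param seed integer seed or `NULL`.
#' @return list with `trace` and `labels`.
#' @export
simulate_day <- function(schedule, rate_hz = 50, seed = NULL) {
  stopifnot(inherits(schedule, "sim_schedule"))
  with_seed(seed, {
    parts <- vector("list", nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      spec <- movement_spec(schedule$name[i],
                            duration_s = schedule$duration_s[i])
      parts[[i]] <- simulate_segment(spec, rate_hz = rate_hz)$samples
    }
    trace <- accel_trace(do.call(rbind, parts), sampling_rate_hz = rate_hz)
    labels <- label_intervals(schedule$name, schedule$start_s,
                              schedule$start_s + schedule$duration_s)
    list(trace = trace, labels = labels)
  })
}

#' Rotation matrix from axis and angle
#'
#' @param axis `"x"`, `"y"`, `"z"`, or a length-3 axis vector.
#' @param angle_deg rotation angle in degrees.
#' @return orthonormal 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- if (is.character(axis)) {
    switch(match.arg(axis, c("x", "y", "z")),
           x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  } else as.numeric(axis)
  if (length(u) != 3L || sum(u^2) == 0) stop("invalid rotation axis", call. = FALSE)
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L,
               byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

#' Apply a sensor-displacement artifact
#'
#' From `onset_s` onward every sample is re-expressed in a rotated sensor
#' frame, emulating the accelerometer slipping laterally on the harness; the
#' signal before the onset is unchanged. Rotations preserve the resultant
#' force, so only the axis decomposition (and hence per-axis features) shifts.
#'
#' @param trace an [accel_trace()].
#' @param rotation orthonormal 3 x 3 matrix (e.g. from [rotation_matrix()]).
#' @param onset_s displacement time in seconds from trace start.
#' @return a new [accel_trace()].
#' @export
apply_displacement <- function(trace, rotation, onset_s = 0) {
  stopifnot(inherits(trace, "accel_trace"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be a proper orthonormal 3 x 3 matrix", call. = FALSE)
  stopifnot_scalar_number(onset_s, "onset_s", nonnegative = TRUE)
  s <- trace$samples
  i0 <- floor(onset_s * trace$sampling_rate_hz) + 1L
  if (i0 <= nrow(s)) {
    idx <- i0:nrow(s)
    s[idx, ] <- s[idx, , drop = FALSE] %*% t(rotation)
  }
  accel_trace(s, sampling_rate_hz = trace$sampling_rate_hz,
              start_time = trace$start_time,
              device_range_g = trace$device_range_g)
}
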