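# Streaming seizure detector: slides the classifier over a feature stream and
# turns positive epochs into detection events with debounce + refractory logic,
# emulating a real-time notification prototype.
#
# Event semantics: a run of consecutive seizure epochs fires one event once the
# run reaches `min_consecutive_positives`; the event onset is the start of the
# first positive epoch of the run, and the triggering epoch's distances are
# kept for audit. After an event, no new event may start until `refractory_s`
# has elapsed since the previous onset, so one seizure raises one alert.

#' Detector configuration
#'
#' @param epoch_length_s epoch length in seconds (default 9).
#' @param stride_s window advance in seconds (default 1).
#' @param aggregator per-epoch distance aggregator (default `"mean"`).
#' @param refractory_s minimum separation between event onsets, seconds
#'   (default 60).
#' @param min_consecutive_positives number of consecutive seizure epochs
#'   required before an event fires (default 1, i.e. no debounce).
#' @return a `detector_config` list.
#' @export
detector_config <- function(epoch_length_s = 9, stride_s = 1,
                            aggregator = c("mean", "median", "max"),
                            refractory_s = 60,
                            min_consecutive_positives = 1) {
  aggregator <- match.arg(aggregator)
  stopifnot_scalar_number(epoch_length_s, "epoch_length_s", positive = TRUE,
                          integer = TRUE)
  stopifnot_scalar_number(stride_s, "stride_s", positive = TRUE, integer = TRUE)
  stopifnot_scalar_number(refractory_s, "refractory_s", nonnegative = TRUE)
  stopifnot_scalar_number(min_consecutive_positives, "min_consecutive_positives",
                          positive = TRUE, integer = TRUE)
  structure(list(epoch_length_s = as.integer(epoch_length_s),
                 stride_s = as.integer(stride_s), aggregator = aggregator,
                 refractory_s = refractory_s,
                 min_consecutive_positives = as.integer(min_consecutive_positives)),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "<detector_config> epoch=%d s, stride=%d s, aggregator=%s, refractory=%g s, debounce=%d\n",
    x$epoch_length_s, x$stride_s, x$aggregator, x$refractory_s,
    x$min_consecutive_positives))
  invisible(x)
}

# Event state machine shared verbatim by the batch and streaming paths.
# step() consumes one classified epoch in time order and returns an event row
# or NULL.
new_event_machine <- function(config) {
  run_len <- 0L
  run_start <- NA_real_
  fired_this_run <- FALSE
  last_onset <- -Inf
  step <- function(epoch_start_s, decision, distance_rde, distance_rdne) {
    if (identical(decision, "seizure")) {
      if (run_len == 0L) run_start <<- epoch_start_s
      run_len <<- run_len + 1L
      if (!fired_this_run && run_len >= config$min_consecutive_positives &&
          (run_start - last_onset) >= config$refractory_s) {
        fired_this_run <<- TRUE
        last_onset <<- run_start
        return(data.frame(onset_s = run_start,
                          trigger_epoch_start_s = epoch_start_s,
                          distance_rde = distance_rde,
                          distance_rdne = distance_rdne,
                          stringsAsFactors = FALSE))
      }
    } else {
      run_len <<- 0L
      run_start <<- NA_real_
      fired_this_run <<- FALSE
    }
    NULL
  }
  list(step = step)
}

empty_events <- function() {
  data.frame(onset_s = numeric(0), trigger_epoch_start_s = numeric(0),
             distance_rde = numeric(0), distance_rdne = numeric(0),
             stringsAsFactors = FALSE)
}

events_from_results <- function(results, config) {
  machine <- new_event_machine(config)
  out <- vector("list", 0L)
  for (i in seq_len(nrow(results))) {
    ev <- machine$step(results$epoch_start_s[i], results$decision[i],
                       results$distance_rde[i], results$distance_rdne[i])
    if (!is.null(ev)) out[[length(out) + 1L]] <- ev
  }
  if (length(out) == 0L) empty_events() else do.call(rbind, out)
}

#' Detect seizure events over a feature stream
#'
#' Classifies every sliding epoch (batch path, see [classify_epochs()]) and
#' applies the event state machine. A stream shorter than one epoch yields an
#' empty event table, not an error.
#'
#' @param features per-second feature data.frame or `n x 8` matrix.
#' @param rde,rdne the two reference models.
#' @param config a [detector_config()].
#' @return data.frame `onset_s, trigger_epoch_start_s, distance_rde,
#'   distance_rdne`, one row per event, with the full classification table as
#'   attribute `"results"`.
#' @export
detect_stream <- function(features, rde, rdne, config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  results <- classify_epochs(features, rde, rdne,
                             epoch_length_s = config$epoch_length_s,
                             stride_s = config$stride_s,
                             aggregator = config$aggregator)
  events <- events_from_results(results, config)
  attr(events, "results") <- results
  attr(events, "config") <- config
  events
}

#' Create an incremental (one-second-at-a-time) stream detector
#'
#' Returns a stateful detector fed with [stream_push()]. It maintains a rolling
#' feature buffer, classifies each complete window as it forms, and runs the
#' same event state machine as [detect_stream()]; the two paths are equivalent
#' by construction and by test (see [replay_equivalence()]).
#'
#' @param rde,rdne the two reference models.
#' @param config a [detector_config()].
#' @return a `stream_detector` object.
#' @export
stream_detector <- function(rde, rdne, config = detector_config()) {
  check_model_pair(rde, rdne)
  stopifnot(inherits(config, "detector_config"))
  env <- new.env(parent = emptyenv())
  env$buffer <- matrix(numeric(0), 0L, N_FEATURES)
  env$next_second <- NA_integer_
  env$since_last_epoch <- 0L
  env$n_seen <- 0L
  env$machine <- new_event_machine(config)
  env$results <- list()
  env$events <- list()
  structure(list(rde = rde, rdne = rdne, config = config, state = env),
            class = "stream_detector")
}

#' Push one per-second feature row into a stream detector
#'
#' @param detector a [stream_detector()].
#' @param feature_row named numeric vector (or one-row data.frame) holding the
#'   8 features, plus optionally `second`.
#' @return invisibly, a list with the classification `result` for the window
#'   completed by this row (or `NULL`) and the fired `event` (or `NULL`).
#' @export
stream_push <- function(detector, feature_row) {
  stopifnot(inherits(detector, "stream_detector"))
  st <- detector$state
  cfg <- detector$config
  if (is.data.frame(feature_row)) {
    second <- if (!is.null(feature_row[["second"]]))
      as.integer(feature_row[["second"]][1L]) else NA_integer_
    row <- feature_matrix(feature_row)
  } else {
    second <- if (!is.na(feature_row["second"]))
      as.integer(feature_row[["second"]]) else NA_integer_
    row <- matrix(as.numeric(feature_row[FEATURE_COLS]), 1L,
                  dimnames = list(NULL, FEATURE_COLS))
  }
  if (is.na(second)) second <- st$n_seen
  st$n_seen <- st$n_seen + 1L
  st$buffer <- rbind(st$buffer, row)
  L <- cfg$epoch_length_s
  keep <- max(L, 1L)
  if (nrow(st$buffer) > keep)
    st$buffer <- st$buffer[(nrow(st$buffer) - keep + 1L):nrow(st$buffer), ,
                           drop = FALSE]
  result <- NULL
  event <- NULL
  if (st$n_seen >= L) {
    # a window ends at this row; respect the stride relative to window starts
    start0 <- st$n_seen - L            # 0-based index of window start
    if (start0 %% cfg$stride_s == 0L) {
      ep <- st$buffer
      attr(ep, "start_second") <- second - L + 1L
      result <- classify_epoch(ep, detector$rde, detector$rdne, cfg$aggregator)
      st$results[[length(st$results) + 1L]] <- result
      ev <- st$machine$step(result$epoch_start_s, result$decision,
                            result$distance_rde, result$distance_rdne)
      if (!is.null(ev)) {
        st$events[[length(st$events) + 1L]] <- ev
        event <- ev
      }
    }
  }
  invisible(list(result = result, event = event))
}

#' Collected results and events of a stream detector
#' @param detector a [stream_detector()] after some [stream_push()] calls.
#' @return list with elements `results` (classification data.frame) and
#'   `events` (event data.frame).
#' @export
stream_collect <- function(detector) {
  st <- detector$state
  results <- if (length(st$results) == 0L)
    classify_epochs(matrix(numeric(0), 0L, N_FEATURES), detector$rde,
                    detector$rdne,
                    epoch_length_s = detector$config$epoch_length_s,
                    stride_s = detector$config$stride_s,
                    aggregator = detector$config$aggregator)
  else do.call(rbind, st$results)
  events <- if (length(st$events) == 0L) empty_events()
            else do.call(rbind, st$events)
  rownames(results) <- NULL
  rownames(events) <- NULL
  list(results = results, events = events)
}

#' Check that streaming and batch detection agree
#'
#' Runs the whole-trace batch pipeline and the one-second-at-a-time streaming
#' pipeline over the same input and compares every classification row and
#' every event.
#'
#' @param x an [accel_trace()] or a per-second feature data.frame.
#' @param rde,rdne the two reference models.
#' @param config a [detector_config()].
#' @param tol numeric tolerance on distances.
#' @return list with `equal` (logical), `n_epochs`, `n_events`, and (when
#'   unequal) `first_divergence`, the index of the first differing epoch.
#' @export
replay_equivalence <- function(x, rde, rdne, config = detector_config(),
                               tol = 1e-10) {
  features <- if (inherits(x, "accel_trace")) per_second_features(x) else x
  batch_events <- detect_stream(features, rde, rdne, config)
  batch <- attr(batch_events, "results")
  det <- stream_detector(rde, rdne, config)
  m <- feature_matrix(features)
  secs <- feature_seconds(features)
  for (i in seq_len(nrow(m))) {
    row <- c(second = secs[i], m[i, ])
    stream_push(det, row)
  }
  streamed <- stream_collect(det)
  ok_n <- nrow(batch) == nrow(streamed$results)
  first_div <- NA_integer_
  ok_rows <- ok_n
  if (ok_n && nrow(batch) > 0L) {
    diff_row <- which(
      abs(batch$distance_rde - streamed$results$distance_rde) > tol |
      abs(batch$distance_rdne - streamed$results$distance_rdne) > tol |
      batch$decision != streamed$results$decision |
      batch$epoch_start_s != streamed$results$epoch_start_s)
    if (length(diff_row) > 0L) {
      ok_rows <- FALSE
      first_div <- diff_row[1L]
    }
  }
  ok_events <- nrow(batch_events) == nrow(streamed$events) &&
    (nrow(batch_events) == 0L ||
       (all(abs(batch_events$onset_s - streamed$events$onset_s) <= tol) &&
        all(batch_events$trigger_epoch_start_s ==
              streamed$events$trigger_epoch_start_s)))
  list(equal = ok_n && ok_rows && ok_events,
       n_epochs = nrow(batch), n_events = nrow(batch_events),
       first_divergence = first_div)
}

#' Write a detection event log to CSV
#' @param events event data.frame from [detect_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(
    events[, c("onset_s", "trigger_epoch_start_s", "distance_rde",
               "distance_rdne")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
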