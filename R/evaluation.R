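# Event- and epoch-level scoring of detector output against ground truth.
#
# Event matching is greedy one-to-one in time order: an event matches a truth
# seizure if its onset falls in [start - tolerance, end]; each seizure absorbs
# at most one event. Epoch truth follows a majority-overlap rule: an epoch is
# seizure-truth iff at least half of its span lies inside seizure intervals.

SEIZURE_LABELS <- c("gtcs_tonic", "gtcs_clonic", "gtcs", "seizure")

# Restrict a label track to seizure intervals and merge touching ones.
seizure_intervals <- function(truth, seizure_labels = SEIZURE_LABELS) {
  tr <- as.data.frame(truth)
  tr <- tr[tr$label %in% seizure_labels, , drop = FALSE]
  if (nrow(tr) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  tr <- tr[order(tr$start_s), , drop = FALSE]
  out <- list(c(tr$start_s[1L], tr$end_s[1L]))
  for (i in seq_len(nrow(tr))[-1L]) {
    last <- out[[length(out)]]
    if (tr$start_s[i] <= last[2L] + 1e-9)
      out[[length(out)]] <- c(last[1L], max(last[2L], tr$end_s[i]))
    else
      out[[length(out) + 1L]] <- c(tr$start_s[i], tr$end_s[i])
  }
  m <- do.call(rbind, out)
  data.frame(start_s = m[, 1L], end_s = m[, 2L])
}

#' Match detection events to ground-truth seizures
#'
#' @param events event data.frame from [detect_stream()].
#' @param truth a [label_intervals()] track; intervals whose label is one of
#'   `seizure_labels` are the seizures (contiguous tonic/clonic intervals are
#'   merged into one seizure).
#' @param tolerance_s seconds before the truth onset within which an event
#'   still counts as a detection (default 5).
#' @param seizure_labels labels regarded as seizure ground truth.
#' @return list with `matches` (data.frame `truth_start_s, truth_end_s,
#'   onset_s, latency_s`), `unmatched_events` (false-positive event rows) and
#'   `unmatched_truth` (missed seizure intervals).
#' @export
match_events <- function(events, truth, tolerance_s = 5,
                         seizure_labels = SEIZURE_LABELS) {
  stopifnot_scalar_number(tolerance_s, "tolerance_s", nonnegative = TRUE)
  sz <- seizure_intervals(truth, seizure_labels)
  ev <- as.data.frame(events)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  used <- rep(FALSE, nrow(ev))
  matches <- list()
  matched_truth <- rep(FALSE, nrow(sz))
  for (i in seq_len(nrow(sz))) {
    lo <- sz$start_s[i] - tolerance_s
    hi <- sz$end_s[i]
    cand <- which(!used & ev$onset_s >= lo & ev$onset_s <= hi)
    if (length(cand) > 0L) {
      j <- cand[1L]
      used[j] <- TRUE
      matched_truth[i] <- TRUE
      matches[[length(matches) + 1L]] <-
        data.frame(truth_start_s = sz$start_s[i], truth_end_s = sz$end_s[i],
                   onset_s = ev$onset_s[j],
                   latency_s = ev$onset_s[j] - sz$start_s[i])
    }
  }
  list(
    matches = if (length(matches) == 0L)
      data.frame(truth_start_s = numeric(0), truth_end_s = numeric(0),
                 onset_s = numeric(0), latency_s = numeric(0))
      else do.call(rbind, matches),
    unmatched_events = ev[!used, , drop = FALSE],
    unmatched_truth = sz[!matched_truth, , drop = FALSE])
}

#' Epoch-level confusion table
#'
#' Crosses each epoch's decision with its ground-truth class. An epoch of
#' length L starting at second s is seizure-truth iff at least L/2 of the
#' seconds in [s, s+L) lie inside a seizure interval (a second counts when its
#' midpoint is covered).
#'
#' @param results classification data.frame from [classify_epochs()] (its
#'   `epoch_length_s` attribute supplies L).
#' @param truth a [label_intervals()] track.
#' @param seizure_labels labels regarded as seizure ground truth.
#' @return 2 x 2 integer table, rows = decision, columns = truth
#'   (`seizure`, `non_seizure`).
#' @export
epoch_confusion <- function(results, truth, seizure_labels = SEIZURE_LABELS) {
  L <- attr(results, "epoch_length_s")
  if (is.null(L)) stop("results lack the epoch_length_s attribute", call. = FALSE)
  sz <- seizure_intervals(truth, seizure_labels)
  second_is_seizure <- function(k) {
    mid <- k + 0.5
    any(mid >= sz$start_s & mid < sz$end_s)
  }
  lv <- c("seizure", "non_seizure")
  truth_class <- vapply(results$epoch_start_s, function(s) {
    n_sz <- sum(vapply(s:(s + L - 1L), second_is_seizure, logical(1)))
    if (n_sz >= L / 2) "seizure" else "non_seizure"
  }, character(1))
  table(decision = factor(results$decision, levels = lv),
        truth = factor(truth_class, levels = lv))
}

#' Score a detection run
#'
#' Combines event matching and (optionally) the epoch confusion table into one
#' report: sensitivity, false-positive events, the false-positive rate per
#' 24 h, and mean detection latency.
#'
#' @param events event data.frame from [detect_stream()].
#' @param truth a [label_intervals()] track.
#' @param duration_s monitored duration in seconds (for the FP/24 h rate).
#' @param results optional classification data.frame for the epoch table.
#' @param tolerance_s event-matching tolerance, seconds.
#' @param seizure_labels labels regarded as seizure ground truth.
#' @return an `eval_report` list: `true_positives, false_negatives,
#'   false_positive_events, sensitivity, false_positives_per_24h,
#'   mean_latency_s, epoch_confusion`.
#' @export
evaluate_detection <- function(events, truth, duration_s, results = NULL,
                               tolerance_s = 5,
                               seizure_labels = SEIZURE_LABELS) {
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  m <- match_events(events, truth, tolerance_s, seizure_labels)
  tp <- nrow(m$matches)
  fn <- nrow(m$unmatched_truth)
  fp <- nrow(m$unmatched_events)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  report <- list(
    true_positives = tp,
    false_negatives = fn,
    false_positive_events = fp,
    sensitivity = sens,
    false_positives_per_24h = fp / duration_s * 86400,
    mean_latency_s = if (tp > 0) mean(m$matches$latency_s) else NA_real_,
    epoch_confusion = if (!is.null(results))
      epoch_confusion(results, truth, seizure_labels) else NULL,
    matching = m)
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  true positives:        %d\n", x$true_positives))
  cat(sprintf("  false negatives:       %d\n", x$false_negatives))
  cat(sprintf("  false positive events: %d\n", x$false_positive_events))
  cat(sprintf("  sensitivity:           %s\n",
              if (is.na(x$sensitivity)) "undefined (no seizures in truth)"
              else sprintf("%.3f", x$sensitivity)))
  cat(sprintf("  FP per 24 h:           %.4f\n", x$false_positives_per_24h))
  if (!is.na(x$mean_latency_s))
    cat(sprintf("  mean latency:          %.2f s\n", x$mean_latency_s))
  if (!is.null(x$epoch_confusion)) {
    cat("  epoch confusion (decision x truth):\n")
    print(x$epoch_confusion)
  }
  invisible(x)
}

#' Write an evaluation report to JSON
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  payload <- report[c("true_positives", "false_negatives",
                      "false_positive_events", "sensitivity",
                      "false_positives_per_24h", "mean_latency_s")]
  if (!is.null(report$epoch_confusion))
    payload$epoch_confusion <- as.vector(report$epoch_confusion)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
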