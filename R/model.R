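# The fitted detector object: both reference models plus the epoching and
# decision configuration, with the usual modelling-verb methods.

#' Map a label track onto per-second class labels
#'
#' Assigns each whole second of a feature series to `"seizure"` or
#' `"non_seizure"` according to whether the second's midpoint lies inside a
#' seizure interval, and records which movement label covers it.
#'
#' @param labels a [label_intervals()] track.
#' @param seconds integer vector of 0-based seconds (e.g. `features$second`).
#' @param seizure_labels interval labels regarded as seizure.
#' @return data.frame `second, label, class`.
#' @export
second_labels <- function(labels, seconds,
                          seizure_labels = SEIZURE_LABELS) {
  tr <- as.data.frame(labels)
  mid <- seconds + 0.5
  lab <- vapply(mid, function(m) {
    hit <- which(tr$start_s <= m & m < tr$end_s)
    if (length(hit) == 0L) NA_character_ else tr$label[hit[1L]]
  }, character(1))
  data.frame(second = seconds, label = lab,
             class = ifelse(!is.na(lab) & lab %in% seizure_labels,
                            "seizure", "non_seizure"),
             stringsAsFactors = FALSE)
}

#' Fit a two-reference Mahalanobis seizure detector
#'
#' Builds the seizure reference (RDE) from the feature rows labelled seizure
#' and the daily-activity reference (RDNE) from the rest, and bundles them with
#' the epoching/decision configuration into a fitted `seizure_detector` object.
#'
#' @param x per-second features: a data.frame from [per_second_features()] or
#'   an `n x 8` matrix.
#' @param labels per-second class labels: a character vector of
#'   `"seizure"`/`"non_seizure"` of length `nrow(x)`, or a
#'   [label_intervals()] track (mapped with [second_labels()]).
#' @param ridge covariance ridge strength (see [regularize_covariance()]).
#' @param config a [detector_config()] used by `predict(..., type = "events")`.
#' @param source_manifest optional recording identifiers stored with both
#'   references.
#' @return an object of class `seizure_detector` with components `rde`, `rdne`,
#'   `config`, `n_seizure_rows`, `n_nonseizure_rows`.
#' @examples
#' \donttest{
#' day <- simulate_day(rdne_schedule(), seed = 1)
#' sz <- simulate_gtcs(seed = 2)
#' feats <- rbind(per_second_features(day$trace), per_second_features(sz$trace))
#' cls <- c(rep("non_seizure", 1215), rep("seizure", 30))
#' fit <- seizure_detector(feats, cls)
#' coef(fit)
#' }
#' @export
seizure_detector <- function(x, labels, ridge = 0.01,
                             config = detector_config(),
                             source_manifest = character(0)) {
  m <- feature_matrix(x)
  if (inherits(labels, "label_intervals") || is.data.frame(labels)) {
    cls <- second_labels(labels, feature_seconds(x))$class
  } else {
    cls <- as.character(labels)
  }
  if (length(cls) != nrow(m))
    stop("labels must supply one class per feature row", call. = FALSE)
  if (!all(cls %in% c("seizure", "non_seizure")))
    stop("labels must be 'seizure' or 'non_seizure'", call. = FALSE)
  rde <- build_reference(m[cls == "seizure", , drop = FALSE],
                         label = "seizure", ridge = ridge,
                         source_manifest = source_manifest)
  rdne <- build_reference(m[cls == "non_seizure", , drop = FALSE],
                          label = "non_seizure", ridge = ridge,
                          source_manifest = source_manifest)
  structure(list(rde = rde, rdne = rdne, config = config,
                 n_seizure_rows = rde$n_rows,
                 n_nonseizure_rows = rdne$n_rows,
                 call = match.call()),
            class = "seizure_detector")
}

#' @export
print.seizure_detector <- function(x, ...) {
  cat("Two-reference Mahalanobis seizure detector\n")
  cat(sprintf("  RDE  (seizure):     %d per-second feature rows\n",
              x$n_seizure_rows))
  cat(sprintf("  RDNE (non-seizure): %d per-second feature rows\n",
              x$n_nonseizure_rows))
  print(x$config)
  invisible(x)
}

#' @export
coef.seizure_detector <- function(object, ...) {
  rbind(seizure = object$rde$mean, non_seizure = object$rdne$mean)
}

#' @export
summary.seizure_detector <- function(object, ...) {
  cond <- function(model) {
    ev <- eigen(model$covariance, symmetric = TRUE, only.values = TRUE)$values
    max(ev) / min(ev)
  }
  out <- list(
    coef = coef(object),
    n_rows = c(seizure = object$n_seizure_rows,
               non_seizure = object$n_nonseizure_rows),
    ridge_used = c(seizure = object$rde$ridge_used,
                   non_seizure = object$rdne$ridge_used),
    condition = c(seizure = cond(object$rde), non_seizure = cond(object$rdne)),
    mean_separation = sqrt(mahalanobis_sq(object$rde$mean, object$rdne) /
                             N_FEATURES),
    config = object$config)
  class(out) <- "summary.seizure_detector"
  out
}

#' @export
print.summary.seizure_detector <- function(x, ...) {
  cat("Two-reference Mahalanobis seizure detector\n\n")
  cat("Class feature means:\n")
  print(round(x$coef, 4))
  cat("\nRows per reference: ")
  cat(sprintf("seizure=%d, non_seizure=%d\n", x$n_rows[1L], x$n_rows[2L]))
  cat(sprintf("Covariance condition numbers: seizure=%.3g, non_seizure=%.3g\n",
              x$condition[1L], x$condition[2L]))
  cat(sprintf("Ridge applied (lambda): seizure=%.3g, non_seizure=%.3g\n",
              x$ridge_used[1L], x$ridge_used[2L]))
  cat(sprintf(
    "Scaled distance of seizure mean from the non-seizure reference: %.2f\n",
    x$mean_separation))
  print(x$config)
  invisible(x)
}

#' Classify new data with a fitted detector
#'
#' @param object a [seizure_detector()] fit.
#' @param newdata an [accel_trace()] or a per-second feature data.frame.
#' @param type `"epochs"` for the per-epoch classification table,
#'   `"events"` for detection events (see [detect_stream()]).
#' @param ... unused.
#' @return a classification data.frame or an event data.frame.
#' @export
predict.seizure_detector <- function(object, newdata,
                                     type = c("epochs", "events"), ...) {
  type <- match.arg(type)
  features <- if (inherits(newdata, "accel_trace"))
    per_second_features(newdata) else newdata
  if (type == "epochs") {
    classify_epochs(features, object$rde, object$rdne,
                    epoch_length_s = object$config$epoch_length_s,
                    stride_s = object$config$stride_s,
                    aggregator = object$config$aggregator)
  } else {
    detect_stream(features, object$rde, object$rdne, object$config)
  }
}

#' Plot epoch distances for a trace under a fitted detector
#'
#' Draws the aggregated distance to each reference against epoch start time
#' and shades epochs decided as seizure.
#'
#' @param x a [seizure_detector()] fit.
#' @param newdata an [accel_trace()] or feature data.frame to classify.
#' @param ... further arguments passed to [graphics::plot()].
#' @return the classification data.frame, invisibly.
#' @export
plot.seizure_detector <- function(x, newdata, ...) {
  res <- predict(x, newdata, type = "epochs")
  if (nrow(res) == 0L) {
    warning("input shorter than one epoch; nothing to plot", call. = FALSE)
    return(invisible(res))
  }
  ylim <- range(res$distance_rde, res$distance_rdne)
  graphics::plot(res$epoch_start_s, res$distance_rdne, type = "l",
                 xlab = "epoch start (s)", ylab = "scaled Mahalanobis distance",
                 ylim = ylim, col = "grey30", ...)
  graphics::lines(res$epoch_start_s, res$distance_rde, col = "firebrick")
  hit <- res$decision == "seizure"
  if (any(hit))
    graphics::points(res$epoch_start_s[hit], res$distance_rde[hit],
                     pch = 16, cex = 0.5, col = "firebrick")
  graphics::legend("topright", legend = c("to RDNE", "to RDE", "seizure call"),
                   col = c("grey30", "firebrick", "firebrick"),
                   lty = c(1, 1, NA), pch = c(NA, NA, 16), bty = "n")
  invisible(res)
}
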