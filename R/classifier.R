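# Two-reference Mahalanobis classification of feature epochs.
#
# Per-second distances are scaled by the feature dimension
# (d_t = sqrt(D^2_t / 8), the Mahalanobis-Taguchi convention, so reference
# members score near 1) and aggregated over the epoch (mean by default). The
# decision rule is threshold-free: an epoch is a seizure iff its aggregated
# distance to the seizure reference (RDE) is strictly shorter than to the
# daily-activity reference (RDNE); ties favour non_seizure.

N_FEATURES <- 8L

#' Squared Mahalanobis distance to a reference model
#'
#' `(x - mu)' Sigma^{-1} (x - mu)`, computed through the model's cached
#' Cholesky factor (a triangular solve, never an explicit inverse).
#'
#' @param x numeric vector of length 8, or an `n x 8` matrix of rows.
#' @param model a [build_reference()] model.
#' @return non-negative squared distance(s); 0 iff `x` equals the model mean.
#' @export
mahalanobis_sq <- function(x, model) {
  stopifnot(inherits(model, "reference_model"))
  if (is.null(dim(x))) {
    if (length(x) != N_FEATURES)
      stop(sprintf("expected a length-%d feature vector, got %d", N_FEATURES,
                   length(x)), call. = FALSE)
    x <- matrix(as.numeric(x), 1L)
  }
  if (ncol(x) != N_FEATURES)
    stop(sprintf("expected %d feature columns, got %d", N_FEATURES, ncol(x)),
         call. = FALSE)
  centred <- t(x) - model$mean
  z <- backsolve(model$chol, centred, transpose = TRUE)
  d2 <- colSums(z^2)
  unname(d2)
}

# Dimension-scaled per-row distance d_t = sqrt(D^2_t / 8).
row_distance <- function(x, model) sqrt(mahalanobis_sq(x, model) / N_FEATURES)

#' Aggregated epoch-to-reference distance
#'
#' Each of the epoch's per-second rows is scored as
#' `d_t = sqrt(mahalanobis_sq(row_t)/8)` and the scores are combined with the
#' chosen aggregator (default mean).
#'
#' @param epoch an `L x 8` feature matrix (an element of [make_epochs()]).
#' @param model a `reference_model`.
#' @param aggregator one of `"mean"`, `"median"`, `"max"`.
#' @return non-negative aggregated distance.
#' @export
epoch_distance <- function(epoch, model, aggregator = c("mean", "median", "max")) {
  aggregator <- match.arg(aggregator)
  epoch <- feature_matrix(epoch)
  if (nrow(epoch) == 0L) stop("empty epoch", call. = FALSE)
  d <- row_distance(epoch, model)
  switch(aggregator, mean = mean(d), median = stats::median(d), max = max(d))
}

#' Shorter-distance decision rule
#'
#' `"seizure"` iff the distance to the seizure reference is strictly shorter
#' than to the daily-activity reference; an exact tie classifies as
#' `"non_seizure"` (favouring specificity). The rule is invariant to any
#' monotone transform applied to both distances.
#'
#' @param distance_rde distance(s) to the seizure reference.
#' @param distance_rdne distance(s) to the non-seizure reference.
#' @return character vector of decisions.
#' @examples
#' shorter_distance_rule(c(5.3, 3.43), c(5.38, 6.2)) # both "seizure"
#' @export
shorter_distance_rule <- function(distance_rde, distance_rdne) {
  if (length(distance_rde) != length(distance_rdne))
    stop("distance vectors must have equal length", call. = FALSE)
  ifelse(distance_rde < distance_rdne, "seizure", "non_seizure")
}

check_model_pair <- function(rde, rdne) {
  stopifnot(inherits(rde, "reference_model"), inherits(rdne, "reference_model"))
  if (rde$label == rdne$label)
    stop("the two reference models carry the same label ('", rde$label,
         "'); need one seizure and one non_seizure model", call. = FALSE)
}

#' Classify one epoch against the two references
#'
#' @param epoch an `L x 8` feature matrix; its `start_second` attribute (set by
#'   `epoch_set` extraction) is reported when present.
#' @param rde seizure reference model.
#' @param rdne non-seizure reference model.
#' @param aggregator per-epoch distance aggregator (see [epoch_distance()]).
#' @return one-row data.frame `epoch_start_s, distance_rde, distance_rdne,
#'   decision` (plus attribute `aggregator_used`).
#' @export
classify_epoch <- function(epoch, rde, rdne, aggregator = "mean") {
  check_model_pair(rde, rdne)
  d1 <- epoch_distance(epoch, rde, aggregator)
  d2 <- epoch_distance(epoch, rdne, aggregator)
  start <- attr(epoch, "start_second") %||% NA_integer_
  out <- data.frame(epoch_start_s = start, distance_rde = d1,
                    distance_rdne = d2,
                    decision = shorter_distance_rule(d1, d2),
                    stringsAsFactors = FALSE)
  attr(out, "aggregator_used") <- aggregator
  out
}

#' Classify every sliding epoch of a feature series
#'
#' Vectorised batch path: per-second distances to both references are computed
#' once, then aggregated over each window of `epoch_length_s` rows advanced by
#' `stride_s`.
#'
#' @param features per-second feature data.frame or `n x 8` matrix.
#' @param rde,rdne the two reference models.
#' @param epoch_length_s epoch length in seconds (default 9).
#' @param stride_s window advance in seconds (default 1).
#' @param aggregator `"mean"`, `"median"` or `"max"`.
#' @return data.frame `epoch_start_s, distance_rde, distance_rdne, decision`
#'   with one row per epoch (zero rows if the stream is shorter than one
#'   epoch); attributes `epoch_length_s`, `stride_s`, `aggregator_used`.
#' @export
classify_epochs <- function(features, rde, rdne, epoch_length_s = 9,
                            stride_s = 1, aggregator = c("mean", "median", "max")) {
  aggregator <- match.arg(aggregator)
  check_model_pair(rde, rdne)
  stopifnot_scalar_number(epoch_length_s, "epoch_length_s", positive = TRUE,
                          integer = TRUE)
  stopifnot_scalar_number(stride_s, "stride_s", positive = TRUE, integer = TRUE)
  m <- feature_matrix(features)
  secs <- feature_seconds(features)
  n <- nrow(m)
  if (n < epoch_length_s) {
    out <- data.frame(epoch_start_s = integer(0), distance_rde = numeric(0),
                      distance_rdne = numeric(0), decision = character(0),
                      stringsAsFactors = FALSE)
  } else {
    starts <- seq.int(0L, n - epoch_length_s, by = stride_s)
    d1 <- row_distance(m, rde)
    d2 <- row_distance(m, rdne)
    D1 <- roll_aggregate(d1, epoch_length_s, starts, aggregator)
    D2 <- roll_aggregate(d2, epoch_length_s, starts, aggregator)
    out <- data.frame(epoch_start_s = secs[starts + 1L], distance_rde = D1,
                      distance_rdne = D2,
                      decision = shorter_distance_rule(D1, D2),
                      stringsAsFactors = FALSE)
  }
  attr(out, "epoch_length_s") <- as.integer(epoch_length_s)
  attr(out, "stride_s") <- as.integer(stride_s)
  attr(out, "aggregator_used") <- aggregator
  out
}

roll_aggregate <- function(d, window, starts0, aggregator) {
  if (aggregator == "mean") {
    cs <- c(0, cumsum(d))
    (cs[starts0 + window + 1L] - cs[starts0 + 1L]) / window
  } else {
    fun <- if (aggregator == "median") stats::median else max
    vapply(starts0, function(s) fun(d[(s + 1L):(s + window)]), numeric(1))
  }
}

#' Write batch classification results to CSV
#' @param results data.frame from [classify_epochs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification_csv <- function(results, path) {
  utils::write.csv(
    results[, c("epoch_start_s", "distance_rde", "distance_rdne", "decision")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
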