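# Reference models: per-class feature mean + variance-covariance matrix.
#
# Two models drive the classifier: the seizure reference (RDE), built from
# every per-second feature row of the tonic-clonic phase of the source
# seizures, and the daily-activity reference (RDNE), built from the pooled
# per-second rows of the fifteen movement classes. At least nine rows are
# required -- the generic-invertibility threshold for an 8x8 covariance.

REFERENCE_SCHEMA_VERSION <- 1L
MIN_REFERENCE_ROWS <- 9L

#' Build a reference model from per-second feature rows
#'
#' Computes the column means and the population (divide-by-n)
#' variance-covariance matrix of the eight features, then conditions the
#' covariance with [regularize_covariance()] so the model is always positive
#' definite. The Cholesky factor is cached for fast Mahalanobis solves.
#'
#' @param rows feature rows: a data.frame from [per_second_features()] or an
#'   `n x 8` matrix; `n >= 9`.
#' @param label class name, `"seizure"` (RDE) or `"non_seizure"` (RDNE).
#' @param ridge relative ridge strength passed to [regularize_covariance()].
#' @param source_manifest optional character vector of contributing recording
#'   identifiers, kept for provenance.
#' @return an object of class `reference_model` with fields `label`, `mean`
#'   (length 8), `covariance` (8 x 8), `n_rows`, `ridge_used` (the lambda
#'   actually added, 0 if none) and `source_manifest`.
#' @export
build_reference <- function(rows, label = c("non_seizure", "seizure"),
                            ridge = 0.01, source_manifest = character(0)) {
  label <- match.arg(label)
  m <- feature_matrix(rows)
  n <- nrow(m)
  if (n < MIN_REFERENCE_ROWS)
    stop(sprintf(
      "reference requires at least %d feature rows to estimate the 8x8 variance-covariance matrix; got %d",
      MIN_REFERENCE_ROWS, n), call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite feature values", call. = FALSE)
  mu <- colMeans(m)
  centred <- sweep(m, 2L, mu)
  cov_pop <- crossprod(centred) / n
  cov_reg <- regularize_covariance(cov_pop, ridge = ridge)
  new_reference_model(label = label, mean = mu, covariance = cov_reg,
                      n_rows = n,
                      ridge_used = attr(cov_reg, "lambda"),
                      source_manifest = as.character(source_manifest))
}

new_reference_model <- function(label, mean, covariance, n_rows, ridge_used,
                                source_manifest) {
  covariance <- unname(as.matrix(covariance))
  attr(covariance, "lambda") <- NULL
  dimnames(covariance) <- list(FEATURE_COLS, FEATURE_COLS)
  mean <- stats::setNames(as.numeric(mean), FEATURE_COLS)
  chol_u <- tryCatch(chol(covariance), error = function(e)
    stop("reference covariance is not positive definite", call. = FALSE))
  structure(
    list(label = label, mean = mean, covariance = covariance,
         n_rows = as.integer(n_rows), ridge_used = as.numeric(ridge_used),
         source_manifest = source_manifest, chol = chol_u),
    class = "reference_model")
}

#' Condition a covariance matrix for invertibility
#'
#' Returns `cov + lambda * I` with `lambda = ridge * trace(cov)/p` whenever the
#' smallest eigenvalue is at or below `1e-8 * trace(cov)/p`; a well-conditioned
#' input is returned unchanged (`lambda = 0`). A zero-trace (all-identical
#' rows) input falls back to an absolute floor `lambda = 1e-12` so degenerate
#' references remain usable. The applied lambda is attached as attribute
#' `"lambda"`.
#'
#' @param cov symmetric `p x p` matrix.
#' @param ridge relative ridge strength (default 0.01).
#' @return positive-definite matrix of the same dimension.
#' @export
regularize_covariance <- function(cov, ridge = 0.01) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || !isSymmetric(unname(cov), tol = 1e-10))
    stop("covariance must be a symmetric square matrix", call. = FALSE)
  stopifnot_scalar_number(ridge, "ridge", nonnegative = TRUE)
  p <- nrow(cov)
  tr <- sum(diag(cov))
  eps_cond <- 1e-8 * tr / p
  lambda <- 0
  ev_min <- min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= eps_cond) {
    lambda <- ridge * tr / p
    if (lambda <= 0) lambda <- 1e-12
    cov <- cov + diag(lambda, p)
  }
  attr(cov, "lambda") <- lambda
  cov
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> label=%s, n_rows=%d, ridge_used=%g\n",
              x$label, x$n_rows, x$ridge_used))
  cat("  feature means:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Save a reference model to JSON
#'
#' Schema: `{schema_version, label, mean[8], covariance[8][8], n_rows,
#' ridge_used, source_manifest[]}`, written at full double precision so a
#' save/load round trip is elementwise exact.
#'
#' @param model a `reference_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_reference <- function(model, path) {
  stopifnot(inherits(model, "reference_model"))
  payload <- list(
    schema_version = REFERENCE_SCHEMA_VERSION,
    label = model$label,
    mean = unname(model$mean),
    covariance = unname(model$covariance),
    n_rows = model$n_rows,
    ridge_used = model$ridge_used,
    source_manifest = model$source_manifest)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a reference model from JSON
#'
#' Validates schema version, field presence, matrix shape and the minimum-rows
#' invariant before reconstructing the model (and its cached factorisation).
#'
#' @param path JSON file written by [save_reference()].
#' @return a `reference_model`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("schema_version", "label", "mean", "covariance", "n_rows",
            "ridge_used")
  missing <- setdiff(need, names(payload))
  if (length(missing) > 0L)
    stop("reference JSON missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (payload$schema_version != REFERENCE_SCHEMA_VERSION)
    stop(sprintf("unsupported reference schema version %s (expected %d)",
                 payload$schema_version, REFERENCE_SCHEMA_VERSION),
         call. = FALSE)
  cov <- as.matrix(payload$covariance)
  if (length(payload$mean) != 8L || !all(dim(cov) == c(8L, 8L)))
    stop("reference JSON has wrong mean/covariance dimensions", call. = FALSE)
  if (payload$n_rows < MIN_REFERENCE_ROWS)
    stop(sprintf("reference n_rows=%d violates the %d-row minimum",
                 payload$n_rows, MIN_REFERENCE_ROWS), call. = FALSE)
  if (!payload$label %in% c("seizure", "non_seizure"))
    stop("reference label must be 'seizure' or 'non_seizure'", call. = FALSE)
  new_reference_model(label = payload$label, mean = payload$mean,
                      covariance = cov, n_rows = payload$n_rows,
                      ridge_used = payload$ridge_used,
                      source_manifest = as.character(payload$source_manifest %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
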