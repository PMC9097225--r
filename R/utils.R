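# Internal helpers shared across modules.

# Feature column order used everywhere a feature matrix is built or consumed.
FEATURE_COLS <- c("mean_x", "mean_y", "mean_z", "mean_r",
                  "cv_x", "cv_y", "cv_z", "cv_r")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulator calls do not perturb the session RNG.
#' A `NULL` seed evaluates `code` against the current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Coerce a per-second feature object (data.frame from per_second_features(), or
# a bare matrix with the right columns) to an n x 8 numeric matrix.
feature_matrix <- function(features) {
  if (is.matrix(features)) {
    if (ncol(features) == length(FEATURE_COLS) && is.null(colnames(features)))
      colnames(features) <- FEATURE_COLS
    m <- features[, FEATURE_COLS, drop = FALSE]
  } else {
    missing <- setdiff(FEATURE_COLS, names(features))
    if (length(missing) > 0L)
      stop("feature input lacks columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    m <- as.matrix(features[, FEATURE_COLS, drop = FALSE])
  }
  storage.mode(m) <- "double"
  m
}

# Seconds (0-based) attached to a feature object; defaults to 0..n-1.
feature_seconds <- function(features) {
  if (!is.matrix(features) && !is.null(features[["second"]]))
    as.integer(features[["second"]])
  else
    seq_len(NROW(features)) - 1L
}

stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                    nonnegative = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonnegative && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  if (integer && x != trunc(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(x)
}
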