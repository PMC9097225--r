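# Shared fixtures, built in code at test time.

# Random uniformly sampled trace with values safely inside the device range.
random_trace <- function(n = 250, rate = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  accel_trace(matrix(stats::rnorm(n * 3, sd = 0.5), ncol = 3),
              sampling_rate_hz = rate)
}

FEATURE_COLS_T <- c("mean_x", "mean_y", "mean_z", "mean_r",
                    "cv_x", "cv_y", "cv_z", "cv_r")

feature_matrix_for_tests <- function(f) as.matrix(f[, FEATURE_COLS_T])

# Concatenate per-second feature frames with contiguous 0-based seconds.
combine_features <- function(...) {
  out <- do.call(rbind, list(...))
  out$second <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}

# One fitted detector shared across test files: references built from the
# simulator's study conditions (1,215 s of the 15 daily activities for the
# RDNE; one 5 s tonic + 25 s clonic seizure for the RDE), fixed seed.
fixture_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      day <- simulate_day(rdne_schedule(), seed = 101)
      sz <- simulate_gtcs(tonic_s = 5, clonic_s = 25, seed = 102)
      feats <- combine_features(per_second_features(day$trace),
                                per_second_features(sz$trace))
      cls <- c(rep("non_seizure", 1215L), rep("seizure", 30L))
      cache <<- seizure_detector(feats, cls)
    }
    cache
  }
})

# Schedule for a synthetic monitoring day with k embedded seizures (5 s tonic
# + 25 s clonic each), separated by >= 120 s of daily activity so the default
# 60-s refractory never merges two seizures.
day_with_seizures_schedule <- function(k, block_s = 150) {
  acts <- daily_activity_names()
  names <- c()
  durs <- c()
  add_block <- function(i0) {
    nm <- acts[((i0 + seq_len(10)) %% length(acts)) + 1L]
    names <<- c(names, nm)
    durs <<- c(durs, rep(block_s / 10, 10))
  }
  add_block(0)
  for (i in seq_len(k)) {
    names <- c(names, "gtcs_tonic", "gtcs_clonic")
    durs <- c(durs, 5, 25)
    add_block(i * 3)
  }
  sim_schedule(names, durs)
}
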