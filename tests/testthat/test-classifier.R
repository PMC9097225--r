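# Mahalanobis distances, epoch aggregation and the shorter-distance rule.

random_model <- function(n = 200, label = "non_seizure", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shift <- stats::rnorm(8, sd = 2)
  A <- matrix(stats::rnorm(64), 8)
  rows <- sweep(matrix(stats::rnorm(n * 8), ncol = 8) %*% A, 2, shift, "+")
  build_reference(rows, label)
}

test_that("squared distance is zero at the mean and Euclidean under identity", {
  model <- random_model(seed = 31)
  expect_equal(mahalanobis_sq(model$mean, model), 0, tolerance = 1e-12)
  # identity covariance: unit basis offset gives squared distance 1
  rows <- matrix(stats::rnorm(5000 * 8), ncol = 8)  # approx identity cov
  id_model <- build_reference(rows, "seizure")
  # exact check against the stored covariance through the oracle instead
  x <- id_model$mean + c(1, rep(0, 7))
  d2 <- mahalanobis_sq(x, id_model)
  oracle <- drop(t(c(1, rep(0, 7))) %*% solve(id_model$covariance) %*%
                   c(1, rep(0, 7)))
  expect_equal(d2, oracle, tolerance = 1e-10)
})

test_that("factorized solve equals the explicit-inverse quadratic form", {
  set.seed(32)
  for (i in 1:50) {
    model <- random_model(n = 60)
    x <- stats::rnorm(8, sd = 3)
    diff <- x - model$mean
    oracle <- drop(t(diff) %*% solve(model$covariance) %*% diff)
    got <- mahalanobis_sq(x, model)
    expect_equal(got, oracle, tolerance = 1e-10)
    # independent cross-check against stats::mahalanobis
    expect_equal(got,
                 unname(stats::mahalanobis(matrix(x, 1), model$mean,
                                           model$covariance)),
                 tolerance = 1e-10)
  }
})

test_that("dimension mismatches are rejected", {
  model <- random_model(seed = 33)
  expect_error(mahalanobis_sq(1:3, model), "length-8")
  expect_error(epoch_distance(matrix(0, 9, 8), model, "nope"))
})

test_that("epoch distance aggregates scaled per-row distances (loop oracle)", {
  set.seed(34)
  model <- random_model(n = 100)
  ep <- matrix(stats::rnorm(9 * 8, sd = 2), 9)
  d_rows <- sapply(1:9, function(i) sqrt(mahalanobis_sq(ep[i, ], model) / 8))
  expect_equal(epoch_distance(ep, model, "mean"), mean(d_rows), tolerance = 1e-10)
  expect_equal(epoch_distance(ep, model, "median"), stats::median(d_rows),
               tolerance = 1e-10)
  expect_equal(epoch_distance(ep, model, "max"), max(d_rows), tolerance = 1e-10)
  expect_gte(epoch_distance(ep, model, "max"), epoch_distance(ep, model, "mean"))
  # an epoch sitting exactly on the mean scores zero for every aggregator
  ep0 <- matrix(rep(model$mean, each = 9), 9)
  colnames(ep0) <- colnames(ep)
  for (agg in c("mean", "median", "max"))
    expect_equal(epoch_distance(ep0, model, agg), 0, tolerance = 1e-12)
})

test_that("the shorter-distance rule decides seizure iff RDE is nearer", {
  expect_identical(shorter_distance_rule(1, 2), "seizure")
  expect_identical(shorter_distance_rule(2, 1), "non_seizure")
  expect_identical(shorter_distance_rule(1.5, 1.5), "non_seizure")  # tie
})

test_that("classify_epoch reports both distances and enforces distinct labels", {
  rde <- random_model(label = "seizure", seed = 35)
  rdne <- random_model(label = "non_seizure", seed = 36)
  ep <- matrix(stats::rnorm(9 * 8), 9)
  attr(ep, "start_second") <- 4L
  res <- classify_epoch(ep, rde, rdne)
  expect_equal(res$epoch_start_s, 4L)
  expect_identical(res$decision,
                   shorter_distance_rule(res$distance_rde, res$distance_rdne))
  # swapping the model arguments inverts every non-tie decision
  res_sw <- classify_epoch(ep, rdne, rde)
  expect_equal(res_sw$distance_rde, res$distance_rdne, tolerance = 1e-12)
  expect_false(res_sw$decision == res$decision &&
                 res$distance_rde != res$distance_rdne)
  expect_error(classify_epoch(ep, rde, rde), "same label")
})

test_that("batch classification equals the per-epoch path for every aggregator", {
  rde <- random_model(label = "seizure", seed = 37)
  rdne <- random_model(label = "non_seizure", seed = 38)
  set.seed(39)
  feats <- matrix(stats::rnorm(60 * 8), ncol = 8)
  for (agg in c("mean", "median", "max")) {
    batch <- classify_epochs(feats, rde, rdne, aggregator = agg)
    eps <- make_epochs(feats)
    expect_equal(nrow(batch), length(eps))
    for (i in seq_len(length(eps))) {
      one <- classify_epoch(eps[[i]], rde, rdne, agg)
      expect_equal(batch$distance_rde[i], one$distance_rde, tolerance = 1e-10)
      expect_equal(batch$distance_rdne[i], one$distance_rdne, tolerance = 1e-10)
      expect_identical(batch$decision[i], one$decision)
    }
  }
})

test_that("distances and decisions are affine invariant", {
  set.seed(40)
  n <- 300
  rows_a <- matrix(stats::rnorm(n * 8), ncol = 8)
  rows_b <- sweep(matrix(stats::rnorm(n * 8), ncol = 8), 2, 4, "+")
  x <- matrix(stats::rnorm(20 * 8, sd = 2), ncol = 8)
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(64), 8) + 2 * diag(8)   # comfortably invertible
    b <- stats::rnorm(8)
    tf <- function(m) sweep(m %*% A, 2, b, "+")
    m1 <- build_reference(rows_a, "seizure")
    m2 <- build_reference(rows_b, "non_seizure")
    m1t <- build_reference(tf(rows_a), "seizure")
    m2t <- build_reference(tf(rows_b), "non_seizure")
    expect_equal(m1t$ridge_used, 0)
    expect_equal(m2t$ridge_used, 0)
    expect_equal(mahalanobis_sq(tf(x), m1t), mahalanobis_sq(x, m1),
                 tolerance = 1e-6)
    expect_equal(mahalanobis_sq(tf(x), m2t), mahalanobis_sq(x, m2),
                 tolerance = 1e-6)
  }
})

test_that("well-separated Gaussian classes classify perfectly over 10,000 epochs", {
  set.seed(41)
  n_rows <- 10008L
  mu_a <- rep(0, 8)
  mu_b <- rep(8, 8)           # 8 pooled SDs apart per feature
  rows_a <- matrix(stats::rnorm(400 * 8), ncol = 8)
  rows_b <- sweep(matrix(stats::rnorm(400 * 8), ncol = 8), 2, mu_b, "+")
  rde <- build_reference(rows_b, "seizure")
  rdne <- build_reference(rows_a, "non_seizure")
  stream_a <- matrix(stats::rnorm(n_rows * 8), ncol = 8)
  stream_b <- sweep(matrix(stats::rnorm(n_rows * 8), ncol = 8), 2, mu_b, "+")
  res_a <- classify_epochs(stream_a, rde, rdne)
  res_b <- classify_epochs(stream_b, rde, rdne)
  expect_equal(nrow(res_a), 10000L)
  expect_true(all(res_a$decision == "non_seizure"))
  expect_true(all(res_b$decision == "seizure"))
})
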