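# Per-second feature extraction and epoching.

test_that("resultant force matches known values and an independent norm", {
  expect_identical(resultant_force(0, 0, 1), 1)
  expect_identical(resultant_force(3, 4, 0), 5)
  set.seed(42)
  for (i in 1:1000) {
    v <- stats::rnorm(3)
    expect_equal(resultant_force(v[1], v[2], v[3]), norm(v, type = "2"))
  }
  expect_error(resultant_force(NA, 0, 0), "non-finite")
})

test_that("coefficient of variation: zero variance, scale invariance, oracle", {
  expect_identical(coefficient_of_variation(c(5, 5, 5, 5)), 0)
  # (1,2,3): population sd via a two-pass oracle
  x <- c(1, 2, 3)
  m <- (1 + 2 + 3) / 3
  sd_pop <- sqrt(((1 - m)^2 + (2 - m)^2 + (3 - m)^2) / 3)
  expect_equal(coefficient_of_variation(x), sd_pop / m)
  # positive scaling leaves the ratio unchanged when the mean clears the floor
  set.seed(3)
  for (i in 1:20) {
    y <- stats::rnorm(30, mean = 2)
    c_ <- stats::runif(1, 0.5, 10)
    expect_equal(coefficient_of_variation(c_ * y),
                 coefficient_of_variation(y), tolerance = 1e-12)
  }
  expect_error(coefficient_of_variation(1), "at least 2")
})

test_that("near-zero means are guarded by the denominator floor", {
  x <- c(-0.01, 0.01, -0.01, 0.01)  # mean 0, sd 0.01
  expect_equal(coefficient_of_variation(x, mean_floor = 0.05), 0.01 / 0.05)
})

test_that("per-second features agree with a brute-force per-bin loop", {
  set.seed(9)
  rate <- 50
  t <- (0:(rate * 7 - 1)) / rate
  s <- cbind(0.3 * sin(2 * pi * 1.7 * t) + stats::rnorm(length(t), 0, 0.05),
             0.1 * sin(2 * pi * 3.1 * t + 1),
             1 + 0.2 * sin(2 * pi * 0.9 * t))
  tr <- accel_trace(s, sampling_rate_hz = rate)
  feats <- per_second_features(tr, mean_floor = 0.05)
  expect_equal(nrow(feats), 7L)
  for (k in 0:6) {
    rows <- (k * rate + 1):((k + 1) * rate)
    bin <- s[rows, , drop = FALSE]
    r <- sqrt(rowSums(bin^2))
    ch <- cbind(bin, r)
    for (j in 1:4) {
      mu <- mean(ch[, j])
      sd_pop <- sqrt(mean((ch[, j] - mu)^2))
      expect_equal(feats[[c("mean_x", "mean_y", "mean_z", "mean_r")[j]]][k + 1],
                   mu, tolerance = 1e-12)
      expect_equal(feats[[c("cv_x", "cv_y", "cv_z", "cv_r")[j]]][k + 1],
                   sd_pop / max(abs(mu), 0.05), tolerance = 1e-10)
    }
  }
})

test_that("a trailing partial second is dropped and sub-second input errors", {
  tr <- random_trace(n = 485, seed = 5)   # 9.7 s at 50 Hz
  expect_equal(nrow(per_second_features(tr)), 9L)
  tr9 <- random_trace(n = 450, seed = 5)  # exact fit
  expect_equal(nrow(per_second_features(tr9)), 9L)
  expect_error(per_second_features(random_trace(n = 49)), "shorter than one second")
})

test_that("features are invariant to permuting samples within a bin", {
  tr <- random_trace(n = 150, seed = 6)
  base <- per_second_features(tr)
  set.seed(1)
  perm <- unlist(lapply(0:2, function(k) k * 50 + sample(50)))
  tr2 <- accel_trace(tr$samples[perm, ], sampling_rate_hz = 50)
  expect_equal(per_second_features(tr2), base, tolerance = 1e-12)
})

test_that("epoch count follows floor((T - L)/stride) + 1 (enumeration oracle)", {
  # explicit enumeration oracle: walk the starts
  count_oracle <- function(T, L, stride) {
    n <- 0L; s <- 0L
    while (s + L <= T) { n <- n + 1L; s <- s + stride }
    n
  }
  set.seed(11)
  for (i in 1:60) {
    T <- sample(0:60, 1); L <- sample(1:12, 1); stride <- sample(1:5, 1)
    feats <- matrix(stats::rnorm(T * 8), ncol = 8)
    eps <- make_epochs(feats, length_s = L, stride_s = stride)
    expect_identical(length(eps), count_oracle(T, L, stride))
    if (T >= L) expect_identical(length(eps), (T - L) %/% stride + 1L)
  }
  # boundary cases
  f9 <- matrix(0, 9, 8)
  expect_identical(length(make_epochs(f9, 9)), 1L)
  expect_identical(length(make_epochs(matrix(0, 8, 8), 9)), 0L)
})

test_that("epochs expose consecutive feature rows with the right start", {
  tr <- random_trace(n = 50 * 15, seed = 8)
  feats <- per_second_features(tr)
  eps <- make_epochs(feats, length_s = 9, stride_s = 1)
  expect_identical(length(eps), 7L)
  ep3 <- eps[[3]]
  expect_identical(attr(ep3, "start_second"), 2L)
  expect_equal(unname(ep3), unname(feature_matrix_for_tests(feats)[3:11, ]),
               ignore_attr = TRUE)
  expect_identical(epoch_starts(eps), 0:6)
})

test_that("feature CSV round trips", {
  feats <- per_second_features(random_trace(n = 300, seed = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(feats, path)
  back <- read_features_csv(path)
  expect_equal(back$mean_x, feats$mean_x, tolerance = 1e-12)
  expect_equal(back$second, feats$second)
})
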