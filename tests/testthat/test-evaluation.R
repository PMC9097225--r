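# Event matching and epoch-level scoring.

fake_events <- function(onsets) {
  data.frame(onset_s = onsets, trigger_epoch_start_s = onsets,
             distance_rde = rep(1, length(onsets)),
             distance_rdne = rep(2, length(onsets)))
}

test_that("three seizures matched by three events gives perfect recovery", {
  truth <- label_intervals(rep("gtcs_clonic", 3),
                           c(100, 500, 900), c(130, 530, 930))
  ev <- fake_events(c(102, 498, 905))   # one slightly early, within tolerance
  rep <- evaluate_detection(ev, truth, duration_s = 3600)
  expect_equal(rep$true_positives, 3L)
  expect_equal(rep$false_negatives, 0L)
  expect_equal(rep$false_positive_events, 0L)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$false_positives_per_24h, 0)
  expect_equal(rep$mean_latency_s, mean(c(2, -2, 5)))
})

test_that("no seizures and no events gives zero FP rate and undefined sensitivity", {
  truth <- label_intervals("walking", 0, 100)
  rep <- evaluate_detection(fake_events(numeric(0)), truth, duration_s = 86400)
  expect_equal(rep$false_positives_per_24h, 0)
  expect_true(is.na(rep$sensitivity))
})

test_that("matching is greedy one-to-one and order-invariant", {
  truth <- label_intervals(c("gtcs_clonic", "gtcs_clonic"),
                           c(100, 200), c(130, 230))
  # two events inside the first seizure: only one matches, the other is FP
  m <- match_events(fake_events(c(105, 110)), truth)
  expect_equal(nrow(m$matches), 1L)
  expect_equal(nrow(m$unmatched_events), 1L)
  expect_equal(nrow(m$unmatched_truth), 1L)
  # permuting the event order never changes the matching
  set.seed(81)
  onsets <- c(95, 112, 205, 700, 42)
  base <- match_events(fake_events(onsets), truth)
  for (i in 1:10) {
    perm <- match_events(fake_events(sample(onsets)), truth)
    expect_equal(perm$matches, base$matches)
    expect_equal(sort(perm$unmatched_events$onset_s),
                 sort(base$unmatched_events$onset_s))
  }
  expect_error(match_events(fake_events(1), truth, tolerance_s = -1), ">= 0")
})

test_that("an event before the tolerance window is a false positive", {
  truth <- label_intervals("gtcs_clonic", 100, 130)
  rep <- evaluate_detection(fake_events(93), truth, duration_s = 3600,
                            tolerance_s = 5)
  expect_equal(rep$true_positives, 0L)
  expect_equal(rep$false_positive_events, 1L)
  rep2 <- evaluate_detection(fake_events(95), truth, duration_s = 3600,
                             tolerance_s = 5)
  expect_equal(rep2$true_positives, 1L)
})

test_that("epoch confusion matches a hand-counted oracle on 20 epochs", {
  set.seed(82)
  truth <- label_intervals(c("walking", "gtcs_clonic", "sitting"),
                           c(0, 8, 20), c(8, 20, 40))
  res <- data.frame(epoch_start_s = 0:19,
                    distance_rde = stats::runif(20),
                    distance_rdne = stats::runif(20))
  res$decision <- shorter_distance_rule(res$distance_rde, res$distance_rdne)
  attr(res, "epoch_length_s") <- 9L
  tab <- epoch_confusion(res, truth)
  # hand count: epoch s covers seconds s..s+8; seizure truth iff >= 4.5 of
  # those seconds lie in [8, 20)
  truth_cls <- sapply(0:19, function(s) {
    secs <- s:(s + 8)
    if (sum(secs >= 8 & secs < 20) >= 4.5) "seizure" else "non_seizure"
  })
  for (d in c("seizure", "non_seizure")) for (t in c("seizure", "non_seizure"))
    expect_equal(unname(tab[d, t]), sum(res$decision == d & truth_cls == t))
  expect_equal(sum(tab), 20L)   # conservation
})

test_that("a perfectly classified all-seizure stream has zero off-diagonals", {
  truth <- label_intervals("gtcs_clonic", 0, 30)
  res <- data.frame(epoch_start_s = 0:21, distance_rde = 1, distance_rdne = 2,
                    decision = "seizure")
  attr(res, "epoch_length_s") <- 9L
  tab <- epoch_confusion(res, truth)
  expect_equal(unname(tab["seizure", "seizure"]), 22L)
  expect_equal(unname(tab["seizure", "non_seizure"]), 0L)
  expect_equal(unname(tab["non_seizure", "seizure"]), 0L)
})

test_that("scores are invariant to a common time shift", {
  truth <- label_intervals(c("gtcs_clonic", "gtcs_clonic"),
                           c(50, 300), c(80, 330))
  ev <- fake_events(c(52, 340))
  base <- evaluate_detection(ev, truth, duration_s = 1000)
  shift <- 123
  truth2 <- label_intervals(truth$label, truth$start_s + shift,
                            truth$end_s + shift)
  ev2 <- fake_events(ev$onset_s + shift)
  shifted <- evaluate_detection(ev2, truth2, duration_s = 1000)
  expect_equal(shifted$sensitivity, base$sensitivity)
  expect_equal(shifted$false_positives_per_24h, base$false_positives_per_24h)
  expect_equal(shifted$mean_latency_s, base$mean_latency_s)
})

test_that("adjacent tonic and clonic intervals count as one seizure", {
  truth <- label_intervals(c("gtcs_tonic", "gtcs_clonic"), c(100, 105),
                           c(105, 130))
  rep <- evaluate_detection(fake_events(101), truth, duration_s = 3600)
  expect_equal(rep$true_positives, 1L)
  expect_equal(rep$false_negatives, 0L)
})

test_that("reports serialise to JSON", {
  truth <- label_intervals("gtcs_clonic", 10, 40)
  rep <- evaluate_detection(fake_events(12), truth, duration_s = 3600)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$sensitivity, 1)
  expect_equal(back$true_positives, 1L)
})
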