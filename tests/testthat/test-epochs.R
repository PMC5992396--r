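test_that("epochs have the right spans and reference points", {
  pre <- small_pre()
  ep <- small_epochs()
  ev <- attr(ep, "events")
  fs <- pre$recording$fs
  for (e in ep) {
    expect_equal(ncol(e$eeg), 375)  # exactly 1.5 s at 250 Hz
    if (e$kind == "pre_response") {
      resp <- ev$response_time_s[e$event]
      expect_equal(e$t_start, round((resp - 1.5) * fs) / fs, tolerance = 1e-9)
      # a 700 ms reaction leaves the stimulus inside the window
      expect_lte(ev$stimulus_time_s[e$event] - e$t_start, 1.5)
    }
    if (e$kind == "post_stimulus") {
      expect_equal(e$t_start,
                   round(ev$stimulus_time_s[e$event] * fs) / fs,
                   tolerance = 1e-9)
    }
  }
})

test_that("non-braking epochs keep 3 s clearance from all events, exhaustively", {
  ep <- small_epochs()
  ev <- attr(ep, "events")
  anchors <- c(ev$stimulus_time_s, ev$response_time_s)
  anchors <- anchors[!is.na(anchors)]
  nb <- Filter(function(e) e$kind == "non_braking", ep)
  expect_gt(length(nb), 0)
  for (e in nb) {
    lo <- e$t_start; hi <- e$t_start + 1.5
    d <- pmin(abs(anchors - lo), abs(anchors - hi))
    d[anchors > lo & anchors < hi] <- 0
    expect_gte(min(d), 3 - 1e-6)
  }
  # and no two epochs overlap
  starts <- vapply(nb, `[[`, 0, "t_start")
  expect_true(all(diff(sort(starts)) >= 1.5 - 1e-9))
})

test_that("pre-response and non-braking epochs come in balanced pairs", {
  ep <- small_epochs()
  kinds <- vapply(ep, `[[`, "", "kind")
  ds <- small_dataset()
  expect_equal(sum(ds$y == 1), sum(ds$y == -1))
  expect_lte(sum(ds$y == 1), sum(kinds == "pre_response"))
  # one pre-response and one non-braking instance per contributing event
  tab <- table(ds$meta$event)
  expect_true(all(tab == 2))
})

test_that("the 10 windows tile 375 samples as alternating 38/37", {
  b <- brakesense:::window_boundaries(375, 10)
  expect_equal(b, c(38, 75, 113, 150, 188, 225, 263, 300, 338, 375))
  sizes <- diff(c(0, b))
  expect_equal(sum(sizes), 375)
  expect_true(all(sizes %in% c(37, 38)))
})

test_that("feature maps equal brute-force window means", {
  # channel = sample index: compare against an explicit loop
  eeg <- matrix(rep(0:374, each = 7), nrow = 7, byrow = FALSE)
  eeg[2, ] <- (0:374)^1.5  # a second, nonlinear channel
  ep <- list(eeg = eeg, kind = "pre_response", t_start = 0, event = 1L)
  fm <- epoch_to_feature_map(ep)
  expect_equal(dim(fm$X), c(7, 10))
  bounds <- c(38, 75, 113, 150, 188, 225, 263, 300, 338, 375)
  starts <- c(1, head(bounds, -1) + 1)
  for (j in 1:10) {
    for (i in c(1, 2)) {
      expect_equal(fm$X[i, j], mean(eeg[i, starts[j]:bounds[j]]))
    }
  }
  expect_equal(fm$label, 1)
})

test_that("a constant channel yields ten identical features", {
  eeg <- matrix(3.25, 7, 375)
  fm <- epoch_to_feature_map(list(eeg = eeg, kind = "non_braking",
                                  t_start = 0, event = 1L))
  expect_true(all(fm$X == 3.25))
  expect_equal(fm$label, -1)
})

test_that("features are linear in the epoch amplitude", {
  ep <- Filter(function(e) e$kind == "pre_response", small_epochs())[[1]]
  f1 <- epoch_to_feature_map(ep)
  ep2 <- ep; ep2$eeg <- 2.5 * ep$eeg
  f2 <- epoch_to_feature_map(ep2)
  expect_equal(f2$X, 2.5 * f1$X)
})

test_that("flattening is channel-major row-wise and invertible", {
  eeg <- matrix(rnorm(7 * 375), 7, 375)
  fm <- epoch_to_feature_map(list(eeg = eeg, kind = "pre_response",
                                  t_start = 0, event = 1L))
  expect_equal(fm$x, as.vector(t(fm$X)))
  expect_equal(matrix(fm$x, 7, 10, byrow = TRUE), unname(fm$X))
})

test_that("wrong epoch lengths are rejected", {
  expect_error(epoch_to_feature_map(list(eeg = matrix(0, 7, 370),
                                         kind = "pre_response",
                                         t_start = 0, event = 1L)),
               "bad_epoch_length")
})

test_that("datasets are deterministic and post-stimulus epochs unlabeled", {
  ep <- small_epochs()
  d1 <- build_dataset(ep)
  d2 <- build_dataset(ep)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  post <- Filter(function(e) e$kind == "post_stimulus", ep)[[1]]
  expect_true(is.na(epoch_to_feature_map(post)$label))
  expect_error(build_dataset(list()), "length")
})

test_that("null-world class distributions are indistinguishable per feature", {
  ds <- null_dataset()
  p <- vapply(seq_len(ncol(ds$x)), function(j)
    suppressWarnings(wilcox.test(ds$x[ds$y == 1, j],
                                 ds$x[ds$y == -1, j])$p.value),
    numeric(1))
  expect_lt(mean(p < 0.05), 0.2)
  expect_gt(median(p), 0.15)
})
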