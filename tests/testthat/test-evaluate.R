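test_that("accuracy follows the confusion-count formula", {
  expect_equal(accuracy_pct(3, 2, 1, 2), 62.5)
  expect_equal(accuracy_pct(10, 10, 0, 0), 100)
  expect_error(accuracy_pct(0, 0, 0, 0), "empty_confusion")
})

test_that("accuracy equals a direct recount on random prediction sets", {
  set.seed(12)
  for (rep in 1:10) {
    truth <- sample(c(-1, 1), 50, replace = TRUE)
    pred <- sample(c(-1, 1), 50, replace = TRUE)
    tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == -1 & truth == -1)
    fp <- sum(pred == 1 & truth == -1); fn <- sum(pred == -1 & truth == 1)
    expect_equal(accuracy_pct(tp, tn, fp, fn), 100 * mean(pred == truth))
  }
})

test_that("chance level matches the brute-force binomial oracle up to n = 2000", {
  # oracle: exact partial sums of the binomial pmf
  for (alpha in c(0.05, 0.01)) {
    for (n in c(1:50, seq(60, 600, by = 27), seq(700, 2000, by = 83))) {
      cdf <- cumsum(dbinom(0:n, n, 0.5))
      k_star <- (0:n)[which(cdf >= 1 - alpha - 1e-12)[1]]
      expect_equal(chance_level(2, n, alpha)$k, k_star,
                   label = paste("n =", n, "alpha =", alpha))
    }
  }
})

test_that("chance level reproduces the reference values", {
  expect_equal(chance_level(2, 20, 0.05)$threshold, 70)
  expect_equal(chance_level(2, 600, 0.05)$threshold, 53.33, tolerance = 1e-3)
  # decreases with sample size, increases the confidence demand
  expect_lt(chance_level(2, 600, 0.05)$threshold,
            chance_level(2, 100, 0.05)$threshold)
  expect_gt(chance_level(2, 600, 0.01)$threshold,
            chance_level(2, 600, 0.05)$threshold)
  # alpha -> 0.5 approaches 50% from above
  expect_lt(chance_level(2, 1000, 0.499)$threshold, 51)
  expect_gte(chance_level(2, 1000, 0.499)$threshold, 50)
})

test_that("invalid chance-level inputs are rejected", {
  expect_error(chance_level(2, 100, 1.5), "invalid_alpha")
  expect_error(chance_level(2, 100, 0), "invalid_alpha")
  expect_error(chance_level(2, 0, 0.05), "invalid_n")
})

test_that("ROC endpoints, perfect ranking and degenerate labels", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, -1, -1))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1); expect_equal(tail(r$points$tpr, 1), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, -1, -1))$auc, 0)
  expect_error(roc_auc(runif(5), rep(1, 5)), "single_class")
})

test_that("AUC equals the pairwise rank-comparison oracle, ties included", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 40
    labels <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)  # rounding forces ties
    pos <- scores[labels == 1]; neg <- scores[labels == -1]
    wins <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(scores, labels)$auc, mean(wins), tolerance = 1e-12)
  }
})

test_that("AUC of label-independent scores concentrates near one half", {
  set.seed(31)
  scores <- rnorm(1000)
  labels <- sample(c(-1, 1), 1000, replace = TRUE)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.05)
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- rnorm(80); labels <- sample(c(-1, 1), 80, replace = TRUE)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c(-1, 1),
    direction = "<"))))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-9)
})

test_that("precision-recall reaches full recall and respects prevalence", {
  pr <- precision_recall(c(0.9, 0.8, 0.3, 0.2), c(1, -1, 1, -1))
  expect_equal(tail(pr$recall, 1), 1)
  expect_equal(tail(pr$precision, 1), 0.5)
})

test_that("significance tests behave at the null and under shifts", {
  st <- significance_tests(rep(70, 10), chance = 70)
  expect_equal(st$signed_rank$p, 1)
  set.seed(51)
  a <- rnorm(100)
  st2 <- significance_tests(a, acc2 = a)
  expect_gt(st2$rank_sum$p, 0.9)
  # shifted by two standard deviations: compare against a permutation oracle
  b <- rnorm(100) + 2
  st3 <- significance_tests(b, acc2 = a)
  expect_lt(st3$rank_sum$p, 0.001)
  perm_stat <- function(x, y) mean(x) - mean(y)
  obs <- perm_stat(b, a)
  pooled <- c(a, b)
  perms <- replicate(500, {
    idx <- sample(200, 100)
    perm_stat(pooled[idx], pooled[-idx])
  })
  expect_lt(mean(abs(perms) >= abs(obs)), 0.01)
  # omnibus across three groups
  st4 <- significance_tests(a, groups = list(a = a, b = b, c = rnorm(100)))
  expect_lt(st4$kruskal$p, 0.001)
})

test_that("repeated holdout returns one accuracy per repetition", {
  ds <- toy_signed_dataset(n = 80)
  ev <- repeated_holdout(ds, trainer_perfect(), n_repetitions = 25, seed = 2)
  expect_length(ev$accuracy, 25)
  expect_equal(ev$mean, 100)
  expect_equal(ev$auc, 1)
  expect_true(all(vapply(ev$confusion, sum, 0) == nrow(ds$x) -
                    length(brakesense:::.stratified_split(ds$y, 0.75))))
})

test_that("a coin-flip classifier scores near 50% on balanced data", {
  ds <- toy_signed_dataset(n = 80)
  ev <- repeated_holdout(ds, trainer_coin(), n_repetitions = 100, seed = 3)
  expect_lt(abs(ev$mean - 50), 3)
  expect_lt(abs(ev$auc - 0.5), 0.05)
})

test_that("splits are stratified and reproducible", {
  ds <- toy_signed_dataset(n = 60)
  ev1 <- repeated_holdout(ds, trainer_perfect(), n_repetitions = 5, seed = 4)
  ev2 <- repeated_holdout(ds, trainer_perfect(), n_repetitions = 5, seed = 4)
  expect_identical(ev1$accuracy, ev2$accuracy)
  set.seed(1)
  idx <- brakesense:::.stratified_split(ds$y, 0.75)
  expect_equal(sum(ds$y[idx] == 1), round(0.75 * sum(ds$y == 1)))
  expect_equal(sum(ds$y[idx] == -1), round(0.75 * sum(ds$y == -1)))
})
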