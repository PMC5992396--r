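#' Classification accuracy from confusion counts
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`, in percent.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return accuracy in percent.
#' @export
#' @examples
#' accuracy_pct(3, 2, 1, 2)  # 62.5
accuracy_pct <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty_confusion: all counts are zero")
  100 * (tp + tn) / total
}

#' Significant classification-accuracy chance level
#'
#' The smallest accuracy significantly above random guessing under an exact
#' binomial model: with `n_samples` Bernoulli trials at success probability
#' `1 / n_classes`, the threshold is `100 * k / n_samples` where `k` is the
#' smallest count whose binomial CDF reaches `1 - alpha`. For two classes,
#' 600 samples and `alpha = 0.05` this gives 53.33%.
#'
#' @param n_classes number of classes.
#' @param n_samples number of evaluated samples.
#' @param alpha confidence level (one-sided tail mass).
#' @return object of class `braking_chance` with `threshold` (percent),
#'   `k` and the inputs.
#' @export
#' @examples
#' chance_level(2, 20, 0.05)$threshold   # 70
#' chance_level(2, 600, 0.05)$threshold  # 53.33
chance_level <- function(n_classes = 2, n_samples, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("invalid_alpha: alpha must lie strictly between 0 and 1")
  }
  if (n_samples < 1) stop("invalid_n: n_samples must be >= 1")
  k <- qbinom(1 - alpha, n_samples, 1 / n_classes)
  structure(list(threshold = 100 * k / n_samples, k = as.integer(k),
                 n_classes = n_classes, n_samples = as.integer(n_samples),
                 alpha = alpha),
            class = "braking_chance")
}

#' @export
print.braking_chance <- function(x, ...) {
  cat(sprintf(paste0("Significant chance level: %.2f%% ",
                     "(%d classes, n = %d, alpha = %g)\n"),
              x$threshold, x$n_classes, x$n_samples, x$alpha))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps a threshold over the unique scores (ties grouped), yielding one
#' operating point per distinct score plus the `(0, 0)` and `(1, 1)`
#' endpoints; the AUC is the trapezoidal area, which equals the rank-sum
#' (Mann-Whitney) probability that a positive scores above a negative with
#' ties counted half.
#'
#' @param scores numeric scores, larger = more braking-intention-like.
#' @param labels +1/-1 labels.
#' @return list of class `braking_roc` with `points` (data frame `fpr`,
#'   `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  if (all(pos) || all(!pos)) {
    stop("single_class: ROC needs both classes in the labels")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr,
                                     threshold = c(Inf, s[last])),
                 auc = auc),
            class = "braking_roc")
}

#' Precision-recall curve
#'
#' Same threshold sweep as [roc_auc()], reporting precision and recall.
#'
#' @inheritParams roc_auc
#' @return data frame with `recall`, `precision`, `threshold`.
#' @export
precision_recall <- function(scores, labels) {
  pos <- labels == 1
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); n_pred <- seq_along(p)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(recall = tp[last] / sum(pos),
             precision = tp[last] / n_pred[last],
             threshold = s[last])
}

#' Rank-based significance tests for accuracy distributions
#'
#' Wilcoxon signed-rank of one accuracy distribution against the constant
#' chance threshold; Wilcoxon rank-sum between two distributions when
#' `acc2` is given; Kruskal-Wallis across three or more groups when
#' `groups` is given. All two-sided.
#'
#' @param acc accuracy values (percent) over repetitions.
#' @param chance a [chance_level()] object or threshold in percent.
#' @param acc2 optional second distribution (rank-sum comparison).
#' @param groups optional named list of >= 3 distributions (omnibus test).
#' @return list of class `braking_tests` with the requested test results
#'   (`statistic`, `p`).
#' @export
significance_tests <- function(acc, chance = NULL, acc2 = NULL,
                               groups = NULL) {
  out <- list()
  if (length(acc) < 5) {
    out$warning <- "fewer than 5 repetitions: exact small-sample p-values"
  }
  if (!is.null(chance)) {
    thr <- if (inherits(chance, "braking_chance")) chance$threshold else
      chance
    if (all(acc == thr)) {
      out$signed_rank <- list(statistic = 0, p = 1, mu = thr)
    } else {
      w <- suppressWarnings(wilcox.test(acc, mu = thr))
      out$signed_rank <- list(statistic = unname(w$statistic),
                              p = w$p.value, mu = thr)
    }
  }
  if (!is.null(acc2)) {
    w <- suppressWarnings(wilcox.test(acc, acc2))
    out$rank_sum <- list(statistic = unname(w$statistic), p = w$p.value)
  }
  if (!is.null(groups)) {
    kw <- kruskal.test(groups)
    out$kruskal <- list(statistic = unname(kw$statistic), p = kw$p.value)
  }
  structure(out, class = "braking_tests")
}

# stratified train/eval split: indices for the training part
.stratified_split <- function(y, train_fraction) {
  idx_tr <- integer(0)
  for (cls in unique(y)) {
    members <- which(y == cls)
    n_tr <- max(1L, round(train_fraction * length(members)))
    if (n_tr >= length(members)) n_tr <- length(members) - 1L
    idx_tr <- c(idx_tr, sample(members, n_tr))
  }
  sort(idx_tr)
}

#' Repeated stratified holdout evaluation
#'
#' The evaluation protocol: `n_repetitions` independent random splits into
#' a 75% training and 25% evaluation part (stratified by class so both
#' classes appear in every evaluation set), training the classifier on the
#' training part and scoring the held-out part. Reports the accuracy
#' distribution, per-repetition confusion counts and AUC, plus an ROC and
#' precision-recall curve over the pooled evaluation scores.
#'
#' @param dataset a `braking_dataset`.
#' @param trainer a [trainer_cnn()] or [trainer_svm()] (or any
#'   `braking_trainer`).
#' @param n_repetitions number of random splits.
#' @param train_fraction training share of the data.
#' @param seed integer seed governing splits and training randomness.
#' @return object of class `braking_eval`: `accuracy` (percent, one value
#'   per repetition), `mean`, `sd`, `max`, `min`, `auc` (pooled), `roc`,
#'   `pr`, `auc_per_rep`, `confusion`, `n` (dataset size) and `classifier`.
#' @export
repeated_holdout <- function(dataset, trainer, n_repetitions = 100,
                             train_fraction = 0.75, seed = 1) {
  stopifnot(inherits(trainer, "braking_trainer"))
  x <- dataset$x; y <- dataset$y
  n <- nrow(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  acc <- numeric(n_repetitions)
  auc_rep <- numeric(n_repetitions)
  confusion <- vector("list", n_repetitions)
  pooled_scores <- list(); pooled_labels <- list()
  for (r in seq_len(n_repetitions)) {
    set.seed(derive_seed(seed, paste0("holdout/split/", r)))
    idx_tr <- .stratified_split(y, train_fraction)
    idx_ev <- setdiff(seq_len(n), idx_tr)
    model <- trainer$fit(list(x = x[idx_tr, , drop = FALSE], y = y[idx_tr]),
                         derive_seed(seed, paste0("holdout/train/", r)))
    pred <- predict(model, x[idx_ev, , drop = FALSE])
    scores <- attr(pred, "scores")
    truth <- y[idx_ev]
    tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == -1 & truth == -1)
    fp <- sum(pred == 1 & truth == -1); fn <- sum(pred == -1 & truth == 1)
    acc[r] <- accuracy_pct(tp, tn, fp, fn)
    confusion[[r]] <- c(tp = tp, tn = tn, fp = fp, fn = fn)
    auc_rep[r] <- roc_auc(scores, truth)$auc
    pooled_scores[[r]] <- scores; pooled_labels[[r]] <- truth
  }
  sc <- unlist(pooled_scores); lb <- unlist(pooled_labels)
  roc <- roc_auc(sc, lb)
  structure(list(accuracy = acc,
                 mean = mean(acc), sd = sd(acc),
                 max = max(acc), min = min(acc),
                 auc = roc$auc, roc = roc,
                 pr = precision_recall(sc, lb),
                 auc_per_rep = auc_rep,
                 confusion = confusion,
                 n = n,
                 n_repetitions = n_repetitions,
                 train_fraction = train_fraction,
                 classifier = trainer$name,
                 seed = as.integer(seed)),
            class = "braking_eval")
}

#' @export
print.braking_eval <- function(x, ...) {
  cat(sprintf(paste0("Repeated holdout (%s, %d reps, %d instances): ",
                     "accuracy %.1f +/- %.1f%% [%.1f, %.1f], AUC %.3f\n"),
              x$classifier, x$n_repetitions, x$n, x$mean, x$sd,
              x$min, x$max, x$auc))
  invisible(x)
}

#' @export
plot.braking_eval <- function(x, ...) {
  plot(x$roc$points$fpr, x$roc$points$tpr, type = "l",
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("ROC (%s), AUC = %.3f", x$classifier, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
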