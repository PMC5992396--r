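#' Study-level evaluation protocols
#'
#' Three designs mirroring the study analyses:
#' \describe{
#'   \item{per-participant}{[repeated_holdout()] separately on each
#'     participant's dataset;}
#'   \item{pooled}{repeated holdout on the concatenation of all
#'     participants;}
#'   \item{leave-one-participant-out}{for each participant, train on the
#'     concatenation of all the others (re-seeding the training randomness
#'     each repetition) and evaluate on the entire held-out participant --
#'     the cross-subject transfer test.}
#' }
#' The chance level reported with each protocol uses the smallest dataset
#' size across participants, the convention of the study.
#'
#' @param datasets named list of `braking_dataset`, one per participant.
#' @param trainer a `braking_trainer`.
#' @param n_repetitions repetitions per participant (or per pooled run).
#' @param train_fraction training share for the holdout protocols.
#' @param alpha confidence level for the chance threshold.
#' @param seed integer seed.
#' @return object of class `braking_protocol`: `table` (one row per
#'   participant: mean, sd, max, min accuracy and AUC, plus an `average`
#'   row), `results` (the underlying objects), `chance` and `protocol`.
#' @export
protocol_per_participant <- function(datasets, trainer,
                                     n_repetitions = 100,
                                     train_fraction = 0.75,
                                     alpha = 0.05, seed = 1) {
  .check_datasets(datasets)
  results <- lapply(seq_along(datasets), function(i)
    repeated_holdout(datasets[[i]], trainer, n_repetitions, train_fraction,
                     seed = derive_seed(seed, paste0("within/", i))))
  names(results) <- names(datasets)
  .protocol_result(results, datasets, alpha, "per_participant")
}

#' @rdname protocol_per_participant
#' @export
protocol_pooled <- function(datasets, trainer, n_repetitions = 100,
                            train_fraction = 0.75, alpha = 0.05, seed = 1) {
  .check_datasets(datasets)
  pooled <- merge_datasets(datasets)
  res <- repeated_holdout(pooled, trainer, n_repetitions, train_fraction,
                          seed = derive_seed(seed, "pooled"))
  out <- .protocol_result(list(pooled = res), datasets, alpha, "pooled")
  out$n_pooled <- nrow(pooled$x)
  out
}

#' @rdname protocol_per_participant
#' @export
protocol_leave_one_out <- function(datasets, trainer, n_repetitions = 100,
                                   alpha = 0.05, seed = 1) {
  .check_datasets(datasets)
  if (length(datasets) < 2L) {
    stop("too_few_participants: leave-one-out needs >= 2 participants")
  }
  results <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    train_ds <- merge_datasets(datasets[-i])
    test_ds <- datasets[[i]]
    acc <- numeric(n_repetitions)
    auc_rep <- numeric(n_repetitions)
    pooled_scores <- list(); pooled_labels <- list()
    confusion <- vector("list", n_repetitions)
    for (r in seq_len(n_repetitions)) {
      model <- trainer$fit(train_ds,
                           derive_seed(seed, paste0("loo/", i, "/", r)))
      pred <- predict(model, test_ds$x)
      truth <- test_ds$y
      tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == -1 & truth == -1)
      fp <- sum(pred == 1 & truth == -1); fn <- sum(pred == -1 & truth == 1)
      acc[r] <- accuracy_pct(tp, tn, fp, fn)
      confusion[[r]] <- c(tp = tp, tn = tn, fp = fp, fn = fn)
      scores <- attr(pred, "scores")
      auc_rep[r] <- roc_auc(scores, truth)$auc
      pooled_scores[[r]] <- scores; pooled_labels[[r]] <- truth
    }
    sc <- unlist(pooled_scores); lb <- unlist(pooled_labels)
    roc <- roc_auc(sc, lb)
    results[[i]] <- structure(
      list(accuracy = acc, mean = mean(acc), sd = sd(acc),
           max = max(acc), min = min(acc),
           auc = roc$auc, roc = roc, pr = precision_recall(sc, lb),
           auc_per_rep = auc_rep, confusion = confusion,
           n = nrow(test_ds$x), n_repetitions = n_repetitions,
           train_fraction = NA_real_, classifier = trainer$name,
           seed = as.integer(seed)),
      class = "braking_eval")
  }
  names(results) <- names(datasets)
  .protocol_result(results, datasets, alpha, "leave_one_out")
}

.check_datasets <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  ok <- vapply(datasets, inherits, TRUE, "braking_dataset")
  if (!all(ok)) stop("datasets must be a list of braking_dataset objects")
  if (is.null(names(datasets))) {
    stop("datasets must be a *named* list (one name per participant)")
  }
}

.protocol_result <- function(results, datasets, alpha, protocol) {
  n_min <- min(vapply(datasets, function(d) nrow(d$x), 0))
  chance <- chance_level(2, n_min, alpha)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    st <- significance_tests(r$accuracy, chance)
    data.frame(participant = nm, mean = r$mean, sd = r$sd,
               max = r$max, min = r$min, auc = r$auc,
               p_vs_chance = st$signed_rank$p,
               above_chance = r$mean > chance$threshold &
                 !is.na(st$signed_rank$p) & st$signed_rank$p < alpha,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  if (nrow(table) > 1) {
    avg <- data.frame(participant = "average",
                      mean = mean(table$mean), sd = mean(table$sd),
                      max = max(table$max), min = min(table$min),
                      auc = mean(table$auc), p_vs_chance = NA_real_,
                      above_chance = NA)
    table <- rbind(table, avg)
  }
  structure(list(table = table, results = results, chance = chance,
                 protocol = protocol),
            class = "braking_protocol")
}

#' @export
print.braking_protocol <- function(x, ...) {
  cat(sprintf("Protocol: %s (chance level %.2f%%)\n", x$protocol,
              x$chance$threshold))
  df <- x$table
  df$mean <- sprintf("%.1f", df$mean); df$sd <- sprintf("%.1f", df$sd)
  df$max <- sprintf("%.1f", df$max); df$min <- sprintf("%.1f", df$min)
  df$auc <- sprintf("%.3f", df$auc)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a protocol table as TSV
#' @param protocol a `braking_protocol`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_protocol <- function(protocol, path) {
  data.table::fwrite(protocol$table, path, sep = "\t")
  invisible(path)
}
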