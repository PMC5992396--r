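#' Configuration for a full synthetic study run
#'
#' Bundles every knob of the pipeline -- cohort size, design, reaction-time
#' and signal models, preprocessing thresholds, classifier configurations
#' and evaluation settings -- into one validated, serialisable object.
#'
#' @param seed master seed for the entire run.
#' @param n_participants cohort size.
#' @param design_args list of overrides passed to [make_design()].
#' @param brt a [brt_model()].
#' @param signal a [signal_model()].
#' @param emg_ratio,eeg_amplitude segment-rejection thresholds.
#' @param classifiers which classifiers to run (`"svm"`, `"cnn"`).
#' @param cnn,svm classifier configurations.
#' @param protocols which study protocols to run (`"within"`, `"pooled"`,
#'   `"loo"`).
#' @param n_repetitions evaluation repetitions.
#' @param train_fraction training share of each split.
#' @param alpha confidence level for the chance threshold.
#' @return object of class `braking_study_config`.
#' @export
study_config <- function(seed = 1, n_participants = 7,
                         design_args = list(),
                         brt = brt_model(), signal = signal_model(),
                         emg_ratio = 1.2, eeg_amplitude = 100,
                         classifiers = c("svm", "cnn"),
                         cnn = cnn_config(), svm = svm_config(),
                         protocols = c("within", "pooled", "loo"),
                         n_repetitions = 100, train_fraction = 0.75,
                         alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("invalid_alpha: alpha must lie strictly between 0 and 1")
  }
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("invalid_train_fraction: must lie strictly between 0 and 1")
  }
  stopifnot(n_participants >= 1, n_repetitions >= 1)
  classifiers <- match.arg(classifiers, c("svm", "cnn"), several.ok = TRUE)
  protocols <- match.arg(protocols, c("within", "pooled", "loo"),
                         several.ok = TRUE)
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 design_args = design_args, brt = brt, signal = signal,
                 emg_ratio = emg_ratio, eeg_amplitude = eeg_amplitude,
                 classifiers = classifiers, cnn = cnn, svm = svm,
                 protocols = protocols,
                 n_repetitions = as.integer(n_repetitions),
                 train_fraction = train_fraction, alpha = alpha),
            class = "braking_study_config")
}

#' Run the full study on synthetic data
#'
#' Executes the pipeline end to end: simulate each participant's sessions,
#' preprocess (harmonize, filter, reference, detect, segment, reject),
#' epoch and build the labelled feature datasets, evaluate the requested
#' classifiers under the requested protocols, and run the behavioural
#' analyses (BRT summaries on the detected events and the LEG envelope
#' over the pooled EMG trials). Identical configuration and seed give an
#' identical report.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, `report.json`, protocol
#'   tables, the BRT table and the LEG envelope are written there.
#' @param verbose print stage progress.
#' @return object of class `braking_study`: `datasets`, `events`,
#'   `protocols` (nested by classifier), `brt`, `leg`, `chance`, `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "braking_study_config"))
  say <- function(...) if (verbose) message(...)
  design <- do.call(make_design,
                    c(list(seed = derive_seed(config$seed, "design")),
                      config$design_args))

  datasets <- list()
  all_events <- list()
  emg_trials <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("p%02d", p)
    say("simulating + preprocessing participant ", pid)
    epochs_by_session <- list()
    for (s in seq_len(design$n_sessions)) {
      session <- simulate_session(design, config$brt, config$signal,
                                  pid, s, config$seed)
      pre <- preprocess_session(session, config$emg_ratio,
                                config$eeg_amplitude)
      epochs_by_session[[s]] <- extract_epochs(pre$recording, pre$segments)
      ev <- pre$events
      ev$participant <- pid; ev$session <- s
      all_events[[length(all_events) + 1L]] <- ev
      emg_trials[[length(emg_trials) + 1L]] <-
        extract_emg_trials(pre$recording, pre$events)
    }
    datasets[[pid]] <- build_dataset(epochs_by_session, participant = pid,
                                     session = seq_len(design$n_sessions))
  }
  events <- do.call(rbind, all_events)

  n_min <- min(vapply(datasets, function(d) nrow(d$x), 0))
  chance <- chance_level(2, n_min, config$alpha)

  trainers <- list()
  if ("svm" %in% config$classifiers) trainers$svm <- trainer_svm(config$svm)
  if ("cnn" %in% config$classifiers) trainers$cnn <- trainer_cnn(config$cnn)

  protocol_results <- list()
  for (clf in names(trainers)) {
    res <- list()
    if ("within" %in% config$protocols) {
      say("protocol per-participant (", clf, ")")
      res$within <- protocol_per_participant(
        datasets, trainers[[clf]], config$n_repetitions,
        config$train_fraction, config$alpha,
        seed = derive_seed(config$seed, paste0("eval/within/", clf)))
    }
    if ("pooled" %in% config$protocols) {
      say("protocol pooled (", clf, ")")
      res$pooled <- protocol_pooled(
        datasets, trainers[[clf]], config$n_repetitions,
        config$train_fraction, config$alpha,
        seed = derive_seed(config$seed, paste0("eval/pooled/", clf)))
    }
    if ("loo" %in% config$protocols && length(datasets) >= 2) {
      say("protocol leave-one-out (", clf, ")")
      res$loo <- protocol_leave_one_out(
        datasets, trainers[[clf]], config$n_repetitions, config$alpha,
        seed = derive_seed(config$seed, paste0("eval/loo/", clf)))
    }
    protocol_results[[clf]] <- res
  }

  say("behavioural analyses")
  brt <- brt_summary(events)
  trials <- do.call(rbind, emg_trials)
  attr(trials, "fs") <- attr(emg_trials[[1]], "fs")
  attr(trials, "t0") <- attr(emg_trials[[1]], "t0")
  leg <- leg_envelope(trials)

  study <- structure(list(datasets = datasets, events = events,
                          protocols = protocol_results,
                          brt = brt, leg = leg, chance = chance,
                          config = config),
                     class = "braking_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.braking_study <- function(x, ...) {
  cat("Synthetic braking-intention study\n")
  cat(sprintf("  %d participant(s); chance level %.2f%%\n",
              length(x$datasets), x$chance$threshold))
  cat(sprintf("  overall BRT %.0f +/- %.0f ms\n",
              x$brt$overall["mean"], x$brt$overall["sd"]))
  cat(sprintf("  LEG envelope: onset %.0f ms, peak %.0f ms\n",
              x$leg$onset_ms, x$leg$peak_ms))
  for (clf in names(x$protocols)) {
    for (pr in names(x$protocols[[clf]])) {
      tb <- x$protocols[[clf]][[pr]]$table
      cat(sprintf("  %s / %s: mean accuracy %.1f%%\n", clf, pr,
                  tb$mean[nrow(tb)]))
    }
  }
  invisible(x)
}

#' Write a study's outputs to a directory
#'
#' Writes `report.json` (all scalar metrics, p-values, the chance level and
#' the resolved seeds) plus TSV tables: one protocol table per classifier
#' and protocol, `brt_summary.tsv` and `leg_envelope.tsv`.
#'
#' @param study a [run_study()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the report path.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    seed = study$config$seed,
    n_participants = study$config$n_participants,
    chance = list(threshold_pct = study$chance$threshold,
                  n_samples = study$chance$n_samples,
                  alpha = study$chance$alpha),
    brt = list(overall = as.list(study$brt$overall),
               kruskal_p = study$brt$kruskal$p),
    leg = list(onset_ms = study$leg$onset_ms,
               peak_ms = study$leg$peak_ms,
               n_trials = study$leg$n_trials),
    protocols = lapply(study$protocols, function(res)
      lapply(res, function(pr) pr$table))
  )
  path <- file.path(out_dir, "report.json")
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, dataframe = "rows"), path)
  for (clf in names(study$protocols)) {
    for (pr in names(study$protocols[[clf]])) {
      write_protocol(study$protocols[[clf]][[pr]],
                     file.path(out_dir, sprintf("accuracy_%s_%s.tsv",
                                                clf, pr)))
    }
  }
  data.table::fwrite(study$brt$table, file.path(out_dir, "brt_summary.tsv"),
                     sep = "\t")
  data.table::fwrite(data.frame(time_s = study$leg$time,
                                envelope_uv = study$leg$envelope),
                     file.path(out_dir, "leg_envelope.tsv"), sep = "\t")
  invisible(path)
}
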