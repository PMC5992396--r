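#' Summarise braking reaction times by experimental combination
#'
#' Produces the condition-wise BRT table (mean, sd, min, max, median, n),
#' an omnibus Kruskal-Wallis test across all combinations, pairwise
#' Wilcoxon rank-sum comparisons of every factor-bearing combination
#' against the factor-free baseline `C_o`, and the percent change of each
#' combination's median relative to the baseline median.
#'
#' @param events event table (e.g. from [detect_events()], or truth tables)
#'   with columns `brt_ms` and `condition`; invalid events are dropped.
#' @param baseline the reference combination (default `"C_o"`).
#' @return object of class `braking_brt_summary`: `table` (per-condition
#'   summaries incl. `pct_change_median` and `p_vs_baseline`), `overall`
#'   (the across-all summary), `kruskal` and `dropped` (empty conditions).
#' @export
brt_summary <- function(events, baseline = "C_o") {
  if (!all(c("brt_ms", "condition") %in% names(events))) {
    stop("events must have columns brt_ms and condition")
  }
  if ("valid" %in% names(events)) events <- events[events$valid, ]
  events <- events[!is.na(events$brt_ms) & !is.na(events$condition), ]
  if (!nrow(events)) stop("empty_events: no valid events to summarise")

  conds <- unique(events$condition)
  conds <- c(intersect(CONDITIONS, conds), setdiff(conds, CONDITIONS))
  dropped <- character(0)
  summarise <- function(x) {
    c(n = length(x), mean = mean(x), sd = sd(x),
      max = max(x), min = min(x), median = median(x))
  }
  base_x <- events$brt_ms[events$condition == baseline]
  rows <- lapply(conds, function(cc) {
    x <- events$brt_ms[events$condition == cc]
    s <- summarise(x)
    pct <- if (length(base_x) && cc != baseline) {
      100 * (median(x) / median(base_x) - 1)
    } else if (cc == baseline) 0 else NA_real_
    p <- if (length(base_x) && cc != baseline && length(x)) {
      suppressWarnings(wilcox.test(x, base_x)$p.value)
    } else NA_real_
    data.frame(condition = cc, n = s["n"], mean = s["mean"], sd = s["sd"],
               max = s["max"], min = s["min"], median = s["median"],
               pct_change_median = pct, p_vs_baseline = p,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  groups <- split(events$brt_ms, events$condition)
  groups <- groups[vapply(groups, length, 0L) > 0]
  kruskal <- if (length(groups) >= 2) {
    kw <- kruskal.test(groups)
    list(statistic = unname(kw$statistic), p = kw$p.value)
  } else NULL
  overall <- summarise(events$brt_ms)
  structure(list(table = table,
                 overall = overall,
                 kruskal = kruskal,
                 baseline = baseline,
                 dropped = dropped),
            class = "braking_brt_summary")
}

#' @export
print.braking_brt_summary <- function(x, ...) {
  cat(sprintf("BRT across all events: %.0f +/- %.0f ms (min %.0f, max %.0f, n = %d)\n",
              x$overall["mean"], x$overall["sd"], x$overall["min"],
              x$overall["max"], as.integer(x$overall["n"])))
  if (!is.null(x$kruskal)) {
    cat(sprintf("Kruskal-Wallis across combinations: p = %.3g\n",
                x$kruskal$p))
  }
  df <- x$table
  df$mean <- sprintf("%.0f", df$mean); df$sd <- sprintf("%.0f", df$sd)
  df$median <- sprintf("%.0f", df$median)
  df$pct_change_median <- sprintf("%+.1f%%", df$pct_change_median)
  df$p_vs_baseline <- signif(df$p_vs_baseline, 3)
  print(df[, c("condition", "n", "mean", "sd", "min", "max", "median",
               "pct_change_median", "p_vs_baseline")], row.names = FALSE)
  invisible(x)
}

# Analytic signal via the frequency domain: zero the negative frequencies,
# double the positive ones, inverse-transform. Returns a complex vector
# whose modulus is the instantaneous envelope.
analytic_signal <- function(x) {
  n <- length(x)
  spec <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(spec * h, inverse = TRUE) / n
}

#' Extract stimulus-locked EMG trials from a recording
#'
#' @param recording a (filtered) `braking_recording`.
#' @param events a [detect_events()] table; invalid events are skipped.
#' @param pre_s,post_s window before/after each stimulus, seconds.
#' @return matrix (trials x samples) with attributes `fs` and `t0`
#'   (time of the first column relative to the stimulus, seconds).
#' @export
extract_emg_trials <- function(recording, events, pre_s = 0.5, post_s = 2) {
  stopifnot(inherits(recording, "braking_recording"))
  fs <- recording$fs
  n_pre <- round(pre_s * fs); n_post <- round(post_s * fs)
  T <- length(recording$emg)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    if (!events$valid[i]) next
    s0 <- round(events$stimulus_time_s[i] * fs) + 1L
    if (s0 - n_pre < 1L || s0 + n_post - 1L > T) next
    rows[[length(rows) + 1L]] <- recording$emg[(s0 - n_pre):(s0 + n_post - 1L)]
  }
  out <- do.call(rbind, rows)
  attr(out, "fs") <- fs
  attr(out, "t0") <- -pre_s
  out
}

#' Leg-movement envelope from stimulus-locked EMG trials
#'
#' The muscle-based leg-movement (LEG) signal: each trial is high-pass
#' filtered at 10 Hz (2nd-order Chebyshev Type I, zero-phase), rectified,
#' and the magnitude of its analytic (Hilbert) signal taken; the envelope
#' is then averaged across trials. The onset latency is the first time
#' after the stimulus at which the average envelope exceeds its
#' pre-stimulus baseline mean by 10%; the peak latency is the envelope
#' maximum. The first and last `edge_s` of the window are excluded from
#' both searches (analytic-signal edge artifacts).
#'
#' @param trials trials-by-samples matrix from [extract_emg_trials()] (or
#'   any matrix with attributes `fs` and `t0`).
#' @param fs,t0 sampling rate and time of the first column relative to the
#'   stimulus; taken from the attributes when missing.
#' @param baseline_s window (relative to the stimulus, seconds) over which
#'   the baseline level is measured.
#' @param onset_rise relative rise over baseline defining the onset
#'   (default 0.10).
#' @param edge_s edge exclusion, seconds.
#' @param smooth_s moving-average smoothing of the across-trial envelope
#'   before latency extraction, seconds (0 disables).
#' @param sustain_s the onset crossing must stay above threshold for at
#'   least this long, so brief noise excursions do not qualify.
#' @return object of class `braking_leg`: `time` (s, relative to
#'   stimulus), `envelope` (uV), `baseline`, `onset_ms`, `peak_ms` and the
#'   number of trials.
#' @export
leg_envelope <- function(trials, fs = attr(trials, "fs"),
                         t0 = attr(trials, "t0"),
                         baseline_s = c(-0.2, 0.1), onset_rise = 0.10,
                         edge_s = 0.1, smooth_s = 0.05, sustain_s = 0.1) {
  stopifnot(is.matrix(trials), !is.null(fs), !is.null(t0))
  if (nrow(trials) < 5) {
    warning("fewer than 5 EMG trials: envelope estimate will be noisy")
  }
  env <- matrix(0, nrow(trials), ncol(trials))
  for (i in seq_len(nrow(trials))) {
    x <- cheby_filtfilt(trials[i, ], fs, 10, "high")
    env[i, ] <- Mod(analytic_signal(abs(x)))
  }
  avg <- colMeans(env)
  if (smooth_s > 0) {
    k <- max(1L, round(smooth_s * fs))
    avg <- as.numeric(stats::filter(avg, rep(1 / k, k), sides = 2))
    # moving average is undefined at the very edges; hold the first/last
    # defined values there (the edges are excluded from searches anyway)
    first <- which(!is.na(avg))[1]; last <- tail(which(!is.na(avg)), 1)
    avg[seq_len(first - 1)] <- avg[first]
    if (last < length(avg)) avg[(last + 1):length(avg)] <- avg[last]
  }
  time <- t0 + (seq_along(avg) - 1) / fs

  searchable <- time >= (time[1] + edge_s) &
    time <= (time[length(time)] - edge_s)
  base_idx <- searchable & time >= baseline_s[1] & time <= baseline_s[2]
  baseline <- mean(avg[base_idx])
  above <- searchable & time > baseline_s[2] &
    avg > (1 + onset_rise) * baseline
  n_sustain <- max(1L, round(sustain_s * fs))
  onset_ms <- NA_real_
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= n_sustain)
  if (length(ok)) onset_ms <- 1000 * time[starts[ok[1]]]
  peak_region <- which(searchable & time > 0)
  peak_ms <- 1000 * time[peak_region[which.max(avg[peak_region])]]
  structure(list(time = time, envelope = avg, baseline = baseline,
                 onset_ms = onset_ms, peak_ms = peak_ms,
                 n_trials = nrow(trials)),
            class = "braking_leg")
}

#' @export
print.braking_leg <- function(x, ...) {
  cat(sprintf(paste0("LEG envelope over %d trials: onset %.0f ms, ",
                     "peak %.0f ms post-stimulus\n"),
              x$n_trials, x$onset_ms, x$peak_ms))
  invisible(x)
}

#' @export
plot.braking_leg <- function(x, ...) {
  plot(x$time * 1000, x$envelope, type = "l", xlab = "time (ms)",
       ylab = "envelope (uV)", main = "Leg-movement (LEG) envelope", ...)
  graphics::abline(v = c(x$onset_ms, x$peak_ms), lty = c(3, 2))
  graphics::abline(h = x$baseline, lty = 3, col = "grey50")
  invisible(x)
}
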