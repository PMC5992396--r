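#' Harmonize all channels to a common 250 Hz time base
#'
#' Vehicular channels (50 Hz) are upsampled -- LIGHT by zero-order hold so it
#' stays binary, BRAKE by linear interpolation followed by re-quantization to
#' the 0.01 pedal grid -- while the bio-signals (500 Hz) are decimated by 2
#' with an anti-aliasing FIR lowpass ([signal::decimate], whose flat
#' passband preserves in-band amplitudes to within 0.1%). The result is an
#' unfiltered continuous recording in which every channel shares one 250 Hz
#' clock.
#'
#' @param session a `braking_session`.
#' @return an object of class `braking_recording` with elements `eeg`
#'   (7 x T matrix), `emg`, `light`, `brake`, `fs = 250`, and the session's
#'   truth/metadata carried along.
#' @export
harmonize_rates <- function(session) {
  stopifnot(inherits(session, "braking_session"))
  if (session$fs_bio != 500 || session$fs_veh != 50) {
    stop("expected 500 Hz bio-signals and 50 Hz vehicular signals")
  }
  T50 <- length(session$light)
  if (length(session$brake) != T50) {
    stop("mismatched_duration: LIGHT and BRAKE differ in length")
  }
  if (ncol(session$eeg) != 10L * T50 || length(session$emg) != 10L * T50) {
    stop("mismatched_duration: bio and vehicular channels disagree")
  }
  fs <- 250
  T250 <- ncol(session$eeg) %/% 2L
  t250 <- (seq_len(T250) - 1) / fs
  t50 <- (seq_len(T50) - 1) / 50

  # zero-order hold: index of the latest 50 Hz sample at or before each tick
  idx <- findInterval(t250 + 1e-9, t50)
  light <- session$light[idx]
  brake <- approx(t50, session$brake, xout = t250, rule = 2)$y
  brake <- round(brake * 100) / 100

  eeg <- t(apply(session$eeg, 1, fir_decimate, q = 2))
  rownames(eeg) <- rownames(session$eeg)
  emg <- fir_decimate(session$emg, q = 2)

  structure(list(eeg = eeg[, seq_len(T250), drop = FALSE],
                 emg = emg[seq_len(T250)],
                 light = light, brake = brake,
                 fs = fs,
                 truth = session$truth,
                 block_intervals = session$block_intervals,
                 participant_id = session$participant_id,
                 session_id = session$session_id,
                 filtered = c(eeg = FALSE, emg = FALSE, car = FALSE)),
            class = "braking_recording")
}

#' @export
print.braking_recording <- function(x, ...) {
  cat(sprintf(paste0("Continuous recording at %d Hz: %.1f min, ",
                     "%d EEG channel(s)%s\n"),
              x$fs, ncol(x$eeg) / x$fs / 60, nrow(x$eeg),
              if (x$filtered[["car"]]) ", filtered + CAR" else
                if (x$filtered[["eeg"]]) ", filtered" else " (raw)"))
  invisible(x)
}

# Anti-aliased decimation by an integer factor: order-30 linear-phase FIR
# lowpass at the new Nyquist, applied with its group delay compensated so
# decimated samples stay aligned with the undecimated time base (the
# vehicular channels are never decimated, so any uncompensated delay would
# shift the bio-signals against the event markers).
fir_decimate <- function(x, q = 2, order = 30) {
  b <- signal::fir1(order, 1 / q)
  delay <- order / 2
  y <- signal::fftfilt(b, c(x, numeric(delay)))
  y <- y[(delay + 1):(delay + length(x))]
  y[seq(1, length(x), by = q)]
}

# Zero-phase (forward-backward) Chebyshev Type I filter. `type` and band
# edges in Hz; ripple in dB. Forward-backward application doubles the
# effective order and cancels the group delay.
cheby_filtfilt <- function(x, fs, w, type, order = 2, ripple = 0.5) {
  nyq <- fs / 2
  if (any(w >= nyq)) {
    stop("invalid_cutoff: cutoff ", paste(w, collapse = "-"),
         " Hz is at or above the Nyquist frequency (", nyq, " Hz)")
  }
  flt <- signal::cheby1(order, ripple, w / nyq, type = type)
  signal::filtfilt(flt, x)
}

#' Lowpass-filter the EEG channels
#'
#' 2nd-order Chebyshev Type I lowpass at 45 Hz (0.5 dB passband ripple),
#' applied forward-backward for zero phase shift.
#'
#' @param recording a `braking_recording`.
#' @param cutoff cutoff frequency, Hz.
#' @param ripple passband ripple, dB.
#' @return the recording with filtered EEG.
#' @export
filter_eeg <- function(recording, cutoff = 45, ripple = 0.5) {
  stopifnot(inherits(recording, "braking_recording"))
  recording$eeg <- t(apply(recording$eeg, 1, cheby_filtfilt,
                           fs = recording$fs, w = cutoff, type = "low",
                           ripple = ripple))
  rownames(recording$eeg) <- EEG_CHANNELS[seq_len(nrow(recording$eeg))]
  recording$filtered[["eeg"]] <- TRUE
  recording
}

#' Band-filter the EMG channel
#'
#' 2nd-order Chebyshev Type I bandpass (1--90 Hz by default) plus a band-stop
#' notch around the mains frequency (58--62 Hz), both applied
#' forward-backward.
#'
#' @param recording a `braking_recording`.
#' @param band passband edges, Hz.
#' @param notch stopband edges, Hz.
#' @param ripple passband ripple, dB.
#' @return the recording with filtered EMG.
#' @export
filter_emg <- function(recording, band = c(1, 90), notch = c(58, 62),
                       ripple = 0.5) {
  stopifnot(inherits(recording, "braking_recording"))
  x <- cheby_filtfilt(recording$emg, recording$fs, band, "pass",
                      ripple = ripple)
  recording$emg <- cheby_filtfilt(x, recording$fs, notch, "stop",
                                  ripple = ripple)
  recording$filtered[["emg"]] <- TRUE
  recording
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across all EEG channels from each
#' channel, so the per-sample channel mean is exactly zero afterwards.
#'
#' @param recording a `braking_recording`.
#' @return the re-referenced recording.
#' @export
apply_car <- function(recording) {
  stopifnot(inherits(recording, "braking_recording"))
  if (nrow(recording$eeg) < 2L) {
    stop("too_few_channels: common average reference needs >= 2 channels")
  }
  recording$eeg <- sweep(recording$eeg, 2, colMeans(recording$eeg), "-")
  recording$filtered[["car"]] <- TRUE
  recording
}

#' Detect stimulus and response events from the vehicular channels
#'
#' A stimulus is each 0 -> 1 transition of LIGHT (threshold 0.5); the
#' matching response is the first later sample with `BRAKE >= 0.01`. Events
#' with no response within `max_brt_s` are flagged invalid with reason
#' `"no post-stimulus activation of the brake pedal"`. When the recording
#' carries block intervals, each event is labelled with the experimental
#' combination of the block containing its stimulus.
#'
#' @param recording a `braking_recording`.
#' @param max_brt_s response search window after the stimulus, seconds.
#' @return a data frame (class `braking_events`) with one row per stimulus:
#'   `event`, `stimulus_time_s`, `response_time_s`, `brt_ms`, `condition`,
#'   `block`, `valid`, `reason`.
#' @export
detect_events <- function(recording, max_brt_s = 2) {
  stopifnot(inherits(recording, "braking_recording"))
  fs <- recording$fs
  lit <- recording$light > 0.5
  rises <- which(diff(lit) == 1L) + 1L
  n <- length(rises)
  out <- data.frame(event = seq_len(n),
                    stimulus_time_s = (rises - 1) / fs,
                    response_time_s = NA_real_,
                    brt_ms = NA_real_,
                    condition = NA_character_,
                    block = NA_integer_,
                    valid = TRUE,
                    reason = "",
                    stringsAsFactors = FALSE)
  thr <- 0.01 - 1e-9
  for (i in seq_len(n)) {
    lo <- rises[i] + 1L
    hi <- min(length(recording$brake), rises[i] + round(max_brt_s * fs))
    win <- recording$brake[lo:hi]
    hit <- which(win >= thr)
    if (length(hit)) {
      ridx <- lo + hit[1] - 1L
      out$response_time_s[i] <- (ridx - 1) / fs
      out$brt_ms[i] <- (out$response_time_s[i] - out$stimulus_time_s[i]) * 1000
    } else {
      out$valid[i] <- FALSE
      out$reason[i] <- "no post-stimulus activation of the brake pedal"
    }
  }
  bi <- recording$block_intervals
  if (!is.null(bi)) {
    for (i in seq_len(n)) {
      j <- which(out$stimulus_time_s[i] >= bi$start_s - 1e-6 &
                 out$stimulus_time_s[i] <= bi$end_s + 1e-6)
      if (length(j) == 1L) {
        out$condition[i] <- bi$condition[j]
        out$block[i] <- bi$block[j]
      }
    }
  }
  class(out) <- c("braking_events", "data.frame")
  out
}

#' Cut the recording into 2 s post-stimulus data segments
#'
#' One segment per valid event, spanning `[stimulus, stimulus + 2 s)` (500
#' samples at 250 Hz, half-open so the boundary sample is not counted twice),
#' plus `pre_s` seconds of pre-stimulus context used by the rejection rules
#' and the behavioural analyses. Events whose segment would run past either
#' end of the recording are flagged invalid (`"segment exceeds recording
#' bounds"`) rather than raising an error.
#'
#' @param recording a `braking_recording`.
#' @param events a [detect_events()] table (modified validity is returned as
#'   an attribute `events` on the result).
#' @param length_s segment length, seconds.
#' @param pre_s pre-stimulus context, seconds.
#' @return list of segments (class `braking_segments`); each segment has
#'   `eeg` (7 x 500), `emg`, `light`, `brake`, `eeg_pre`, `emg_pre`,
#'   `t0` (stimulus time) and `event` (row index into `events`).
#' @export
segment_recording <- function(recording, events, length_s = 2, pre_s = 0.5) {
  stopifnot(inherits(recording, "braking_recording"))
  fs <- recording$fs
  n_len <- round(length_s * fs)
  n_pre <- round(pre_s * fs)
  T <- ncol(recording$eeg)
  segments <- list()
  for (i in seq_len(nrow(events))) {
    if (!events$valid[i]) next
    s0 <- round(events$stimulus_time_s[i] * fs) + 1L
    if (s0 - n_pre < 1L || s0 + n_len - 1L > T) {
      events$valid[i] <- FALSE
      events$reason[i] <- "segment exceeds recording bounds"
      next
    }
    keep <- s0:(s0 + n_len - 1L)
    pre <- (s0 - n_pre):(s0 - 1L)
    segments[[length(segments) + 1L]] <-
      list(eeg = recording$eeg[, keep, drop = FALSE],
           emg = recording$emg[keep],
           light = recording$light[keep],
           brake = recording$brake[keep],
           eeg_pre = recording$eeg[, pre, drop = FALSE],
           emg_pre = recording$emg[pre],
           t0 = events$stimulus_time_s[i],
           fs = fs,
           event = i)
  }
  structure(segments, class = "braking_segments", events = events)
}

#' Automated segment rejection
#'
#' Replaces the study's visual inspection with three documented proxy rules:
#' \describe{
#'   \item{vehicular}{no `BRAKE >= 0.01` response inside the segment;}
#'   \item{EMG}{post-stimulus EMG RMS divided by the pre-stimulus baseline
#'     RMS below `emg_ratio` (no post-stimulus amplitude increase);}
#'   \item{EEG}{any sample exceeding `eeg_amplitude` uV in absolute value
#'     after filtering (gross artifact).}
#' }
#'
#' @param segments a [segment_recording()] list.
#' @param emg_ratio minimum post/pre RMS ratio (default 1.2).
#' @param eeg_amplitude amplitude ceiling in uV (default 100).
#' @return list with `kept` (a `braking_segments`), and `rejected`, a data
#'   frame of dropped segments with the triggering rule.
#' @export
reject_segments <- function(segments, emg_ratio = 1.2, eeg_amplitude = 100) {
  stopifnot(inherits(segments, "braking_segments"))
  events <- attr(segments, "events")
  kept <- list(); rejected <- data.frame(event = integer(),
                                         reason = character())
  rms <- function(x) sqrt(mean(x^2))
  for (seg in segments) {
    reason <- NULL
    if (!any(seg$brake >= 0.01 - 1e-9)) {
      reason <- "vehicular: no post-stimulus activation of the brake pedal"
    } else if (rms(seg$emg) / rms(seg$emg_pre) < emg_ratio) {
      reason <- "emg: no post-stimulus amplitude increase"
    } else if (max(abs(seg$eeg)) > eeg_amplitude) {
      reason <- "eeg: amplitude exceeds ceiling"
    }
    if (is.null(reason)) {
      kept[[length(kept) + 1L]] <- seg
    } else {
      rejected <- rbind(rejected,
                        data.frame(event = seg$event, reason = reason))
    }
  }
  structure(list(kept = structure(kept, class = "braking_segments",
                                  events = events),
                 rejected = rejected),
            class = "braking_rejection")
}

#' Run the full preprocessing chain on one session
#'
#' Convenience wrapper: [harmonize_rates()] -> [filter_eeg()] ->
#' [apply_car()] -> [filter_emg()] -> [detect_events()] ->
#' [segment_recording()] -> [reject_segments()].
#'
#' @param session a `braking_session`.
#' @param emg_ratio,eeg_amplitude rejection thresholds, see
#'   [reject_segments()].
#' @return list with `recording`, `events`, `segments` (kept) and `rejected`.
#' @export
preprocess_session <- function(session, emg_ratio = 1.2,
                               eeg_amplitude = 100) {
  rec <- harmonize_rates(session)
  rec <- filter_eeg(rec)
  rec <- apply_car(rec)
  rec <- filter_emg(rec)
  events <- detect_events(rec)
  segs <- segment_recording(rec, events)
  rej <- reject_segments(segs, emg_ratio, eeg_amplitude)
  list(recording = rec, events = attr(rej$kept, "events"),
       segments = rej$kept, rejected = rej$rejected)
}
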