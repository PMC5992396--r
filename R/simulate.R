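#' Simulate one driving session
#'
#' Generates the raw multi-rate recording of a single session: 7-channel EEG
#' and 1-channel leg EMG at 500 Hz, plus the vehicular LIGHT (binary
#' guide-vehicle brake-light state) and BRAKE (pedal deflection in `[0, 1]`,
#' 0.01 resolution) channels at 50 Hz, together with the ground-truth event
#' table.
#'
#' The session timeline follows the block schedule of `design`: after a quiet
#' lead-in, each block presents its events with stimuli separated by the 3 s
#' light-on interval plus a uniform draw from the design's inter-event range
#' (measured from light-off). Stimuli are snapped to the 50 Hz vehicular
#' grid. Each event's braking reaction time is drawn from `brt_model` for
#' the block's experimental combination; the pedal trace jumps to 0.01 at
#' the response and ramps linearly to full deflection over 300 ms, so the
#' first `BRAKE >= 0.01` sample is the first vehicular sample at or after
#' the true response. EEG channels carry `1/f` background noise plus the
#' planted pre-movement ramp (ending at each response) and the post-stimulus
#' visual component; the EMG channel carries baseline muscle noise plus one
#' burst per event.
#'
#' @param design a [make_design()] object.
#' @param brt_model a [brt_model()].
#' @param sig_model a [signal_model()].
#' @param participant_id,session_id identifiers; `session_id` indexes the
#'   design's schedule.
#' @param seed master seed; fans out to named per-stage sub-seeds via
#'   [derive_seed()], so the same (ids, seed) always yields bit-identical
#'   arrays.
#' @param duration_s optional fixed session length in seconds; it is an
#'   error (`insufficient_duration`) if shorter than the schedule needs.
#' @return an object of class `braking_session` with elements `eeg`
#'   (7 x T matrix, uV, 500 Hz, rownames = channel labels), `emg` (uV,
#'   500 Hz), `light`, `brake` (50 Hz), `truth` (event table with
#'   `stimulus_time_s`, `response_time_s`, `brt_ms`, `condition`, `block`,
#'   `valid`), `block_intervals`, sampling rates and metadata.
#' @export
#' @examples
#' d <- make_design(seed = 1, n_sessions = 1, blocks_per_session = 2,
#'                  events_per_block = 3)
#' s <- simulate_session(d, brt_model(), signal_model(), "p01", 1, seed = 1)
#' nrow(s$truth)  # 6 events
simulate_session <- function(design, brt_model, sig_model,
                             participant_id, session_id, seed,
                             duration_s = NULL) {
  stopifnot(inherits(design, "braking_design"),
            inherits(brt_model, "braking_brt_model"),
            inherits(sig_model, "braking_signal_model"))
  session_id <- as.integer(session_id)
  if (session_id < 1L || session_id > design$n_sessions) {
    stop("session_id must index the design's schedule")
  }
  fs_bio <- 500; fs_veh <- 50
  seed_s <- derive_seed(seed, paste0("participant/", participant_id,
                                     "/session/", session_id))
  subseed <- function(label) derive_seed(seed_s, label)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  conditions <- design$schedule[[session_id]]
  n_blocks <- design$blocks_per_session
  n_ev <- design$events_per_block

  # --- event schedule ------------------------------------------------------
  set.seed(subseed("schedule"))
  stim <- numeric(0); block_id <- integer(0)
  block_intervals <- data.frame(block = seq_len(n_blocks),
                                start_s = NA_real_, end_s = NA_real_,
                                condition = conditions,
                                stringsAsFactors = FALSE)
  cursor <- design$lead_in_s
  for (b in seq_len(n_blocks)) {
    block_intervals$start_s[b] <- cursor
    for (k in seq_len(n_ev)) {
      gap <- runif(1, design$iei_range[1], design$iei_range[2])
      t_k <- if (k == 1) cursor + gap else
        stim[length(stim)] + design$light_duration_s + gap
      t_k <- round(t_k * fs_veh) / fs_veh  # snap to the vehicular grid
      stim <- c(stim, t_k)
      block_id <- c(block_id, b)
    }
    cursor <- stim[length(stim)] + design$light_duration_s +
      design$block_gap_s
    block_intervals$end_s[b] <- stim[length(stim)] + design$light_duration_s
  }
  needed_s <- cursor + 5
  if (!is.null(duration_s)) {
    if (duration_s < needed_s) {
      stop("insufficient_duration: schedule needs ", round(needed_s, 1),
           " s but duration_s = ", duration_s)
    }
    needed_s <- duration_s
  }
  T50 <- ceiling(needed_s * fs_veh)
  T500 <- T50 * 10L
  t500 <- (seq_len(T500) - 1) / fs_bio

  # --- reaction times ------------------------------------------------------
  brt <- numeric(length(stim))
  for (b in seq_len(n_blocks)) {
    idx <- which(block_id == b)
    brt[idx] <- sample_brt(brt_model, conditions[b], length(idx),
                           seed = subseed(paste0("brt/block/", b)))
  }
  resp <- stim + brt / 1000
  truth <- data.frame(event = seq_along(stim),
                      block = block_id,
                      condition = conditions[block_id],
                      stimulus_time_s = stim,
                      response_time_s = resp,
                      brt_ms = brt,
                      valid = TRUE,
                      stringsAsFactors = FALSE)

  # --- vehicular channels --------------------------------------------------
  light <- numeric(T50); brake <- numeric(T50)
  t50 <- (seq_len(T50) - 1) / fs_veh
  ramp_s <- 0.3; hold_s <- 1; release_s <- 0.5
  for (i in seq_along(stim)) {
    on <- which(t50 >= stim[i] & t50 < stim[i] + design$light_duration_s)
    light[on] <- 1
    win <- which(t50 >= resp[i] & t50 < resp[i] + ramp_s + hold_s + release_s)
    dt <- t50[win] - resp[i]
    v <- ifelse(dt < ramp_s, 0.01 + 0.99 * dt / ramp_s,
                ifelse(dt < ramp_s + hold_s, 1,
                       1 - (dt - ramp_s - hold_s) / release_s))
    brake[win] <- pmax(brake[win], pmin(1, pmax(0, v)))
  }
  brake <- round(brake * 100) / 100

  # --- EEG -----------------------------------------------------------------
  eeg <- matrix(0, nrow = length(EEG_CHANNELS), ncol = T500,
                dimnames = list(EEG_CHANNELS, NULL))
  for (ch in seq_along(EEG_CHANNELS)) {
    set.seed(subseed(paste0("eeg/noise/", EEG_CHANNELS[ch])))
    eeg[ch, ] <- pink_noise(T500, fs_bio, sig_model$eeg_noise$exponent,
                            sig_model$eeg_noise$rms)
  }
  pm <- sig_model$pre_movement
  ev <- sig_model$erp_visual
  if (pm$amplitude != 0 || ev$amplitude != 0) {
    comp <- numeric(T500)  # shared time course, scaled per channel below
    pm_course <- numeric(T500); ev_course <- numeric(T500)
    for (i in seq_along(stim)) {
      # readiness ramp: 0 -> amplitude over duration, back over release
      i0 <- floor((resp[i] - pm$duration_ms / 1000) * fs_bio) + 1
      i1 <- floor(resp[i] * fs_bio) + 1
      i2 <- min(floor((resp[i] + pm$release_ms / 1000) * fs_bio) + 1, T500)
      if (i0 >= 1 && i1 <= T500) {
        ramp <- seq(0, 1, length.out = i1 - i0 + 1)
        pm_course[i0:i1] <- pm_course[i0:i1] + ramp
        if (i2 > i1) {
          rel <- seq(1, 0, length.out = i2 - i1 + 1)[-1]
          pm_course[(i1 + 1):i2] <- pm_course[(i1 + 1):i2] + rel
        }
      }
      # visual evoked component
      mu <- stim[i] + ev$latency_ms / 1000
      j0 <- max(1, floor((mu - 4 * ev$sd_ms / 1000) * fs_bio))
      j1 <- min(T500, ceiling((mu + 4 * ev$sd_ms / 1000) * fs_bio))
      tt <- t500[j0:j1]
      ev_course[j0:j1] <- ev_course[j0:j1] +
        exp(-(tt - mu)^2 / (2 * (ev$sd_ms / 1000)^2))
    }
    for (ch in seq_along(EEG_CHANNELS)) {
      lab <- EEG_CHANNELS[ch]
      eeg[ch, ] <- eeg[ch, ] +
        pm$amplitude * pm$weights[[lab]] * pm_course +
        ev$amplitude * ev$weights[[lab]] * ev_course
    }
  }
  ln <- sig_model$line_noise
  if (ln$amplitude != 0) {
    mains <- ln$amplitude * sin(2 * pi * ln$freq * t500)
    eeg <- sweep(eeg, 2, mains, "+")
  }

  # --- EMG -----------------------------------------------------------------
  eb <- sig_model$emg_burst
  set.seed(subseed("emg/baseline"))
  emg <- band_noise(T500, fs_bio, eb$band, eb$noise_rms)
  if (eb$amplitude != 0) {
    env <- numeric(T500)
    ref_ms <- if (is.null(eb$response_ref_ms)) 700 else eb$response_ref_ms
    for (i in seq_along(stim)) {
      anchor <- if (identical(eb$lock, "response"))
        resp[i] - ref_ms / 1000 else stim[i]
      on <- anchor + eb$onset_ms / 1000
      pk <- anchor + eb$peak_ms / 1000
      en <- pk + eb$fall_ms / 1000
      k0 <- max(1, floor(on * fs_bio) + 1)
      k1 <- min(T500, floor(en * fs_bio) + 1)
      if (k1 <= k0) next
      tt <- t500[k0:k1]
      e <- ifelse(tt <= pk,
                  0.5 * (1 - cos(pi * (tt - on) / (pk - on))),
                  0.5 * (1 + cos(pi * (tt - pk) / (en - pk))))
      env[k0:k1] <- pmax(env[k0:k1], e)
    }
    set.seed(subseed("emg/carrier"))
    carrier <- band_noise(T500, fs_bio, eb$band, 1)
    emg <- emg + eb$amplitude * carrier * env
  }
  if (ln$amplitude != 0) emg <- emg + ln$amplitude *
      sin(2 * pi * ln$freq * t500)

  # --- artifact injector ---------------------------------------------------
  art <- sig_model$artifact
  if (art$rate > 0) {
    set.seed(subseed("artifacts"))
    n_art <- round(art$rate)
    for (a in seq_len(n_art)) {
      at <- runif(1, design$lead_in_s, needed_s - 1)
      ch <- sample.int(length(EEG_CHANNELS), 1)
      k0 <- floor(at * fs_bio) + 1
      k1 <- min(T500, k0 + round(art$duration_ms / 1000 * fs_bio))
      eeg[ch, k0:k1] <- eeg[ch, k0:k1] + art$amplitude
    }
  }

  structure(list(eeg = eeg, emg = emg, light = light, brake = brake,
                 fs_bio = fs_bio, fs_veh = fs_veh,
                 truth = truth, block_intervals = block_intervals,
                 participant_id = as.character(participant_id),
                 session_id = session_id,
                 seed = as.integer(seed),
                 signal_model = sig_model),
            class = "braking_session")
}

#' @export
print.braking_session <- function(x, ...) {
  cat(sprintf(paste0("Synthetic driving session: participant %s, session %d\n",
                     "  %d events, %.1f min, EEG/EMG at %d Hz, ",
                     "vehicular at %d Hz\n"),
              x$participant_id, x$session_id, nrow(x$truth),
              ncol(x$eeg) / x$fs_bio / 60, x$fs_bio, x$fs_veh))
  invisible(x)
}

#' Simulate all sessions of one participant
#'
#' @inheritParams simulate_session
#' @param sessions which sessions to simulate (default: all in the design).
#' @return list of [simulate_session()] objects.
#' @export
simulate_participant <- function(design, brt_model, sig_model,
                                 participant_id, seed,
                                 sessions = seq_len(design$n_sessions)) {
  lapply(sessions, function(s)
    simulate_session(design, brt_model, sig_model, participant_id, s, seed))
}
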