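# Builds a minimal raw session-like object from supplied channels so the
# resampling path can be tested on analytically known signals.
raw_session <- function(T50, eeg_fun = function(t) 0 * t,
                        light = NULL, brake = NULL) {
  t500 <- (seq_len(T50 * 10) - 1) / 500
  eeg <- t(vapply(1:7, function(i) eeg_fun(t500), numeric(length(t500))))
  rownames(eeg) <- c("F3", "F4", "C3", "C4", "Cz", "P3", "P4")
  structure(list(eeg = eeg, emg = eeg_fun(t500),
                 light = if (is.null(light)) numeric(T50) else light,
                 brake = if (is.null(brake)) numeric(T50) else brake,
                 fs_bio = 500, fs_veh = 50,
                 truth = NULL, block_intervals = NULL,
                 participant_id = "toy", session_id = 1L, seed = 0L,
                 signal_model = NULL),
            class = "braking_session")
}

test_that("rate harmonization brings all channels to one 250 Hz clock", {
  s <- raw_session(50, light = rep(1, 50))
  rec <- harmonize_rates(s)
  expect_equal(rec$fs, 250)
  expect_equal(length(rec$light), ncol(rec$eeg))
  expect_equal(length(rec$brake), ncol(rec$eeg))
  expect_equal(length(rec$emg), ncol(rec$eeg))
  expect_true(all(rec$light == 1))  # constant LIGHT stays constant
})

test_that("a sinusoid survives decimation with its amplitude intact", {
  s <- raw_session(100, eeg_fun = function(t) sin(2 * pi * 5 * t))
  rec <- harmonize_rates(s)
  mid <- 100:400  # avoid filter edge transients
  expect_lt(abs(max(rec$eeg[1, mid]) - 1), 0.01)
  # frequency preserved: count zero crossings
  zc <- sum(diff(sign(rec$eeg[1, mid])) != 0)
  expect_lte(abs(zc - 2 * 5 * length(mid) / 250), 2)
})

test_that("one LIGHT step yields exactly one rising edge after resampling", {
  light <- c(rep(0, 20), rep(1, 30))
  s <- raw_session(50, light = light)
  rec <- harmonize_rates(s)
  expect_true(all(rec$light %in% c(0, 1)))
  expect_equal(sum(diff(rec$light > 0.5) == 1), 1)
})

test_that("BRAKE is re-quantized to the 0.01 grid after interpolation", {
  brake <- round(seq(0, 1, length.out = 50), 2)
  s <- raw_session(50, brake = brake)
  rec <- harmonize_rates(s)
  expect_true(all(abs(rec$brake * 100 - round(rec$brake * 100)) < 1e-9))
})

test_that("mismatched channel durations are rejected", {
  s <- raw_session(50)
  s$brake <- s$brake[-1]
  expect_error(harmonize_rates(s), "mismatched_duration")
})

test_that("EEG lowpass passes 10 Hz within ripple and kills 80 Hz", {
  t <- (0:4999) / 250
  mk <- function(f) toy_recording(t(vapply(1:7, function(i)
    sin(2 * pi * f * t), numeric(length(t)))))
  mid <- 1000:4000
  low <- filter_eeg(mk(10))
  expect_lt(abs(max(low$eeg[1, mid]) - 1), 0.12)   # within ripple bound
  high <- filter_eeg(mk(80))
  atten <- 20 * log10(max(abs(high$eeg[1, mid])))
  expect_lt(atten, -12)
})

test_that("the zero-phase filter has a symmetric impulse response", {
  x <- matrix(0, 7, 1001); x[, 501] <- 1
  rec <- filter_eeg(toy_recording(x))
  h <- rec$eeg[1, ]
  expect_lt(max(abs(h - rev(h))), 1e-8)
})

test_that("filtering is idempotent in the passband within ripple", {
  t <- (0:2999) / 250
  x <- t(vapply(1:7, function(i) sin(2 * pi * 10 * t), numeric(length(t))))
  once <- filter_eeg(toy_recording(x))
  twice <- filter_eeg(once)
  mid <- 500:2500
  expect_lt(max(abs(twice$eeg[1, mid] - once$eeg[1, mid])), 0.12)
})

test_that("cutoffs at or above Nyquist are rejected", {
  x <- matrix(rnorm(7 * 100), 7, 100)
  expect_error(filter_eeg(toy_recording(x), cutoff = 125), "invalid_cutoff")
  expect_error(filter_emg(toy_recording(x,
                                        emg = rnorm(100)), band = c(1, 130)),
               "invalid_cutoff")
})

test_that("EMG filter notches 60 Hz, blocks drift, passes 30 Hz", {
  t <- (0:4999) / 250
  mk <- function(f) toy_recording(matrix(0, 7, length(t)),
                                  emg = sin(2 * pi * f * t))
  mid <- 1000:4000
  mains <- filter_emg(mk(60))
  expect_lt(20 * log10(max(abs(mains$emg[mid]))), -20)
  slow <- filter_emg(mk(0.1))
  expect_lt(20 * log10(max(abs(slow$emg[mid]))), -12)
  # frequency-response oracle: forward-backward filtering realises the
  # squared magnitude of the bandpass/band-stop cascade
  bp <- signal::cheby1(2, 0.5, c(1, 90) / 125, type = "pass")
  st <- signal::cheby1(2, 0.5, c(58, 62) / 125, type = "stop")
  gain_at <- function(flt, f) {
    h <- signal::freqz(flt, n = 4096, Fs = 250)
    approx(h$f, abs(h$h), xout = f)$y
  }
  expected <- gain_at(bp, 30)^2 * gain_at(st, 30)^2
  mid_band <- filter_emg(mk(30))
  expect_lt(abs(max(mid_band$emg[mid]) - expected), 0.02)
  expect_gt(expected, 0.7)
})

test_that("common average referencing zeroes the instantaneous mean", {
  rec <- small_pre()$recording
  expect_lt(max(abs(colMeans(rec$eeg))), 1e-9)
})

test_that("CAR matches the brute-force subtraction on a toy input", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7,
                0, 0, 7, 7, 3, 3, 1,
                -2, 4, 0, 1, 9, -5, 2), nrow = 7)
  rec <- apply_car(toy_recording(x))
  oracle <- x
  for (j in 1:3) oracle[, j] <- x[, j] - mean(x[, j])
  expect_equal(rec$eeg, oracle, ignore_attr = TRUE)
  # identical channels are annihilated
  same <- matrix(rep(rnorm(50), each = 7), nrow = 7)
  expect_lt(max(abs(apply_car(toy_recording(same))$eeg)), 1e-12)
})

test_that("CAR requires at least two channels", {
  x <- matrix(rnorm(100), 1, 100)
  expect_error(apply_car(toy_recording(x)), "too_few_channels")
})

test_that("event detection finds every planted stimulus", {
  pre <- small_pre()
  s <- small_session()
  expect_equal(nrow(pre$events), nrow(s$truth))
  expect_true(all(pre$events$valid))
  expect_equal(pre$events$condition, s$truth$condition)
})

test_that("detected reaction times match ground truth within one sample", {
  pre <- small_pre()
  s <- small_session()
  err <- abs(pre$events$brt_ms - s$truth$brt_ms)
  expect_gte(mean(err <= 20), 0.99)
})

test_that("a dead pedal flags every event invalid with the stated reason", {
  T <- 5000
  light <- numeric(T); light[c(500, 2000, 3500)] <- NA
  light <- numeric(T)
  for (k in c(500, 2000, 3500)) light[k:(k + 750)] <- 1
  rec <- toy_recording(matrix(0, 7, T), light = light, brake = numeric(T))
  ev <- detect_events(rec)
  expect_equal(nrow(ev), 3)
  expect_true(all(!ev$valid))
  expect_true(all(grepl("no post-stimulus activation", ev$reason)))
})

test_that("response timing arithmetic is exact", {
  # stimulus at 10.000 s, pedal crossing 0.01 at 10.716 s (on the 250 Hz
  # grid) -> a reaction time of 716 ms by pure subtraction
  T <- 5000
  light <- numeric(T); light[2501:3250] <- 1
  brake <- numeric(T)
  brake[(10.716 * 250 + 1):T] <- 0.05
  rec <- toy_recording(matrix(0, 7, T), light = light, brake = brake)
  ev <- detect_events(rec)
  expect_equal(ev$stimulus_time_s, 10)
  expect_equal(ev$brt_ms, 716, tolerance = 1e-9)
})

test_that("segments span exactly 2 s and conserve the event count", {
  pre <- small_pre()
  segs <- segment_recording(pre$recording, pre$events)
  expect_equal(length(segs), sum(pre$events$valid))
  for (seg in segs) {
    expect_equal(ncol(seg$eeg), 500)
    expect_equal(length(seg$emg), 500)
    # the segment contains its event's response
    expect_true(any(seg$brake >= 0.01))
  }
})

test_that("an event too close to the recording end is flagged, not fatal", {
  T <- 1000
  light <- numeric(T); light[900:T] <- 1
  brake <- numeric(T); brake[950:T] <- 0.5
  rec <- toy_recording(matrix(0, 7, T), light = light, brake = brake)
  ev <- detect_events(rec)
  segs <- segment_recording(rec, ev)
  expect_length(segs, 0)
  ev2 <- attr(segs, "events")
  expect_false(ev2$valid[1])
  expect_match(ev2$reason[1], "exceeds recording bounds")
})

test_that("rejection rules fire on planted defects and conserve counts", {
  pre <- small_pre()
  segs <- segment_recording(pre$recording, pre$events)
  rej <- reject_segments(segs)
  expect_equal(length(rej$kept) + nrow(rej$rejected), length(segs))
  # a 500 uV spike trips the EEG amplitude rule
  spiked <- segs
  spiked[[1]]$eeg[3, 100] <- 500
  rej2 <- reject_segments(spiked)
  expect_true(any(rej2$rejected$event == spiked[[1]]$event &
                    grepl("eeg", rej2$rejected$reason)))
  # most segments with the planted burst pass the EMG rule
  expect_gte(length(rej$kept) / length(segs), 0.8)
})
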