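#' Phenomenological model of the recorded bio-signals
#'
#' Describes what the synthetic generator plants on top of the noise floor of
#' each session. All amplitudes are in microvolts; all latencies in
#' milliseconds. Setting every component amplitude to zero yields pure noise
#' channels, which is the null condition used for type-I-error checks.
#'
#' Components:
#' \describe{
#'   \item{`eeg_noise`}{Background EEG as `1/f^exponent` noise scaled to a
#'     target RMS per channel (default exponent 1, 10 uV RMS -- a standard
#'     resting-EEG background model).}
#'   \item{`pre_movement`}{A slow negative readiness ramp ending at the
#'     response: linear from 0 to `amplitude` over `duration_ms`, returning
#'     to baseline over `release_ms` after the response. Channel topography
#'     given by `weights`, largest over the vertex (Cz).}
#'   \item{`erp_visual`}{A Gaussian post-stimulus evoked component
#'     (`latency_ms` to peak, `sd_ms` width) largest over parietal sites.}
#'   \item{`emg_burst`}{A leg-muscle burst: band-limited noise carrier
#'     multiplied by a raised-cosine envelope whose planted rise starts at
#'     `onset_ms`, peaks at `peak_ms` and decays over `fall_ms` (latencies
#'     relative to the stimulus). Note that the *measured* leg-movement
#'     envelope (see [leg_envelope()]) departs from baseline earlier than
#'     the planted rise, because the analytic-signal magnitude of a burst
#'     has leading tails; the defaults (rise 745 ms, peak 855 ms, 18 uV on
#'     a 5 uV baseline) are calibrated so the measured across-trial
#'     envelope crosses its 10%-over-baseline onset near 600 ms and peaks
#'     near 850 ms, the observed leg-movement phenomenology. `lock` chooses
#'     whether latencies are anchored to the stimulus (default) or to each
#'     event's response (shifted by `response_ref_ms`, so both anchorings
#'     coincide for a 700 ms reaction time).}
#'   \item{`line_noise`}{Mains interference added to EEG and EMG.}
#'   \item{`artifact`}{An optional amplitude-outlier injector: `rate` square
#'     pulses (100 ms, `amplitude` uV, one random EEG channel) per session,
#'     emulating gross movement artifacts for the rejection rules. Off by
#'     default.}
#' }
#'
#' @param eeg_noise list(exponent, rms).
#' @param pre_movement list(duration_ms, amplitude, release_ms, weights).
#' @param erp_visual list(latency_ms, sd_ms, amplitude, weights).
#' @param emg_burst list(onset_ms, peak_ms, fall_ms, amplitude, band,
#'   noise_rms, lock).
#' @param line_noise list(freq, amplitude).
#' @param artifact list(rate, amplitude, duration_ms).
#' @return an object of class `braking_signal_model`.
#' @export
#' @examples
#' quiet <- signal_model(pre_movement = list(amplitude = 0),
#'                       erp_visual = list(amplitude = 0),
#'                       emg_burst = list(amplitude = 0))
signal_model <- function(eeg_noise = list(),
                         pre_movement = list(),
                         erp_visual = list(),
                         emg_burst = list(),
                         line_noise = list(),
                         artifact = list()) {
  model <- list(
    eeg_noise = modifyList(
      list(exponent = 1, rms = 10), eeg_noise),
    pre_movement = modifyList(
      list(duration_ms = 1200, amplitude = -10, release_ms = 300,
           weights = c(F3 = 0.2, F4 = 0.2, C3 = 0.8, C4 = 0.6,
                       Cz = 1.0, P3 = 0.3, P4 = 0.3)),
      pre_movement),
    erp_visual = modifyList(
      list(latency_ms = 200, sd_ms = 50, amplitude = 5,
           weights = c(F3 = 0.1, F4 = 0.1, C3 = 0.3, C4 = 0.3,
                       Cz = 0.4, P3 = 1.0, P4 = 1.0)),
      erp_visual),
    emg_burst = modifyList(
      list(onset_ms = 745, peak_ms = 855, fall_ms = 350, amplitude = 18,
           band = c(30, 90), noise_rms = 5, lock = "stimulus",
           response_ref_ms = 700),
      emg_burst),
    line_noise = modifyList(
      list(freq = 60, amplitude = 1), line_noise),
    artifact = modifyList(
      list(rate = 0, amplitude = 500, duration_ms = 100), artifact)
  )
  stopifnot(model$emg_burst$lock %in% c("stimulus", "response"),
            model$emg_burst$onset_ms < model$emg_burst$peak_ms,
            model$eeg_noise$rms >= 0)
  class(model) <- "braking_signal_model"
  model
}

#' @export
print.braking_signal_model <- function(x, ...) {
  cat("Signal model:\n")
  cat(sprintf("  EEG noise: 1/f^%g, %g uV RMS\n",
              x$eeg_noise$exponent, x$eeg_noise$rms))
  cat(sprintf("  pre-movement ramp: %g uV over %g ms (Cz-weighted)\n",
              x$pre_movement$amplitude, x$pre_movement$duration_ms))
  cat(sprintf("  visual ERP: %g uV at %g ms (parietal)\n",
              x$erp_visual$amplitude, x$erp_visual$latency_ms))
  cat(sprintf("  EMG burst: %g uV, onset %g ms, peak %g ms (%s-locked)\n",
              x$emg_burst$amplitude, x$emg_burst$onset_ms,
              x$emg_burst$peak_ms, x$emg_burst$lock))
  invisible(x)
}

# 1/f^alpha noise of length n at rate fs, unit-free, scaled to target RMS.
# Spectrum is flattened below f_lo to keep the DC region finite. Synthesis
# happens at a highly composite FFT length (R's FFT is slow for lengths
# with large prime factors) and is truncated to n.
pink_noise <- function(n, fs, exponent = 1, rms = 1, f_lo = 0.5) {
  if (rms == 0) return(numeric(n))
  nfft <- stats::nextn(n, c(2, 3, 5))
  freqs <- seq(0, fs / 2, length.out = floor(nfft / 2) + 1)
  shape <- pmax(freqs, f_lo)^(-exponent / 2)
  shape[1] <- 0  # no DC
  half <- floor(nfft / 2) + 1
  re <- rnorm(half); im <- rnorm(half)
  spec_half <- complex(real = re, imaginary = im) * shape
  spec <- complex(length.out = nfft)
  spec[seq_len(half)] <- spec_half
  if (nfft %% 2 == 0) {
    spec[half] <- complex(real = re[half] * shape[half], imaginary = 0)
    if (half > 2) spec[nfft:(half + 1)] <- Conj(spec_half[2:(half - 1)])
  } else {
    if (half > 1) spec[nfft:(half + 1)] <- Conj(spec_half[2:half])
  }
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)] / nfft
  x * rms / sqrt(mean(x^2))
}

# Band-limited white noise (simple FFT brick-wall), scaled to target RMS.
band_noise <- function(n, fs, band, rms = 1) {
  if (rms == 0) return(numeric(n))
  nfft <- stats::nextn(n, c(2, 3, 5))
  x <- rnorm(nfft)
  spec <- fft(x)
  freqs <- c(seq(0, floor(nfft / 2)),
             seq(-ceiling(nfft / 2) + 1, -1)) * fs / nfft
  keep <- abs(freqs) >= band[1] & abs(freqs) <= band[2]
  spec[!keep] <- 0
  y <- Re(fft(spec, inverse = TRUE))[seq_len(n)] / nfft
  y * rms / sqrt(mean(y^2))
}
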