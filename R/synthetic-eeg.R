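# Synthetic EEG substrate: amplitude-modulated 1/f^alpha background and
# spike-and-wave seizure injection. These generators define the study
# conditions every downstream stage is tested against.

#' Default background-model parameters
#'
#' @param baseline_amplitude RMS amplitude (microvolts) of the recovered /
#'   pre-asphyxia background.
#' @param isoelectric_duration_s flat (suppressed) interval after asphyxia,
#'   in simulated seconds.
#' @param recovery_tau_s exponential recovery time constant of the RMS
#'   envelope, simulated seconds.
#' @param alpha one-over-f spectral exponent (PSD ~ 1/f^alpha over the
#'   analysis band).
#' @param baseline_duration_s optional pre-asphyxia baseline segment at full
#'   amplitude prepended before the isoelectric interval (0 = none).
#' @param floor_amplitude_uv residual RMS during the isoelectric interval.
#' @param sampling_rate,n_channels,channel_labels signal layout.
#' @return parameter list for [generate_background()].
#' @export
background_params <- function(baseline_amplitude = 25,
                              isoelectric_duration_s = 0,
                              recovery_tau_s = 1,
                              alpha = 2,
                              baseline_duration_s = 0,
                              floor_amplitude_uv = 1,
                              sampling_rate = 256,
                              n_channels = 8,
                              channel_labels = eeg_montage()) {
  check_positive(baseline_amplitude, "baseline_amplitude")
  check_positive(sampling_rate, "sampling_rate")
  if (isoelectric_duration_s < 0 || recovery_tau_s < 0 ||
      baseline_duration_s < 0)
    stop_invalid("durations and time constants must be non-negative")
  list(baseline_amplitude = baseline_amplitude,
       isoelectric_duration_s = isoelectric_duration_s,
       recovery_tau_s = recovery_tau_s, alpha = alpha,
       baseline_duration_s = baseline_duration_s,
       floor_amplitude_uv = floor_amplitude_uv,
       sampling_rate = sampling_rate, n_channels = n_channels,
       channel_labels = channel_labels[seq_len(n_channels)])
}

# Band-limited 1/f^alpha Gaussian noise, unit RMS, via FFT spectral shaping.
colored_noise <- function(n, sampling_rate, alpha, fmin = 0.5, fmax = 30) {
  wn <- stats::rnorm(n)
  sp <- stats::fft(wn)
  freqs <- (seq_len(n) - 1L) * sampling_rate / n
  fmag <- pmin(freqs, sampling_rate - freqs)
  shape <- numeric(n)
  inband <- fmag >= fmin & fmag <= fmax
  shape[inband] <- fmag[inband]^(-alpha / 2)
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x / rms(x)
}

#' Generate post-asphyxia background EEG
#'
#' Multi-channel amplitude-modulated 1/f^alpha Gaussian noise band-limited
#' to the analysis range. The RMS envelope is near zero (isoelectric) for
#' `isoelectric_duration_s`, then recovers exponentially with time constant
#' `recovery_tau_s` toward `baseline_amplitude`; an optional full-amplitude
#' pre-asphyxia baseline segment can be prepended (the recording's
#' `start_offset` is set to minus its length).
#'
#' @param duration_s post-asphyxia record length in simulated seconds (> 0);
#'   total length is `baseline_duration_s + duration_s`.
#' @param params a [background_params()] list.
#' @param seed integer seed for reproducibility (optional).
#' @param timeline_compression nominal seconds per simulated second.
#' @return an [eeg_recording()] with `start_offset = -baseline_duration_s`.
#' @export
generate_background <- function(duration_s, params = background_params(),
                                seed = NULL, timeline_compression = 1) {
  check_positive(duration_s, "duration_s")
  check_positive(params$baseline_amplitude, "baseline_amplitude")
  if (!is.null(seed)) set.seed(seed)
  sr <- params$sampling_rate
  bd <- params$baseline_duration_s
  n <- round((bd + duration_s) * sr)
  t_post <- (seq_len(n) - 1L) / sr - bd   # time relative to reventilation
  env <- numeric(n)
  env[t_post < 0] <- params$baseline_amplitude
  iso <- t_post >= 0 & t_post < params$isoelectric_duration_s
  env[iso] <- params$floor_amplitude_uv
  rec_phase <- t_post >= params$isoelectric_duration_s
  tau <- params$recovery_tau_s
  trec <- t_post[rec_phase] - params$isoelectric_duration_s
  level <- if (tau <= 1e-12) rep(1, length(trec)) else 1 - exp(-trec / tau)
  env[rec_phase] <- pmax(params$floor_amplitude_uv,
                         params$baseline_amplitude * level)
  sig <- matrix(0, nrow = params$n_channels, ncol = n)
  for (ch in seq_len(params$n_channels))
    sig[ch, ] <- colored_noise(n, sr, params$alpha) * env
  eeg_recording(sig, sr, channel_labels = params$channel_labels,
                start_offset = -bd,
                timeline_compression = timeline_compression)
}

# One spike-and-wave cycle at `discharge_hz`: biphasic 20 ms spike followed
# by a slow half-sine wave filling the rest of the cycle; unit-RMS train.
spike_wave_kernel <- function(sampling_rate, discharge_hz) {
  period <- round(sampling_rate / discharge_hz)
  if (period < 4L) stop_invalid("discharge frequency too high for this rate")
  spike_n <- max(2L, round(0.020 * sampling_rate))
  spike_n <- min(spike_n, period - 2L)
  half <- ceiling(spike_n / 2)
  spike <- c(sin(pi * seq_len(half) / half),
             -0.5 * sin(pi * seq_len(spike_n - half) / (spike_n - half)))
  wave_n <- period - spike_n
  wave <- 0.8 * sin(pi * seq_len(wave_n) / wave_n)
  cyc <- c(spike, wave)
  cyc / rms(cyc)
}

#' Inject a spike-and-wave seizure episode
#'
#' Adds a generalized spike-and-wave discharge train (repeating at
#' `discharge_hz`) over `[start_s, start_s + duration_s]` on every channel,
#' scaled per channel to `amplitude_gain` times the local background RMS of
#' that interval. The signal outside the interval is bit-identical to the
#' input, and a `"seizure"` annotation with the exact interval is appended.
#' A zero-duration request returns the recording unchanged.
#'
#' @param recording an [eeg_recording()].
#' @param start_s,duration_s episode interval in record coordinates
#'   (simulated seconds); must lie inside the record and not overlap a
#'   previously injected seizure.
#' @param discharge_hz discharge repetition rate (default 10 Hz).
#' @param amplitude_gain episode amplitude as a multiple of the local
#'   background RMS (default 4).
#' @return the modified [eeg_recording()].
#' @export
inject_seizure <- function(recording, start_s, duration_s, discharge_hz = 10,
                           amplitude_gain = 4) {
  if (duration_s == 0) return(recording)
  check_positive(duration_s, "duration_s")
  check_positive(amplitude_gain, "amplitude_gain")
  dur <- recording_duration(recording)
  if (start_s < 0 || start_s + duration_s > dur + 1e-9)
    stop_invalid("seizure interval [", start_s, ", ", start_s + duration_s,
                 "] outside the record (", dur, " s)")
  prior <- recording$annotations
  prior <- prior[prior$label == "seizure", , drop = FALSE]
  if (nrow(prior) && any(pmin(prior$end_s, start_s + duration_s) -
                         pmax(prior$start_s, start_s) > 1e-9))
    stop_invalid("seizure interval overlaps a previously injected seizure")
  sr <- recording$sampling_rate
  i0 <- floor(start_s * sr) + 1L
  i1 <- min(i0 + round(duration_s * sr) - 1L, ncol(recording$signal))
  cyc <- spike_wave_kernel(sr, discharge_hz)
  train <- rep_len(cyc, i1 - i0 + 1L)
  global_rms <- rms(as.vector(recording$signal))
  for (ch in seq_len(nrow(recording$signal))) {
    local <- rms(recording$signal[ch, i0:i1])
    if (local < 1e-6) local <- max(global_rms, 1)
    recording$signal[ch, i0:i1] <- recording$signal[ch, i0:i1] +
      amplitude_gain * local * train
  }
  recording$annotations <- rbind(
    recording$annotations,
    data.frame(label = "seizure", start_s = start_s,
               end_s = start_s + duration_s, channel_scope = "generalized"))
  recording
}
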