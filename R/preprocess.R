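#' Zero-phase broadband bandpass filter
#'
#' Applies a 4th-order Butterworth bandpass (default 1-30 Hz) forward and
#' backward (`signal::filtfilt`), i.e. zero-phase so evoked-potential
#' latencies are preserved. The effective magnitude response is the squared
#' Butterworth response (>= 40 dB attenuation one octave beyond the edges).
#'
#' @param recording an [eeg_recording()].
#' @param low_hz,high_hz passband edges in Hz; `0 < low < high < Nyquist`.
#' @param order filter order of the underlying single-pass design.
#' @return a filtered [eeg_recording()] of identical dimensions.
#' @export
eeg_bandpass <- function(recording, low_hz = 1, high_hz = 30, order = 4) {
  nyq <- recording$sampling_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop_invalid("need 0 < low_hz < high_hz < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- recording
  for (ch in seq_len(nrow(out$signal)))
    out$signal[ch, ] <- signal::filtfilt(bf, recording$signal[ch, ])
  out
}

#' Standard qEEG band partition
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30 Hz (configurable).
#' @return named list of `c(low, high)` edges in Hz.
#' @export
qeeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Decompose a broadband recording into standard frequency bands
#'
#' Splits the signal into delta/theta/alpha/beta components by zero-phase
#' spectral masking (FFT brick-wall at the band edges). The masks partition
#' the broadband range exactly, so per-epoch band powers sum to the broadband
#' power (Parseval) up to edge-bin assignment.
#'
#' @param recording an [eeg_recording()], already bandpass filtered.
#' @param bands named list of band edges as from [qeeg_bands()].
#' @return named list of band-limited [eeg_recording()]s.
#' @export
band_decompose <- function(recording, bands = qeeg_bands()) {
  edges <- unlist(bands)
  if (any(diff(unlist(lapply(bands, identity))) < 0) ||
      any(vapply(bands, function(b) b[2] <= b[1], TRUE)))
    stop_invalid("band edges must be increasing")
  n <- ncol(recording$signal)
  freqs <- (seq_len(n) - 1L) * recording$sampling_rate / n
  # fold to two-sided frequency magnitudes
  fmag <- pmin(freqs, recording$sampling_rate - freqs)
  out <- lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    # half-open (low, high] bins so adjacent bands never share a bin
    mask <- fmag > b[1] & fmag <= b[2]
    rec <- recording
    for (ch in seq_len(nrow(rec$signal))) {
      sp <- stats::fft(recording$signal[ch, ])
      sp[!mask] <- 0+0i
      rec$signal[ch, ] <- Re(stats::fft(sp, inverse = TRUE)) / n
    }
    rec
  })
  names(out) <- names(bands)
  out
}

#' Tile a recording into analysis epochs
#'
#' Contiguous tiling of the record with a configurable window and fractional
#' overlap; every sample is covered except a tail shorter than one hop.
#'
#' @param recording an [eeg_recording()].
#' @param window_s epoch length in (simulated) seconds.
#' @param overlap_fraction fractional overlap in `[0, 1)`; default 0.5.
#' @return data frame with `epoch`, `start_s`, `end_s`; hop stored in
#'   attribute `hop_s`.
#' @export
epoch_stream <- function(recording, window_s = 30, overlap_fraction = 0.5) {
  check_positive(window_s, "window_s")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_invalid("`overlap_fraction` must be in [0, 1)")
  dur <- recording_duration(recording)
  if (window_s > dur + 1e-9)
    stop_invalid("window (", window_s, " s) longer than record (", dur, " s)")
  hop <- window_s * (1 - overlap_fraction)
  starts <- seq(0, dur - window_s + 1e-9, by = hop)
  out <- data.frame(epoch = seq_along(starts), start_s = starts,
                    end_s = starts + window_s)
  attr(out, "hop_s") <- hop
  out
}

# Extract the sample block of one epoch (all channels).
epoch_samples <- function(recording, start_s, window_s) {
  sr <- recording$sampling_rate
  i0 <- floor(start_s * sr) + 1L
  i1 <- min(i0 + round(window_s * sr) - 1L, ncol(recording$signal))
  recording$signal[, i0:i1, drop = FALSE]
}
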