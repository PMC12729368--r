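# Small fixture builders used across test files. Everything is generated in
# code; no stored data.

rms <- neoqeeg:::rms

# sample() treats a length-1 vector as 1:n; this always picks from `x`
pick_one <- function(x) x[sample.int(length(x), 1L)]
sim_s_to_nominal_h <- neoqeeg:::sim_s_to_nominal_h

# Stationary (fully recovered) background record.
stationary_record <- function(duration_s = 60, amplitude = 25, alpha = 2,
                              n_channels = 2, seed = 1, srate = 256) {
  generate_background(
    duration_s,
    background_params(baseline_amplitude = amplitude,
                      isoelectric_duration_s = 0, recovery_tau_s = 1e-9,
                      alpha = alpha, n_channels = n_channels,
                      channel_labels = paste0("ch", seq_len(n_channels)),
                      sampling_rate = srate),
    seed = seed)
}

sine_record <- function(freq_hz, duration_s = 10, srate = 256,
                        amplitude = 10, n_channels = 1) {
  t <- (seq_len(round(duration_s * srate)) - 1L) / srate
  sig <- matrix(rep(amplitude * sin(2 * pi * freq_hz * t), n_channels),
                nrow = n_channels, byrow = TRUE)
  eeg_recording(sig, srate, paste0("ch", seq_len(n_channels)))
}

# PSD-like object on an explicit grid.
make_psd <- function(power, frequencies = seq_along(power), df = 1) {
  list(frequencies = frequencies, power = power, df = df)
}

# RMS of the central portion of a vector (drops filter edge transients).
central_rms <- function(x, drop_s = 1, srate = 256) {
  n <- length(x)
  k <- round(drop_s * srate)
  sqrt(mean(x[(k + 1):(n - k)]^2))
}
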