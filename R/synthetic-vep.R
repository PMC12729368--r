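#' Default flash-VEP simulation parameters
#'
#' The stimulation protocol is 10 trains of 10 flashes at 1 Hz with 10 s
#' pauses between trains (100 trials total). Each stimulus-locked epoch is a
#' deterministic P100 template — a positive Gaussian-shaped deflection
#' peaking at `p100_latency_ms` — plus independent Gaussian noise.
#'
#' @param p100_latency_ms template peak latency (default 100 ms).
#' @param p100_amplitude_uv template peak amplitude (default 10 uV).
#' @param noise_sd_uv per-sample noise standard deviation (default 5 uV).
#' @param peak_width_ms Gaussian template sigma (default 15 ms).
#' @param n_trains,stimuli_per_train,stimulus_rate_hz,train_gap_s protocol.
#' @param epoch_window_s peri-stimulus epoch `c(pre, post)` in seconds.
#' @param sampling_rate Hz.
#' @return parameter list for [generate_vep_trials()].
#' @export
vep_params <- function(p100_latency_ms = 100, p100_amplitude_uv = 10,
                       noise_sd_uv = 5, peak_width_ms = 15,
                       n_trains = 10, stimuli_per_train = 10,
                       stimulus_rate_hz = 1, train_gap_s = 10,
                       epoch_window_s = c(0.05, 0.35),
                       sampling_rate = 256) {
  check_positive(p100_latency_ms, "p100_latency_ms")
  check_positive(p100_amplitude_uv, "p100_amplitude_uv")
  if (noise_sd_uv < 0) stop_invalid("`noise_sd_uv` must be non-negative")
  list(p100_latency_ms = p100_latency_ms,
       p100_amplitude_uv = p100_amplitude_uv, noise_sd_uv = noise_sd_uv,
       peak_width_ms = peak_width_ms, n_trains = n_trains,
       stimuli_per_train = stimuli_per_train,
       stimulus_rate_hz = stimulus_rate_hz, train_gap_s = train_gap_s,
       epoch_window_s = epoch_window_s, sampling_rate = sampling_rate)
}

vep_template <- function(params) {
  sr <- params$sampling_rate
  t_ms <- seq(-params$epoch_window_s[1], params$epoch_window_s[2],
              by = 1 / sr) * 1000
  tmpl <- params$p100_amplitude_uv *
    exp(-0.5 * ((t_ms - params$p100_latency_ms) / params$peak_width_ms)^2)
  list(times_ms = t_ms, template = tmpl)
}

#' Simulate stimulus-locked flash-VEP trials
#'
#' @param params a [vep_params()] list.
#' @param seed integer seed (optional).
#' @return list with `trials` (n_trials x n_samples matrix, uV),
#'   `times_ms` (peri-stimulus sample times), `template` (noiseless epoch),
#'   and `stimulus_times_s` (flash times within the session).
#' @export
generate_vep_trials <- function(params = vep_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tp <- vep_template(params)
  n_trials <- params$n_trains * params$stimuli_per_train
  trials <- matrix(rep(tp$template, each = n_trials), nrow = n_trials)
  if (params$noise_sd_uv > 0)
    trials <- trials + matrix(stats::rnorm(length(trials),
                                           sd = params$noise_sd_uv),
                              nrow = n_trials)
  isi <- 1 / params$stimulus_rate_hz
  train_len <- params$stimuli_per_train * isi
  stim <- as.vector(vapply(seq_len(params$n_trains) - 1L, function(k)
    k * (train_len + params$train_gap_s) + (seq_len(params$stimuli_per_train) - 1L) * isi,
    numeric(params$stimuli_per_train)))
  list(trials = trials, times_ms = tp$times_ms, template = tp$template,
       stimulus_times_s = stim)
}
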