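test_that("detection features separate rhythmic discharges from background", {
  rec <- stationary_record(300, n_channels = 2, seed = 14)
  rec <- inject_seizure(rec, 150, 40, discharge_hz = 10, amplitude_gain = 4)
  filt <- eeg_bandpass(rec)
  feats <- entropy_feature_series(filt)
  inside <- feats$start_s >= 150 & feats$end_s <= 190
  expect_lt(median(feats$entropy[inside]),
            median(feats$entropy[!inside], na.rm = TRUE))
  # amplitude rises well above background (the 1-30 Hz filter sheds the
  # spike harmonics, so the post-filter ratio sits below the raw gain of 4)
  expect_gt(median(feats$rms_uv[inside]) / median(feats$rms_uv[!inside]), 2.5)

  # featureless zero record: all suppressed sentinels
  zero <- eeg_recording(matrix(0, 2, 256 * 60), 256, c("a", "b"))
  fz <- entropy_feature_series(zero)
  expect_true(all(fz$suppressed))
  expect_true(all(is.na(fz$entropy)))
})

test_that("injected episodes are detected with accurate intervals", {
  rec <- stationary_record(600, n_channels = 4, seed = 15)
  truth <- data.frame(start = c(100, 300, 500), dur = 60)
  for (st in truth$start) rec <- inject_seizure(rec, st, 60)
  filt <- eeg_bandpass(rec)
  ev <- detect_events(entropy_feature_series(filt), recording = filt)
  expect_equal(nrow(ev), 3)
  for (k in seq_len(nrow(truth))) {
    a0 <- truth$start[k]; a1 <- a0 + truth$dur[k]
    ov <- pmin(ev$end_s, a1) - pmax(ev$start_s, a0)
    i <- which.max(ov)
    jaccard <- ov[i] / (max(ev$end_s[i], a1) - min(ev$start_s[i], a0))
    expect_gte(jaccard, 0.8)
  }
  expect_true(all(ev$dominant_hz == 10))
  expect_true(all(ev$channel_scope == "generalized"))
})

test_that("seizure-free recordings yield no events", {
  for (seed in 1:5) {
    p <- background_params(baseline_amplitude = 25,
                           isoelectric_duration_s = 7.5,
                           recovery_tau_s = 60, baseline_duration_s = 7.5,
                           n_channels = 4,
                           channel_labels = paste0("ch", 1:4))
    rec <- generate_background(360, p, seed = seed)
    filt <- eeg_bandpass(rec)
    ev <- detect_events(entropy_feature_series(filt), recording = filt)
    expect_equal(nrow(ev), 0)
  }
})

test_that("raising the entropy threshold never increases the event count", {
  rec <- stationary_record(400, n_channels = 2, seed = 16)
  for (st in c(100, 200, 320)) rec <- inject_seizure(rec, st, 30)
  filt <- eeg_bandpass(rec)
  feats <- entropy_feature_series(filt)
  sweeps <- lapply(c(1, 2, 3, 6, 12), function(z)
    detect_events(feats, detection_config(z_thr = z)))
  # total flagged duration shrinks monotonically; the raw event count can
  # transiently rise when a stricter threshold splits one event in two, so
  # it is only compared between the extremes
  durations <- vapply(sweeps, function(ev) sum(ev$duration_s), numeric(1))
  expect_true(all(diff(durations) <= 0))
  expect_lte(nrow(sweeps[[length(sweeps)]]), nrow(sweeps[[1]]))
})

test_that("no events are emitted inside suppressed spans", {
  p <- background_params(baseline_amplitude = 25,
                         isoelectric_duration_s = 150, recovery_tau_s = 20,
                         n_channels = 2, channel_labels = c("a", "b"))
  rec <- generate_background(400, p, seed = 17)
  rec <- inject_seizure(rec, 300, 40)
  filt <- eeg_bandpass(rec)
  feats <- entropy_feature_series(filt)
  ev <- detect_events(feats, recording = filt)
  supp_end <- max(feats$end_s[feats$suppressed])
  expect_true(all(ev$start_s >= supp_end))
  expect_gte(nrow(ev), 1)
})

test_that("seizure summaries compute burden and onset in nominal hours", {
  none <- summarize_seizures(
    data.frame(start_s = numeric(), end_s = numeric()), "a1", "A-TH")
  expect_true(none$seizure_free)
  expect_equal(none$total_duration_h, 0)
  expect_true(is.na(none$onset_latency_h))

  ev <- data.frame(start_s = c(1000, 5000), end_s = c(1000 + 1200, 5000 + 2400))
  s <- summarize_seizures(ev, "a2", "A-NT", timeline_compression = 1)
  expect_equal(s$total_duration_h, 1.0)
  expect_equal(s$event_count, 2)
  expect_equal(s$onset_latency_h, 1000 / 3600)

  overlapping <- data.frame(start_s = c(0, 50), end_s = c(100, 150))
  expect_error(summarize_seizures(overlapping, "a3", "A-NT"), "overlap")
})

test_that("group onset profiles aggregate incidence and onsets", {
  summ <- rbind(
    summarize_seizures(data.frame(start_s = 100, end_s = 200), "n1", "A-NT"),
    summarize_seizures(data.frame(start_s = 300, end_s = 400), "n2", "A-NT"),
    summarize_seizures(data.frame(start_s = 500, end_s = 600), "h1", "A-H2"),
    summarize_seizures(data.frame(start_s = numeric(), end_s = numeric()),
                       "t1", "A-TH"))
  prof <- group_onset_profile(summ)
  expect_equal(prof$incidence[prof$group == "A-TH"], 0)
  expect_equal(prof$n_seizing[prof$group == "A-NT"], 2)
  expect_gt(prof$median_onset_h[prof$group == "A-H2"],
            prof$median_onset_h[prof$group == "A-NT"])
  # identical groups give identical profiles
  two <- rbind(
    summarize_seizures(data.frame(start_s = 100, end_s = 200), "x", "A-NT"),
    summarize_seizures(data.frame(start_s = 100, end_s = 200), "y", "A-H2"))
  p2 <- group_onset_profile(two)
  expect_equal(p2$median_onset_h[1], p2$median_onset_h[2])
  expect_equal(p2$mean_burden_h[1], p2$mean_burden_h[2])
})
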