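test_that("background generator respects suppression and recovery limits", {
  # isoelectric covering the whole record: every 30 s epoch stays flat
  p_iso <- background_params(baseline_amplitude = 25,
                             isoelectric_duration_s = 120,
                             recovery_tau_s = 3600)
  rec <- generate_background(90, p_iso, seed = 1)
  eps <- epoch_stream(rec, 30, 0)
  for (e in seq_len(nrow(eps)))
    expect_lt(rms(as.vector(
      neoqeeg:::epoch_samples(rec, eps$start_s[e], 30))), 5)

  # instant recovery: epoch RMS sits at the baseline amplitude throughout
  rec2 <- stationary_record(90, amplitude = 25, seed = 2)
  expect_equal(rms(as.vector(rec2$signal)), 25, tolerance = 1e-4)
  eps2 <- epoch_stream(rec2, 30, 0)
  for (e in seq_len(nrow(eps2))) {
    r <- rms(as.vector(neoqeeg:::epoch_samples(rec2, eps2$start_s[e], 30)))
    expect_gt(r, 25 * 0.7)
    expect_lt(r, 25 * 1.3)
  }
})

test_that("background spectral exponent is recovered by a log-log slope fit", {
  rec <- stationary_record(300, alpha = 1, n_channels = 1, seed = 3)
  psd <- compute_psd(rec$signal[1, ], 256)
  sel <- psd$frequencies >= 2 & psd$frequencies <= 20
  slope <- unname(coef(lm(log10(psd$power[sel]) ~
                            log10(psd$frequencies[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("background generator rejects invalid parameters", {
  expect_error(generate_background(0, background_params()), "positive")
  expect_error(generate_background(-5, background_params()), "positive")
  expect_error(background_params(baseline_amplitude = -1), "positive")
})

test_that("seizure injection scales, annotates exactly, and leaves the rest untouched", {
  rec <- stationary_record(120, seed = 4)
  bg_rms <- rms(rec$signal[1, (256 * 40 + 1):(256 * 70)])
  out <- inject_seizure(rec, 40, 30, discharge_hz = 10, amplitude_gain = 5)
  seg <- out$signal[1, (256 * 40 + 1):(256 * 70)]
  expect_gte(rms(seg), 5 * bg_rms)
  # outside the interval: bit-identical
  expect_identical(out$signal[, 1:(256 * 40)], rec$signal[, 1:(256 * 40)])
  expect_identical(out$signal[, (256 * 70 + 1):ncol(rec$signal)],
                   rec$signal[, (256 * 70 + 1):ncol(rec$signal)])
  expect_equal(out$annotations$start_s, 40)
  expect_equal(out$annotations$end_s, 70)

  # modal frequency of the injected interval is the discharge rate
  psd <- compute_psd(seg, 256, segment_s = 2)
  expect_equal(psd$frequencies[which.max(psd$power)], 10)

  # zero duration: unchanged; overlap and out-of-range: errors
  expect_identical(inject_seizure(rec, 40, 0), rec)
  expect_error(inject_seizure(out, 50, 10), "overlap")
  expect_error(inject_seizure(rec, 115, 20), "outside")
})

test_that("VEP trial generator follows the 10x10 protocol and its noise model", {
  tr <- generate_vep_trials(vep_params(noise_sd_uv = 0))
  expect_equal(nrow(tr$trials), 100)
  expect_equal(length(tr$stimulus_times_s), 100)
  # noiseless: every trial equals the template, recovered latency exact
  expect_true(all(apply(tr$trials, 1, identical, tr$template)))
  res <- extract_p100(average_trials(tr))
  expect_lt(abs(res$latency_ms - 100), 0.1)

  # noise at template amplitude: 100-trial averages keep the latency
  set.seed(11)
  lats <- replicate(200, {
    trn <- generate_vep_trials(vep_params(noise_sd_uv = 10))
    extract_p100(average_trials(trn))$latency_ms
  })
  expect_lt(abs(mean(lats) - 100), 8)
  expect_gte(mean(abs(lats - 100) <= 8), 0.95)
})

test_that("protocol schedules encode the cooling/rewarming trajectory", {
  nt <- generate_protocol_schedule("A-NT")
  expect_true(all(schedule_temperature(nt, c(0, 12, 24, 48)) == 38.5))
  th <- generate_protocol_schedule("A-TH")
  expect_equal(schedule_temperature(th, 36), 33.5)
  expect_equal(schedule_temperature(th, 2), 33.5)
  # mid-rewarming at the stated 0.5 C/h ramp
  expect_equal(schedule_temperature(th, 42), 33.5 + 0.5 * 5)
  expect_equal(schedule_temperature(th, 48), 38.5)
  expect_error(generate_protocol_schedule("bogus"), "must be one of")
})

test_that("pathology generator reproduces its binomial injury model", {
  animals <- data.frame(animal_id = "x", group = "A-NT")
  p0 <- pathology_params(injury_p = matrix(
    0, 5, 3, dimnames = list(subcortical_regions(), group_labels())))
  expect_true(all(generate_pathology(animals, p0, seed = 1)$counts$damaged == 0))
  p1 <- pathology_params(injury_p = matrix(
    1, 5, 3, dimnames = list(subcortical_regions(), group_labels())))
  g1 <- generate_pathology(animals, p1, seed = 1)$counts
  expect_true(all(g1$damaged == g1$total))

  # p = 0.9, 200 neurons: cohort-mean percent within +/- 1 of 90
  many <- data.frame(animal_id = sprintf("a%04d", 1:1000), group = "A-NT")
  p9 <- pathology_params(injury_p = matrix(
    0.9, 5, 3, dimnames = list(subcortical_regions(), group_labels())))
  cts <- percent_damaged(generate_pathology(many, p9, seed = 2)$counts)
  m <- mean(cts$percent_damaged[cts$region == "thalamus"])
  expect_lt(abs(m - 90), 1)
})

test_that("cohort bundles are deterministic and carry the group structure", {
  spec <- cohort_spec(n_per_group = c(`A-NT` = 1, `A-H2` = 1, `A-TH` = 1),
                      seed = 5, timeline_compression = 2400, n_channels = 2)
  b1 <- generate_cohort(spec)
  b2 <- generate_cohort(spec)
  expect_identical(b1, b2)
  expect_equal(nrow(b1$animals), 3)

  # default arm sizes reproduce the 22-animal cohort without simulating it
  expect_equal(sum(cohort_spec()$n_per_group), 22)

  # A-TH animals carry no injected seizures; annotated intervals conserve
  # the injected totals exactly
  spec2 <- cohort_spec(n_per_group = c(`A-NT` = 4, `A-H2` = 4, `A-TH` = 4),
                       seed = 6, timeline_compression = 2400, n_channels = 2)
  b <- generate_cohort(spec2)
  ann <- b$annotations
  th_ids <- b$animals$animal_id[b$animals$group == "A-TH"]
  expect_false(any(ann$animal_id %in% th_ids))
  for (id in unique(ann$animal_id)) {
    rec <- b$recordings[[id]]
    a <- rec$annotations
    expect_equal(sum(a$end_s - a$start_s),
                 sum(ann$end_s[ann$animal_id == id] -
                       ann$start_s[ann$animal_id == id]))
  }
})

test_that("injected seizure onsets are later under H2 than under normothermia", {
  onsets <- list(`A-NT` = c(), `A-H2` = c())
  for (seed in 1:4) {
    spec <- cohort_spec(n_per_group = c(`A-NT` = 4, `A-H2` = 4, `A-TH` = 0),
                        seed = seed, timeline_compression = 2400,
                        n_channels = 1)
    b <- generate_cohort(spec)
    ann <- b$annotations
    for (grp in names(onsets)) {
      ids <- b$animals$animal_id[b$animals$group == grp]
      on <- vapply(ids, function(id) {
        a <- ann[ann$animal_id == id, ]
        if (!nrow(a)) return(NA_real_)
        rec <- b$recordings[[id]]
        sim_s_to_nominal_h(min(a$start_s) + rec$start_offset,
                           spec$timeline_compression)
      }, numeric(1))
      onsets[[grp]] <- c(onsets[[grp]], on[is.finite(on)])
    }
  }
  expect_gt(median(onsets$`A-H2`), median(onsets$`A-NT`))
  # configured onset-window dominance: every H2 quantile at or above A-NT's
  qs <- seq(0.1, 0.9, by = 0.2)
  expect_true(all(quantile(onsets$`A-H2`, qs) >=
                    quantile(onsets$`A-NT`, qs) - 1e-9))
})
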