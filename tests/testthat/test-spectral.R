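test_that("Welch PSD conserves power and localizes tones", {
  rec <- eeg_bandpass(stationary_record(30, n_channels = 1, seed = 8))
  x <- rec$signal[1, ]
  psd <- compute_psd(x, 256)
  expect_true(all(psd$power >= 0))
  expect_true(all(diff(psd$frequencies) > 0))
  expect_lt(abs(sum(psd$power) * psd$df - var(x)) / var(x), 0.1)

  p10 <- compute_psd(sine_record(10, 30)$signal[1, ], 256)
  expect_equal(p10$frequencies[which.max(p10$power)], 10)

  pz <- compute_psd(rep(0, 256 * 30), 256)
  expect_true(pz$suppressed)
  expect_true(all(pz$power == 0))
  expect_true(is.na(spectral_edge_frequency(pz)))
  expect_true(is.na(spectral_entropy(pz)))

  expect_error(compute_psd(rnorm(100), 256, segment_s = 4), "shorter")
})

test_that("spectral edge frequency matches its defining cumulative property", {
  # point mass
  pm <- make_psd(as.numeric(1:30 == 12), 1:30)
  expect_equal(spectral_edge_frequency(pm), 12)
  # flat grid: first bin whose cumulative fraction reaches 95%
  flat <- make_psd(rep(1, 30), 1:30)
  expect_equal(spectral_edge_frequency(flat), 29)

  # random PSDs: cumulative power at SEF >= 95% of total, and equality with
  # a brute-force cumulative-sum oracle
  set.seed(9)
  for (i in 1:200) {
    n <- sample(20:120, 1)
    freqs <- seq(1, 30, length.out = n)
    pw <- runif(n)^2
    psd <- make_psd(pw, freqs)
    sef <- spectral_edge_frequency(psd)
    expect_gte(sum(pw[freqs <= sef]) / sum(pw), 0.95)
    oracle <- freqs[min(which(cumsum(pw) >= 0.95 * sum(pw)))]
    expect_identical(sef, oracle)
  }
})

test_that("SEF never decreases when power mass moves upward in frequency", {
  set.seed(10)
  for (i in 1:200) {
    pw <- runif(30)
    psd <- make_psd(pw, 1:30)
    s0 <- spectral_edge_frequency(psd)
    lo <- sample(1:29, 1)
    hi <- pick_one((lo + 1):30)
    moved <- pw
    shift <- runif(1, 0, pw[lo])
    moved[lo] <- moved[lo] - shift
    moved[hi] <- moved[hi] + shift
    expect_gte(spectral_edge_frequency(make_psd(moved, 1:30)), s0)
  }
})

test_that("spectral entropy hits its closed forms, bounds and invariances", {
  expect_equal(spectral_entropy(make_psd(rep(1, 30))), 1)
  expect_equal(spectral_entropy(make_psd(c(1, rep(0, 29)))), 0)
  expect_equal(spectral_entropy(make_psd(c(1, 1, rep(0, 62)))),
               log(2) / log(64))

  set.seed(11)
  for (i in 1:100) {
    pw <- runif(40)
    psd <- make_psd(pw)
    h <- spectral_entropy(psd)
    expect_gte(h, 0); expect_lte(h, 1)
    # direct-formula oracle
    p <- pw / sum(pw)
    expect_equal(h, -sum(p * log(p)) / log(40), tolerance = 1e-12)
    # scale invariance of entropy and SEF
    c_ <- runif(1, 0.01, 100)
    expect_equal(spectral_entropy(make_psd(c_ * pw)), h, tolerance = 1e-12)
    expect_identical(spectral_edge_frequency(make_psd(c_ * pw)),
                     spectral_edge_frequency(psd))
  }
})

test_that("baseline normalization maps the baseline to one and scales linearly", {
  t_s <- seq(0, 90, by = 10)
  v <- rep(4, length(t_s))
  expect_true(all(normalize_to_baseline(v, t_s, c(0, 30)) == 1))
  v2 <- c(4, 4, 4, 2, 2, 2, 8, 8, 8, 8)
  out <- normalize_to_baseline(v2, t_s, c(0, 30))
  expect_equal(out[4], 0.5)
  expect_equal(out[7], 2)
  expect_error(normalize_to_baseline(rep(0, 10), t_s, c(0, 30)), "zero")
  expect_error(normalize_to_baseline(v2, t_s, c(200, 300)), "no epochs")
})

test_that("normalized delta power rises through the simulated recovery", {
  p <- background_params(baseline_amplitude = 25, isoelectric_duration_s = 20,
                         recovery_tau_s = 60, baseline_duration_s = 30,
                         n_channels = 4,
                         channel_labels = paste0("ch", 1:4))
  rec <- generate_background(280, p, seed = 12)
  tab <- qeeg_timecourse(eeg_bandpass(rec), window_s = 10,
                         overlap_fraction = 0)
  tab <- normalize_to_baseline(tab, "start_s", c(0, 30),
                               value_col = "power_delta", by = "channel")
  # channel-mean normalized delta power: rises through the active recovery
  # phase (envelope still well below baseline), then sits near 1
  rising <- tab[tab$start_s >= 60 & tab$start_s < 160, ]
  m <- tapply(rising$power_delta_norm, rising$epoch, mean)
  m <- m[order(as.numeric(names(m)))]
  expect_true(all(diff(m) > -0.1 * diff(range(m))))
  expect_gt(mean(tail(m, 3)), mean(head(m, 3)))
  late <- tab[tab$start_s >= 200, ]
  expect_equal(mean(late$power_delta_norm), 1, tolerance = 0.25)
  # baseline epochs normalize to ~1 on average
  base <- tab[tab$start_s < 30, ]
  expect_equal(mean(base$power_delta_norm), 1, tolerance = 1e-9)
})

test_that("group qEEG summaries are identical for identical inputs", {
  rec <- eeg_bandpass(stationary_record(60, n_channels = 2, seed = 13))
  tab <- qeeg_timecourse(rec, window_s = 10)
  tables <- list(a1 = tab, a2 = tab)
  groups <- c(a1 = "A-NT", a2 = "A-H2")
  s <- qeeg_group_summary(tables, groups)
  expect_equal(s$groups$sef_hz[1], s$groups$sef_hz[2])
  expect_equal(s$groups$entropy[1], s$groups$entropy[2])
})
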