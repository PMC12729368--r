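# neoqeeg

Quantitative EEG, evoked-potential and neuropathology analysis for
preclinical neuroprotection studies in neonatal hypoxic–ischemic
encephalopathy (HIE) models.

In the translational newborn-piglet HIE paradigm this package targets,
asphyxiated animals are monitored for 48 h under three arms — untreated
normothermia (A-NT), continuous 2.1% molecular-hydrogen ventilation
(A-H2), and therapeutic hypothermia at 33.5 °C (A-TH) — with
eight-channel EEG at 256 Hz, flash visual evoked potentials (VEPs), and
post-mortem neuropathology. `neoqeeg` implements the full analysis chain
for such studies, plus a synthetic cohort generator so every stage is
testable without raw recordings:

* **EEG I/O and preprocessing** — minimal 16-bit EDF reader/writer with
  annotation sidecars, zero-phase 1–30 Hz Butterworth bandpass,
  delta/theta/alpha/beta decomposition by exact spectral partition,
  windowed epoching.
* **Quantitative EEG** — Welch PSDs with a Gaussian taper; band powers
  with baseline normalization; the 95% **spectral edge frequency**
  `SEF = min{ f : Σ_{f' ≤ f} P(f') ≥ 0.95 · Σ P }` over 1–30 Hz; and
  normalized **Shannon spectral entropy**
  `H = −Σ pᵢ log pᵢ / log N`, `pᵢ = Pᵢ / Σ P`, with suppressed
  (isoelectric, < 2 µV RMS) epochs excluded.
* **Seizure detection** — entropy-and-amplitude feature detection against
  a causal rolling background (flag when the smoothed entropy z-score
  ≤ −2 and the RMS ratio ≥ 2), run-merging, per-event dominant frequency,
  and per-animal burden/onset summaries with group incidence profiles.
* **Evoked potentials** — 100-trial grand averages (10 trains × 10
  flashes at 1 Hz), P100 latency/amplitude extraction with sub-sample
  peak interpolation, group comparison tables.
* **Neuropathology** — the 0–9 neocortical injury-pattern score
  (`3·(s−1)+t` from worst severity `s` and its frequency tertile `t` over
  40 fields), summed lobar scores, and percent-damaged-neuron metrics for
  CA1/CA3, caudate, putamen and thalamus.
* **Group statistics** — Shapiro–Wilk, Levene, one-/two-way ANOVA (Type
  II) with Tukey HSD, Kruskal–Wallis with Dunn's post hoc, and Welch
  t-tests from summary statistics (`t = (m₁−m₂)/√(sem₁²+sem₂²)`).
* **Synthetic cohorts** — 1/f^α background with isoelectric-to-recovered
  amplitude envelopes, spike-and-wave seizure injection with exact
  annotations, group-structured onset/burden distributions, VEP trial
  streams, cooling/rewarming protocol schedules, and binomial/ordinal
  pathology observations, all on a compressible 48 h timeline.

## Worked example

```r
library(neoqeeg)

# a three-arm synthetic cohort on the compressed timeline (48 h -> 360 s)
spec   <- cohort_spec(n_per_group = c(`A-NT` = 2, `A-H2` = 2, `A-TH` = 2),
                      seed = 7, timeline_compression = 1600, n_channels = 2)
bundle <- generate_cohort(spec)

seiz <- detect_cohort_seizures(bundle)
group_onset_profile(seiz$summaries)
#>   group n n_seizing incidence median_onset_h mean_burden_h sem_burden_h
#> 1  A-H2 2         2         1       34.33333      2.666667     0.000000
#> 2  A-NT 2         2         1       31.44444      7.333333     1.111111
#> 3  A-TH 2         0         0             NA      0.000000     0.000000
```

Hypothermia animals are seizure-free, hydrogen animals seize with a later
median onset than untreated animals, and per-arm mean burdens sit near the
configured group distributions (3.4 h / 3.1 h — with n = 2 per arm the
Monte-Carlo spread is still wide). The same bundle feeds the qEEG and VEP
layers:

```r
res <- run_pipeline(list(cohort = list(
         n_per_group = list(`A-NT` = 2, `A-H2` = 2, `A-TH` = 2),
         timeline_compression = 1600, n_channels = 2)),
       seed = 7, outdir = "run", force = TRUE)
res$qeeg$groups
#>   group n  sef_hz sef_sem   entropy entropy_sem
#> 1  A-H2 2 16.1250  0.8750 0.7127553  0.04008556
#> 2  A-NT 2 14.0625  0.6875 0.6582892  0.00244628
#> 3  A-TH 2  6.5625  0.3125 0.5041573  0.02788983
```

The terminal spectral edge frequency is highest under hydrogen and lowest
under hypothermia, and spectral entropy is lowest under hypothermia —
the arm-level ordering the generator encodes via its per-arm spectral
exponents. `run_pipeline()` also writes per-stage CSVs (with seed and
config-hash headers), a seizure raster and PSD/SEF figure, and a JSON
summary of the group statistics.

## Layout

* `R/` — implementation (synthetic data, EDF I/O, preprocessing, spectral
  markers, seizure detection, VEP, pathology, statistics, pipeline).
* `tests/testthat/` — unit, property and end-to-end suites; fixtures are
  generated in code.
* `vignettes/neoqeeg-methods.Rmd` — the model/methods write-up: design
  choices, generator assumptions, numerical conventions, limitations.
* `scripts/acceptance.R` — headline-number reproduction (above).
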