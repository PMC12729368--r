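---
title: "Quantitative EEG, evoked potentials and neuropathology in a neonatal HIE model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neoqeeg methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`neoqeeg` implements the analysis pipeline of a three-arm preclinical
neuroprotection study in a newborn piglet model of hypoxic–ischemic
encephalopathy (HIE): an untreated normothermic arm (A-NT, n = 6), an arm
ventilated continuously with 2.1% molecular hydrogen (A-H2, n = 8), and an
arm treated with whole-body therapeutic hypothermia (A-TH, n = 8). After a
20-minute asphyxic insult, animals are monitored for 48 h with an
eight-electrode EEG montage sampled at 256 Hz; flash visual evoked
potentials (VEPs) are recorded, and neuropathology is quantified post
mortem. Because raw recordings of such studies are rarely deposited, the
package pairs every analysis stage with a synthetic-data generator that
emulates the study conditions, so the full pipeline is exercisable and
testable from code alone.

# The quantitative EEG layer

EEG is bandpass filtered to 1–30 Hz with a 4th-order Butterworth filter
applied forward and backward (zero phase, so evoked-potential latencies are
preserved; the effective response is the squared Butterworth magnitude).
Band decomposition into delta (1–4 Hz), theta (4–8), alpha (8–13) and beta
(13–30) uses zero-phase spectral masking with half-open bands, which makes
the per-epoch band powers an exact partition of the broadband power
(Parseval); the band edges are configurable. The record is tiled into 30 s
epochs with 50% overlap by default.

Power spectral densities are estimated per channel and epoch by Welch's
method with a Gaussian taper. The taper's "kernel size" is the number of
standard deviations spanned by the window (3–5 by convention; default 4).
Welch sub-segments default to 4 s with 50% overlap; scaling compensates the
taper power so the integrated PSD matches the time-domain variance within a
few percent.

Two summary markers are derived from each PSD over the 1–30 Hz grid:

* **Spectral edge frequency (SEF):** the smallest grid frequency below
  which at least 95% of the total band power resides. It is computed on the
  discrete grid without interpolation, which keeps it reproducible and
  directly checkable against a cumulative-sum oracle.
* **Normalized spectral entropy:** the Shannon entropy of the normalized
  power spectrum, divided by `log N` over the `N` grid bins, hence unitless
  in [0, 1], base-invariant and scale-invariant. 0 indicates a single
  spectral line; 1 a flat spectrum.

Epochs whose RMS amplitude falls below 2 µV (configurable) are flagged
suppressed (isoelectric); their markers are undefined (`NA`) and excluded
from group summaries. Band-power series can be normalized to a
pre-asphyxia baseline interval (the baseline mean maps to 1 by
construction; zero baseline power is an error, reported per channel/band).

Group summaries average markers over channels within animal and then over
animals within arm. Whether such end-of-study comparisons should use the
terminal epoch or the whole-record time average is genuinely open; both
modes are implemented and the terminal epoch is the default, matching
comparisons quoted "at the 47th post-asphyxia hour".

# Seizure detection

Electrographic seizures (spike, spike-and-wave, oscillatory discharges)
concentrate spectral mass — the normalized entropy drops — while their
amplitude rises well above the ongoing background. The detector therefore
works on 1 s detection sub-epochs (decoupled from the 30 s qEEG grid) and
flags an epoch when **both**:

* the entropy, smoothed over 3 epochs, falls at least `z_thr = 1.25` robust
  standard deviations (median/MAD) below a rolling background estimate, and
* the raw epoch RMS is at least `a_thr = 2` times the rolling background
  RMS.

The rolling background is a buffer of the most recent 60 non-flagged,
non-suppressed epochs, updated causally with flagged epochs excluded, so
that long episodes cannot contaminate their own reference. Smoothing only
the entropy keeps boundaries sharp (they are governed by the unsmoothed
amplitude criterion). Flagged runs are merged across gaps of at most 2
epochs; runs shorter than 3 s are discarded (at the default timeline
compression this corresponds to a 24-minute nominal minimum, of the order
of the conventional neonatal 10 s minimum scaled to the compressed
timeline). Suppressed epochs are never flagged. Each event reports the PSD
argmax over its interval as the dominant discharge frequency.

These thresholds are the package's own plumbing, set a priori from the
expected signal-to-noise ratio: with the default amplitude gain of 4, an
injected discharge raises epoch power ~17-fold and drops entropy by several
background MADs, while the joint entropy-and-amplitude criterion makes
false positives on stationary background negligible (the test suite checks
a false-positive rate of zero events across 20 simulated seizure-free
records and burden conservation within 15%).

Per-animal summaries report total burden (hours), onset latency (hours
post-reventilation) and event count; group profiles report incidence,
median onset and mean burden ± SEM.

# Evoked potentials

Flash VEPs follow a 10 × 10 protocol: ten trains of ten 1 Hz flashes with
10 s pauses, i.e. exactly 100 trials per session. Trials are baseline
corrected over −50–0 ms and averaged pointwise; uncorrelated noise in the
average shrinks as 1/√n. The P100 is the maximum positive deflection in a
70–150 ms search window (configurable), refined by parabolic sub-sample
interpolation so that a noiseless template is recovered at its true
latency rather than at the nearest 3.9 ms grid point; amplitude is the
peak relative to the pre-stimulus baseline. Windows without a positive
deflection yield an absent-response flag. The within-animal grand average
is computed first and group comparisons are run on per-animal measures;
this interpretation of "grand mean averages" (within-animal, then across
animals) is a documented choice.

# Neuropathology

Subcortical and hippocampal regions (CA1, CA3, caudate, putamen, thalamus)
are quantified as the percentage of damaged neurons out of the total count.
Neocortical regions are scored 0–9 from 40 microscopy fields using the
four-level ordinal severity scale none < scattered < grouped/laminar <
panlaminar. The published scale fixes the endpoints and the drivers (worst
severity and its frequency) but not the intermediate table; the package's
concrete mapping is `3·(s − 1) + t` where `s` is the worst severity level
present and `t` the tertile of its frequency, which is monotone in both
drivers, reaches 9 only for panlaminar injury in more than two thirds of
fields, and can be replaced by a user-supplied lookup table. Four lobar
scores (frontal, parietal, temporal, occipital) are summed per animal by
default; summing the eight named gyri instead is supported by passing a
different region list.

# Statistics

The statistical layer mirrors standard practice in this literature:
Shapiro–Wilk for normality, Levene (mean-centered by default) for variance
homogeneity, one-way ANOVA with Tukey HSD for group comparisons of qEEG
markers, two-way treatment × time ANOVA (Type II sums of squares, so
unbalanced layouts are handled; Tukey HSD on marginal means) for
longitudinal measures, and Kruskal–Wallis with Dunn's multiple comparisons
for the non-normal pathology percentages. Dunn's z statistics are computed
from the pooled mean ranks with tie correction; unadjusted two-sided
p-values are reported by default (the common convention for "Dunn's
multiple comparisons"), with Bonferroni/Holm corrections available. A Welch
t-test from summary statistics (means, SEMs, group sizes, with
Welch–Satterthwaite degrees of freedom) supports comparisons where only
printed summaries exist. Time is treated as a between-measurements factor
in the two-way layout; a repeated-measures treatment is deliberately out of
scope and this divergence risk is documented here.

# The synthetic cohort generator

The generator defines the study conditions the tests run under; its
defaults are fixed from the study design and are configuration, not tuning
knobs.

**Background EEG** is amplitude-modulated 1/f^α Gaussian noise band-limited
to the analysis range: asphyxia leaves a near-isoelectric hour (floor
1 µV RMS), after which the RMS envelope recovers exponentially (time
constant 8 h nominal) toward a 25 µV baseline. The per-arm spectral
exponents (α = 2.0 A-NT, 1.6 A-H2, 2.6 A-TH) encode the study's terminal
ordering — a flatter, more complex recovered spectrum under hydrogen, a
steeper, more suppressed one under hypothermia — while low frequencies
dominate in all arms. Burst suppression is not modeled.

**Seizures** are generalized spike-and-wave trains: a biphasic 20 ms spike
followed by a slow half-sine wave filling the rest of the cycle, repeated
at 10 Hz, unit-normalized and scaled to 4× the local background RMS. The
per-arm structure follows the reported incidence and burden: seizure
probability 5/6 (A-NT), 1 (A-H2) and 0 (A-TH); onset windows 24–34 h
post-reventilation for A-NT and 30–44 h for A-H2 (delayed onset); and
per-animal total burden drawn from Gamma distributions with mean 3.4 h
(SD 1.0·√6 h) and 3.1 h (SD 0.7·√8 h) respectively — the SDs recover the
reported SEMs at the reported group sizes. Episode counts (1 + Poisson(2))
and the Dirichlet split of burden into episodes are assumptions: per-animal
episode statistics are not reported, only a single ~13-minute example, so
these are configurable and flagged as such. Whether the reported burden
means average over all animals or only seizure-bearing ones is ambiguous
(one A-NT animal was seizure-free); burden parameters therefore describe
the distribution an affected animal draws from, and the acceptance analysis
simulates every animal with a drawn burden, matching its stated setup.
Pharmacological seizure rescue, which truncates natural episodes in vivo,
is not modeled, so burden comparisons are distribution-level only.

**Timeline compression.** Simulating 48 h × 8 channels × 256 Hz is
needlessly heavy for testing; the generator accepts a compression factor
(default 480: the 48 h observation becomes 360 s of signal) and all burden
and onset outputs are rescaled to nominal hours. Signal content
(1–30 Hz background, 10 Hz discharges) lives in simulated time and is
unchanged; only envelopes, schedules and episode durations compress. The
qEEG window shrinks to the compressed baseline span in the pipeline
(`max(4 s, min(30 s, baseline))`), and detection runs on 1 s sub-epochs,
which keeps nominal burden resolution at 8 minutes per epoch at the default
compression. Analyses of uncompressed data use the same code paths with
compression 1.

**VEPs** are the deterministic P100 template (Gaussian peak, 15 ms sigma,
10 µV) plus white noise (5 µV). Latency offsets of 0, −4 and −15 ms for
A-NT, A-H2 and A-TH encode the reported pattern of a significantly shorter
latency under hypothermia only, with amplitudes equal across arms (the
reported amplitude null).

**Pathology** draws subcortical damaged counts binomially (200 neurons per
region) with probabilities 0.95/0.25/0.25 (A-NT/A-H2/A-TH) in the thalamus
— near-complete untreated injury, strongly attenuated under both treatments
— and low group-independent probabilities (0.12–0.15) elsewhere; cortical
field severities are Dirichlet-categorical over the ordinal scale with
group-similar base frequencies, so summed cortical scores do not separate
the arms.

**Protocol schedules** are piecewise linear: normothermic arms constant at
38.5 °C; the hypothermia arm reaches 33.5 °C 47.5 min after asphyxia, holds
until hour 37, rewarms at 0.5 °C/h for 10 h and stays at 38.5 °C for the
final hour.

Cohort generation is deterministic in `(spec, seed)`: per-animal seeds are
drawn once from the master seed, and two calls with the same spec are
identical object-for-object.

## What the generator does and does not establish

Passing tests on synthetic cohorts show that the pipeline recovers the
parameters and orderings it was configured with — burden means within
Monte-Carlo tolerance, onset delay, arm-specific spectral orderings,
near-complete thalamic injury — through the same code paths a real dataset
would take. They do not validate the detector against human-scored clinical
seizures, nor the generative model against real piglet EEG (real background
is nonstationary beyond an amplitude envelope, contains artifacts,
state transitions and focal events, none of which are modeled). Artifact
rejection and re-referencing are out of scope.

# Numerical choices and degenerate inputs

* All-zero epochs yield a valid all-zero PSD flagged suppressed; SEF and
  entropy return `NA` sentinels rather than errors, and summaries exclude
  them.
* SEF uses the first grid bin reaching the edge fraction (no
  interpolation); entropy uses natural logs normalized by `log N`.
* The EDF writer stores one data record spanning the whole signal with a
  per-channel symmetric physical range inflated 0.1% above the sample
  maximum, so round trips stay within half a 16-bit quantization step;
  annotations travel in a sidecar CSV.
* Episode placement enforces a minimum 4 s (simulated) episode length and
  6 s inter-episode gap; Dirichlet fragments below the minimum are merged
  into the largest episode so annotated totals equal drawn burdens exactly.
* The detection background buffer needs 15 epochs of warm-up before any
  flagging; records shorter than that produce no events.
* Degenerate statistics: identical groups give F = 0/H = 0 with p = 1;
  constant groups give a zero Levene statistic; a zero t gives p = 1
  exactly.

# Problem sizes used by the shipped analyses

The test suite and the acceptance script run entirely on synthetic data at
the default compression: burden recovery uses 12 cohorts per arm (72 A-NT
and 96 A-H2 animal-records of 367 s each), calibration checks use 100–2000
replicates, and the property suites use a few hundred randomized cases per
invariant. These sizes are chosen so the whole suite completes in minutes
on one CPU while keeping Monte-Carlo error well inside the asserted
tolerances.
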