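---
title: "Slow-oscillation analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-oscillation analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowwave)
```

## The problem

Under deep anesthesia and slow-wave sleep the neocortex settles into the
slow oscillation (SO): a ~1 Hz alternation between *Up states* (sustained
population firing with gamma-band content) and near-silent *Down states*.
The statistics of this alternation — state durations and their regularity,
Up-state firing rate and spectral content, the spatial propagation of the
Down-to-Up wavefront, and the correlation structure across an electrode
array — are a sensitive readout of the underlying cortical circuit, and are
altered in mouse models of neurodevelopmental disorders such as
Williams–Beuren syndrome.

`slowwave` implements the full analysis chain for multichannel LFP
recordings of this regime, plus a statistical generator of such recordings
with known ground truth, so that every stage can be validated end to end
without access to in-vivo data.

## MUA estimation

Population firing near each electrode is estimated from the high-frequency
content of the LFP spectrum. A short-time Fourier estimate (Hann taper,
default window 5 ms, step 1 ms) is computed per channel; each frequency bin
in the 200–1500 Hz band is divided by its own time-average over the whole
recording, and the normalized bins are averaged across the band. At these
frequencies the normalized spectral density is proportional to aggregate
nearby spiking, and the per-bin normalization cancels the electrode's
linear frequency response and any overall gain. Two consequences are exact
by construction and asserted in the tests:

* **gain invariance** — multiplying a channel by any constant leaves its
  MUA trace unchanged to machine precision;
* **unit mean** — each channel's MUA estimate has whole-recording average 1,
  so only relative quantities (e.g. the Up/Down ratio) are comparable across
  recordings.

The window/step and the band are the main free parameters and are exposed
in `pipeline_config()`. Band averaging is done on normalized *power* (not
amplitude), recorded in the output's `averaging` field; with this
convention a high-band amplitude ratio *r* between states appears as an
MUA ratio *r²*.

## Up/Down detection and SO metrics

Detection thresholds the logarithmically scaled MUA. The log-MUA
distribution of a bistable recording is bimodal; `choose_threshold()`
places the threshold at the minimum of a kernel-smoothed histogram between
the two largest modes, falling back to the 10th/90th-percentile midpoint
when unimodal. Before thresholding, the log MUA is smoothed with a 20 ms
Gaussian kernel (configurable): the raw 5 ms spectral estimates fluctuate
with ~chi-square scatter, and without smoothing the histogram modes blur.
Runs shorter than 50 ms are merged into the flanking state; the mean state
durations are an order of magnitude longer, so this refractory rule only
absorbs glitches. Alternation and tiling of the analyzed span are invariants
asserted on every output.

Metric conventions, fixed for reproducibility:

* the SO frequency is the mean over cycles of the *inverse complete
  Up-to-Down cycle duration* (not the inverse mean cycle); the two differ
  under variability, and the per-cycle definition is recorded in the output;
* coefficients of variation use the population (divide-by-N) standard
  deviation;
* intervals truncated by the recording edges are excluded from duration
  statistics;
* the Down-to-Up transition slope is a least-squares fit of log MUA around
  each crossing reported as an angle, which is meaningless without an axis
  convention: time is measured in units of the mean cycle duration and log
  MUA in units of the Up–Down level span. The convention is explicit in
  `upward_slope()` and configurable.
* Up-state band powers (alpha 8–12, beta 15–32, gamma 32–100 Hz) come from
  a Welch estimate over Up epochs (0.25 s Hann segments, 50% overlap,
  periodograms pooled across epochs); epochs shorter than a segment are
  dropped. No MUA normalization is applied here, so powers scale with gain².

## Wave reconstruction and propagation

Down-to-Up transitions that occur across channels within 250 ms of a wave's
running mean time are merged into one wave; a wave is retained only when a
strict majority of channels participates (both parameters configurable).
Lags are expressed relative to each wave's mean time, so they are zero-mean
per wave, and channels missing from a wave stay missing — they are never
imputed as zero lag.

Each wave's lag field T(x, y) is interpolated with an **exact thin-plate
spline** (radial basis r² log r plus an affine term, zero smoothing
penalty): the surface passes through every observed lag to machine
precision and reproduces affine (planar-wave) fields exactly. The local
propagation speed is

V(x, y) = 1 / √((∂T/∂x)² + (∂T/∂y)²),

evaluated by central differences on the interior of a regular grid spanning
the array. Where the lag surface is flat the speed diverges, so gradient
magnitudes below 10⁻⁴ s/mm (speeds above 10 m/s) are masked; the summary
speed is the median over the valid interior, averaged over waves per
experiment.

Pattern diversity is quantified by projecting the wave-by-channel lag
matrix onto its first two principal components and computing the Shannon
entropy (base 2) of an 8×8 occupancy histogram spanning the data. The value
depends on the bin count, which is therefore reported alongside; waves with
missing channels are excluded from the PCA by default (mean imputation is
available behind a flag). Identical waves give 0 bits and k equally
occupied, well-separated clusters give log₂ k bits, both exactly.

## Functional connectivity

Wideband analysis downsamples the LFP to 250 Hz (anti-alias zero-phase
Butterworth, integer decimation); band-specific analyses additionally apply
a forward–backward Butterworth bandpass (order 4 each way, zero net phase)
and decimate to 4× the band top. Pairwise Pearson correlation gives W;
distances are D = 1/W. Negative or near-zero correlations make the
reciprocal meaningless as a distance, so edges with W ≤ 0.05 (configurable
floor) are treated as absent for both community detection and path length —
the unreachable-pair fraction is reported alongside L.

Community structure and modularity Q come from the Louvain heuristic
(20 restarts, best Q kept, seed recorded); characteristic path length L is
the mean Dijkstra shortest-path distance over reachable ordered pairs. Both
are cross-checked in the test suite against brute-force oracles (exhaustive
partition enumeration; Floyd–Warshall). Functional complexity summarizes
how broadly correlation magnitudes are distributed: with p the histogram of
upper-triangle |r| over M = 20 equal bins on [0, 1],

C = 1 − M/(2(M−1)) · Σ |p − 1/M|,

which is 0 for a delta-like distribution and 1 for exactly uniform
occupancy.

## The synthetic generator

The generator is statistical, not biophysical: it produces exactly the
features the analysis measures, each under independent control.

* **State sequence** — alternating Up/Down durations drawn from gamma
  distributions parameterized by mean and CV (positive support, CV directly
  controllable; the in-vivo duration distribution is not known precisely,
  and the analysis is insensitive to the family).
* **Slow component** — a two-level waveform (Up level negative by the depth
  convention; polarity configurable) smoothed with a 20 ms Gaussian edge.
* **Gamma** — a sinusoid (default 60 Hz) present only during Up states with
  per-state random phase.
* **High band** — 200–1500 Hz bandpassed Gaussian noise whose standard
  deviation is `hf_amp ×` a state-dependent rate parameter; the MUA
  estimator is sensitive only to band power, which this controls exactly, so
  no point-process spiking model is needed.
* **Background** — power-law noise with spectral slope 2 by default.
  Cortical LFP spectra fall off steeply (≈1/f²–1/f³) above a few hertz; the
  steep default also keeps the background out of the MUA band while letting
  it dominate low frequencies, which is what makes wideband correlations
  spread over a realistic range instead of saturating.
* **Propagation** — each Down-to-Up transition reaches channel i with lag
  distance/speed along a planar direction (waves cycle through a
  configurable direction set, default two opposed directions, mirroring the
  stereotyped alternation of observed patterns) or radially from an origin;
  lags are recentred to zero mean per wave and recorded as ground truth.
* **Correlation structure** — each channel's broadband background is mixed
  with a community-level common signal (`sqrt(1−f)·own + sqrt(f)·common`),
  where the common signal is a phase-randomized surrogate of a member
  channel: it has the members' spectrum but is asymptotically uncorrelated
  with them, so previously independent channels end up with within-community
  correlation ≈ f. A second, global mixing stage couples all channels. The
  slow component stays out of the mixing so ground-truth state timing is
  untouched.

### Cohort presets

`cohort_preset("WT")` and `cohort_preset("WBS")` encode the two study
groups. Durations and CVs are the respective group means (Up 0.39/0.40 s,
Down 0.82/0.89 s, CV Up 0.51/0.63, CV Down 0.49/0.60). High-band rates are
set so the Up/Down band-power ratio equals each group's relative firing
rates (0.69/0.20 and 0.53/0.24); gamma amplitudes (35 and 28.6 µV) place
Up-state gamma density near 9 vs 6 µV²/Hz. The syndrome-model-like preset
carries a *larger global common-signal fraction* (0.35 vs 0.10; the
within-community fraction is 0.35 in both): raising the shared signal
everywhere shifts the whole correlation distribution upward and, because it
raises between-community correlations relative to within, lowers modularity
and shortens weighted path lengths — the reported connectivity phenotype.
Raising only the within-community fraction would instead *increase*
modularity, which is why the global stage exists. Per-animal parameters are
jittered by 5% multiplicative lognormal noise (seeded per animal) to create
between-animal variance for group statistics.

Absolute wave speed has no quantitative anchor in the study conditions;
presets use 20 mm/s, in the 10–40 mm/s range typical of cortical slow
waves, and the recovery tests sweep 5–40 mm/s.

### What the generator does not emulate

Passing the recovery tests shows the analysis is correct under the
generator's assumptions, not that it is robust to everything real data
contains: no movement or line-noise artifacts, no electrode drift or broken
channels, no waveform asymmetry between Down-to-Up and Up-to-Down
transitions, no spatially graded amplitudes, no true spike waveforms, and
wave patterns are drawn from a small stereotyped set. Conclusions about
robustness to those features require real recordings.

## Numerical and design choices

* **Container format** — recordings round-trip through a single serialized
  RDS container (`save_recording()`/`load_recording()`), bit-exact for all
  arrays, re-validated on load. Geometry is CSV (`channel,x,y`);
  coordinates are normalized to millimetres on load (micrometre files are
  auto-detected by their pitch). Configuration is YAML over validated
  defaults.
* **Degenerate inputs** — constant log MUA refuses thresholding ("no
  bistability"); a flat lag field refuses a speed map; an all-Up
  segmentation refuses a relative firing rate; zero-variance channels
  refuse correlation. Errors name the offending channel or field.
* **Ties and floors** — `log_mua` is floored at 10⁻³ before the log (silent
  Down windows can yield near-zero estimates); the correlation-to-distance
  floor is 0.05; the speed-map gradient floor is 10⁻⁴ s/mm.
* **Exact small-sample statistics** — the Mann–Whitney U test uses the
  exact null distribution for small untied samples and the tie-corrected
  normal approximation otherwise; SEM uses the divide-by-(n−1) standard
  deviation; tests are two-sided with no multiple-testing correction by
  default (a Holm option exists), matching the per-test reporting convention
  of the study design this pipeline serves.

## Problem sizes used in validation

The packaged tests and the acceptance script run entirely on synthetic
data at desk scale, chosen to balance statistical resolution against
runtime: duration-recovery cohorts use eight 120 s, 16-channel recordings
at 5 kHz; group-contrast cohorts use 9 + 8 animals with 60 s four-channel
depth recordings (the group table draws on the four mid-depth channels) and
30 s 32-channel surface recordings; the firing-rate power check repeats the
9-vs-8 contrast over ten seed sets at 40 s per recording. Wave-speed and
graph-metric checks run on exact constructed inputs and need no
simulation length at all.

## A minimal session

```{r example, eval = FALSE}
cfg <- synth_config(n_channels = 32, duration = 60, wave_mode = "planar",
                    wave_speed = 20, shared_fraction = 0.3,
                    module_assignment = rep(1:2, each = 16))
sim <- simulate_recording(cfg, seed = 1)

mua <- compute_mua(sim$recording)          # normalized firing-rate estimate
seg <- segment_recording(mua)              # Up/Down intervals per channel
so_metrics(seg, mua, sim$recording)        # durations, CVs, band powers...
analyze_waves(seg, cfg$geometry)           # lags, speed maps, entropy
connectivity_graph(sim$recording, seed = 1)  # W, Q, L, complexity
```
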