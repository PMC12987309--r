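---
title: "Methods: extracting and analysing SKNA complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting and analysing SKNA complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sknatools)
```

## Background

Skin sympathetic nerve activity (SKNA) is a non-invasive surrogate of
sympathetic outflow obtained from ordinary ECG electrodes sampled at high
rates (10 kHz here). Postganglionic discharges appear as intermittent,
band-limited (roughly 150–1000 Hz) bursts riding on the much larger, slower
ECG waveform. `sknatools` implements the full analysis chain for such
recordings: preprocessing, extraction of two SKNA envelope representations,
segment-level complexity indices, and the mixed-model / ROC statistical
layer, together with a synthetic-data generator so that every stage can be
validated without access to human recordings.

## Signal model and the synthetic generator

The generator produces, per subject and condition,

\[
x(t) = \mathrm{ECG}(t) + a_s\, g_c\, A \sum_b w_b(t)\, \eta(t) +
\sigma_0\, \eta_0(t) + \textstyle\sum_k A_k \sin(2\pi f_k t),
\]

where `ECG(t)` is a template train of Gaussian P-QRS-T waves (R amplitude
about 1 mV, widths ≥ 8 ms so essentially all ECG energy lies below 150 Hz)
with small cycle-length jitter; \(w_b\) are Hann envelopes at
homogeneous-Poisson burst times with gamma-distributed durations;
\(\eta,\eta_0\) are unit-variance 150–1000 Hz Gaussian carriers; \(g_c\) is
the per-condition amplitude gain; \(a_s \sim \mathrm{lognormal}(0,\sigma_a)\)
is the per-subject multiplicative intercept; and the final sum contains
optional narrowband interference tones.

Default conditions: 20 subjects, a baseline (VAS fixed at 0) and an
activation condition with amplitude gain 2.5 and rate gain 2, burst rate
0.5 /s, mean burst duration 0.35 s, burst amplitude 6 µV over 1 µV
background, subject intercept SD 0.3, and canned 20 s / 5 s segment layouts
for Valsalva-style and thermal-grill-style protocols
(`defaultStudyConfig("vm")` / `"tg"`). VAS ratings are categorical draws per condition so that the
clinical grouping boundaries (0, 3, 4) are exercised. These defaults were
fixed once as a realistic activation contrast for this class of experiment
and are not tuned per analysis.

What the generator deliberately does **not** model: ECG pathology,
respiration and baroreflex coupling, electrode-motion artifacts and EMG
contamination. Passing tests therefore demonstrate that the pipeline
recovers the structure this model encodes (burst-amplitude contrasts,
subject heterogeneity, interference), not that it is robust to every
artifact class of real skin recordings.

Implementation notes. The burst component is a single continuous
band-limited carrier multiplied by the summed Hann envelopes; this makes
the burst channel *exactly* linear in the amplitude parameter at a fixed
seed (a property the tests assert) and keeps generation fast. Overlapping
bursts share the carrier, which is physiologically innocuous (burst
superposition remains band-limited and bursty).

## Preprocessing

* **Resampling 10 kHz → 4 kHz** uses a fixed up = 2 / down = 5 polyphase
  scheme: zero-stuffing, a Kaiser-window anti-aliasing lowpass designed at
  the smaller Nyquist frequency (70 dB design target), delay-compensated
  single-pass application, then decimation. Each polyphase branch is
  normalized to unit DC gain, so a constant input is reproduced to machine
  precision rather than to passband-ripple precision.
* **FIR design** (`designFir`) uses the Kaiser order/β rule for the
  requested stopband attenuation (default 60 dB) and transition width
  (default 50 Hz — narrow enough to keep the SKNA band intact, wide enough
  for moderate order); the realized response is then measured on a frequency
  grid and the order grown until the realized attenuation actually meets the
  target, which the `FirSpec` records.
* **Zero-phase filtering** is forward–backward with odd-reflection padding
  (3× filter length) so edge transients decay outside retained samples; the
  magnitude response is squared relative to a single pass.
* **Interference removal**: mains-like contamination is conventionally
  identified by visual PSD inspection, and only peaks present in *both*
  baseline and task recordings are treated as condition-independent
  artifacts. `detectInterference` automates this:
  Welch PSD (Hann, 50 % overlap), peak prominence in dB over a
  running-median baseline, default threshold 12 dB, and the
  every-condition intersection rule. Removal uses second-order IIR notches
  (Q = 30, −3 dB bandwidth f₀/Q) applied zero-phase; a manual frequency
  list in the configuration overrides detection.

## The two SKNA representations

**iSKNA** (neuECG): 500–1000 Hz Kaiser bandpass (zero-phase), full-wave
rectification, 100 ms moving average. For a steady tone of amplitude A the
envelope settles at the rectified-sine mean 2A/π, which the tests use as an
analytic anchor.

**TVSKNA**: 150 Hz highpass, VFCDM decomposition at 160 Hz component
spacing, summation of the components whose centers lie in 160–1120 Hz
(7 components at 4 kHz), Hilbert instantaneous amplitude of the summed
reconstruction, 100 ms moving average. The 1120 Hz upper edge comes from
the discrete 160 Hz component grid approximating the 150–1000 Hz SKNA band.

VFCDM details: stage one demodulates at fixed centers k·160 Hz and low-pass
filters at 80 Hz with a windowed-sinc whose half-amplitude point sits at the
cutoff, so adjacent subbands tile the spectrum and the component sum
reconstructs the band-limited input (measured relative RMSE ≈ 0.3 % on
band-limited noise). Stage two estimates each subband's instantaneous
frequency from the analytic phase (smoothed over 50 ms, clamped to the
subband), re-demodulates the *component* along that track and low-pass
filters again. The second-stage bandwidth defaults to 0.75 × spacing
(120 Hz): measured reconstruction error on 160–1120 Hz noise is 58 % at
spacing/4, 20 % at spacing/2 and 3.9 % at 0.75 × spacing, so the wider
setting is the only one that preserves the representation's defining
reconstruction property; the sharpening still comes from the variable
center-frequency tracking. Both bandwidths are arguments for users who want
the narrower conventions.

The 100 ms smoothing window is *centered* with reflection padding. Causal
vs centered is not fixed by the envelope's definition; centered smoothing
preserves burst-peak timing, which matters when segments are aligned to
event onsets.

## Complexity indices

All indices are computed per segment, per signal kind, with no
cross-subject normalization (between-subject variability is handled by the
mixed model instead).

* **ApEn / SampEn**: Chebyshev distance, embedding m (default 2), tolerance
  r = r_coeff × SD of *that* segment (default 0.2), self-matches included
  (ApEn) or excluded (SampEn, hence non-negative). SampEn uses the N − m
  templates valid at both lengths. Degenerate cases are conventions, not
  errors: a constant segment gives ApEn 0 with a flag, and SampEn returns
  flagged `NA` when no template pairs match. The kernels are O(N²) C++
  loops with early distance cutoff; a pure-R brute-force transcription of
  the definitions serves as the correctness oracle (agreement < 1e−9 over
  the full m ∈ {2,3} × r ∈ {0.15, 0.20, 0.25} grid). Because r is tied to
  the segment SD, both entropies are exactly invariant to affine scaling.
* **Hjorth mobility / complexity** use unscaled first differences, making
  them dimensionless and sampling-rate-consistent within a study; activity
  is not reported separately because it duplicates the SD benchmark. Useful
  anchors: a sinusoid at frequency f has mobility 2 sin(πf/fs) and
  complexity 1; i.i.d. noise has mobility √2 and complexity √1.5.
* **Katz fractal dimension** treats the waveform as a planar curve with
  unit abscissa steps; n is the number of *steps* (N − 1), following the
  original formulation — the alternative "number of points" reading differs
  by < 0.01 % at 20 000-sample segments and is available via an argument.
  A straight line gives exactly 1.
* **SD** uses the unbiased (n − 1) denominator.

## Statistical layer

Segments are the unit of analysis; subject enters as a random intercept:
`value ~ condition + (1 | subject)`, REML, with Satterthwaite degrees of
freedom. Random slopes are deliberately not offered — with few repeated
observations per subject they routinely produce singular fits, and the
random-intercept model is retained as the stable specification (singular
fits are flagged, not refitted). Variance components on balanced designs
match the closed-form ANOVA estimators to 1e−6, and with one observation
per subject the fixed effects collapse to OLS — both are regression-tested.

Post hoc machinery mirrors common practice: Tukey-adjusted
estimated-marginal-mean contrasts, gated on the omnibus ANOVA at 0.05; no
additional global correction across indices (they are interpreted jointly,
not individually); BH-FDR is applied where many parameter-grid contrasts
are compared. Cohen's d standardizes the EMM difference by
\(\sqrt{\sigma^2_{subject} + \sigma^2_{residual}}\) (the model's total SD);
its CI divides the contrast's Wald interval by the same denominator. This
denominator choice is explicit and swappable; the CI ignores the sampling
noise of the denominator, which costs a few coverage points (measured
~91–93 % at nominal 95 % in the recovery simulations — inside the accepted
90–99 % band).

ROC analysis is segment-level and pooled across subjects (so CIs are
slightly optimistic — inference belongs to the mixed model). AUC is the
Mann–Whitney statistic with ties counted ½; the variance, CI and the paired
two-curve test use DeLong placement values. Class 1 is assigned to the
condition with the higher mean index value, so AUC ≥ 0.5 corresponds to the
expected direction even for indices that *decrease* under activation; the
orientation is always recorded in the result.

Repeated-measures correlation (association between VAS and an index across
repeated segments) is the common within-subject correlation from an
analysis of covariance with subject as a factor; the CI uses the Fisher z
transform on the error degrees of freedom (N − #subjects − 1), which
reduces exactly to the Pearson CI for a single subject.

## Numerical conventions and degenerate inputs

* Invalid arguments (bands at/above Nyquist, events outside a recording,
  overlapping events, out-of-range VAS/DAS or p-values) signal errors;
  statistically *undefined* results (SampEn with no matches, zero-variance
  segments, insufficient degrees of freedom) return flagged `NA` instead.
* All simulation entry points take an integer seed and are bit-reproducible
  from (configuration, seed); the pipeline embeds both in its report.
* FIR designs are cached by (kind, edges, fs, attenuation, transition);
  long convolutions use overlap–save FFT filtering with power-of-two blocks.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script validate: entropy-oracle agreement
on 20 signals of 300–1000 samples over the full parameter grid; Hjorth
limits at 10⁵ samples; filter contracts at 4 kHz with 10-second signals;
VFCDM reconstruction on 15 s of band-limited noise; effect-size recovery
over 200 simulated studies of 40 subjects × 10 segments; DeLong test size
over 2000 null replicates at n = 100; and 20 end-to-end synthetic studies
of 20 subjects (1 baseline + 3 activation segments of 5 s each, amplitude
gain 2.5) in which the iSKNA-SD AUC and the mixed-model condition test must
discriminate. Entropy on full-length 20 s segments (80 000 samples) is
supported but takes tens of seconds per segment per index; the shipped
checks use shorter segments where the property under test does not depend
on segment length.

## Known limitations

* The generator's burst statistics (Poisson arrivals, gamma durations,
  log-normal subject intercepts) are conventions; real SKNA burst-rate and
  amplitude distributions are not characterized well enough to calibrate
  against.
* EMG/motion contamination is not modelled, and no automatic artifact
  rejection is attempted — interference handling is limited to narrowband
  tones.
* EDF input is not supported; recordings travel as two-column CSV with a
  side-car annotation CSV, which is lossless for this purpose.
* Segment-level ROC pools non-independent segments; treat those CIs as
  descriptive.
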