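---
title: "Methods: single-lead ECG denoising, beat detection and rhythm screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-lead ECG denoising, beat detection and rhythm screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgrhythm)
```

`ecgrhythm` analyses single-lead ECG recordings of the kind produced by
handheld home devices: short sessions, dry electrodes, substantial noise,
and no second channel to lean on. This vignette explains the models and
procedures the package implements, the parameters that matter, the
numerical decisions taken where the design was open, and what the synthetic
test bed does and does not establish about real recordings.

## The signal model and the noise classes

A record is a voltage series in millivolts with a known sampling rate
(`fs`, 250 Hz default for synthetic data; the rate is always an explicit
input because device CSV exports do not embed it). Four noise classes are
assumed on top of the cardiac signal:

* **baseline wander** below 0.5 Hz, from respiration, movement and
  electrode impedance;
* **powerline interference** at 50 Hz (European mains);
* **muscle (EMG) noise**, broadband above roughly 20 Hz;
* **large-amplitude noise**: saturation or electrode-slip artifacts far
  larger than the ECG, arriving in bursts;

plus a constant DC offset on the order of 16 mV from the dry-electrode
front end.

## The noise-adequation bench

Four stages run in fixed order; every stage is length-preserving.

**Low-pass, 75 Hz.** A 4th-order Butterworth applied forward-backward
(zero phase) so QRS morphology is not skewed — the filter realisation is a
package choice guided by the requirement to preserve morphology; the
conservative cut-off keeps the full diagnostic band, at the price of only
moderate EMG suppression. The signal mean is removed before filtering and
restored after, so DC passes through this stage exactly; edge transients
are suppressed by odd-reflection padding (one second at each end).

**Baseline spline.** The drift estimate is a natural cubic spline through
knots at the temporal centre of consecutive 1 s segments, each knot's
ordinate being the segment's mean voltage; the spline is subtracted. The
1 s knot spacing (configurable) is long relative to a beat, so knots track
sub-0.5 Hz drift rather than QRS energy, yet short enough to follow
realistic wander. A natural spline reproduces constants and straight lines
exactly, so a clean record is unchanged; the stage also removes the DC
offset. Records shorter than four knots fall back to mean subtraction.

**Notch, 50 Hz.** A second-order IIR notch (RBJ biquad, Q = 30) applied
forward-backward. The biquad places a spectral zero at the mains frequency:
measured attenuation exceeds 80 dB at 50 Hz while a 5 Hz tone passes within
2%. Q = 30 keeps the -3 dB bandwidth under 2 Hz, so neighbouring ECG energy
is spared.

**Large-amplitude-noise (LAN) exclusion.** The signal is divided into
0.5 s blocks; each block's standard deviation is compared against
mean + 2·sd of the ten *preceding* block deviations (a strictly causal
window) and flagged when strictly above. Flagged blocks are *masked*, not
zero-filled — zero-filling would create artificial edges that mimic QRS
complexes. Consequences of the strict inequality: an all-tied history (a
flatline) flags nothing, and the first ten blocks, having no history, are
never flagged. Records shorter than eleven blocks skip the stage with a
warning.

## Beat detection

The detector follows the Pan–Tompkins architecture with a five-tap
derivative feature. The pre-squaring filter is

$$y[n] = \tfrac{1}{10}\left(-2x[n-2] - x[n-1] + x[n+1] + 2x[n+2]\right),$$

implemented as a centred FIR (the two-sample advance is legitimate offline,
and alignment keeps feature peaks on the input time base; the first and
last two samples are zeroed). The feature is $y[n]^2$: nonnegative, exactly
DC-rejecting (the coefficients sum to zero), and invariant to sign
inversion of the ECG — which is what lets the detector localise inverted
(extrasystole-like) complexes.

Zones are maximal runs where the feature strictly exceeds
mean + c·sd (c = 1 by default, exposed as `zone_threshold_c`; the threshold
scales with the feature, so detection positions are invariant to amplitude
scaling of the record). One subtlety: the squared derivative is exactly
zero at the R crest, so a literal run decomposition splits each QRS into
its two flanks. Runs separated by less than 50 ms (`merge_gap_s`) are
therefore merged — 50 ms is far below any physiological beat spacing and
comfortably above the crest gap, and plays the role of the moving-window
integration in classical Pan–Tompkins. Zones touching masked samples are
discarded entirely.

Each zone is refined to the sample of maximum *absolute* filtered
amplitude, then candidates pass a greedy 0.2 s refractory filter: of two
candidates closer than the refractory period, the one with the larger
feature value — the stronger QRS evidence — survives. The 0.2 s default is
the physiological ventricular refractory period; the threshold constant and
refractory period are both configurable because neither is fixed by theory.

## Rhythm warnings and AF screening

From the beat series, RR[n] intervals and their first difference dRR[n]
are formed; intervals spanning masked samples are excluded from statistics.
Two warnings use strict printed rules: a *rhythm alteration* flags
|RR[n] − RR[n−1]| / RR[n−1] > 0.30, and a *pause* flags RR[n] > 3 s.

AF screening works on consecutive non-overlapping 75 s segments (the
operating segment length of the screening approach the package implements).
Within a segment:

1. **Outlier fencing.** An interval is discarded when it falls outside
   [P25 − 3·IQR, P75 + 3·IQR] of the segment's RR distribution, or outside
   the analogous fence of the dRR distribution. Boundary values are kept,
   which makes the degenerate IQR = 0 case (metronomic rhythm) flag
   nothing. A `fence_rule = "literal"` switch keeps only the upper fence on
   each axis — the conjunction-of-">" form reduces to that — and exists for
   fidelity comparisons; the two-sided rule is the default because a
   one-sided fence cannot remove short-interval artifacts.
   Percentiles use R's default (type 7) quantile definition.
2. **Discretized Lorenz–Poincaré diagram.** Remaining (RR, dRR) points are
   binned on an equally-spaced grid. The grid spans *fixed* physiologic
   ranges — RR ∈ [0.24, 2.0] s, dRR ∈ [−0.88, 0.88] s, 30 bins per axis —
   rather than the data range, so the index is comparable across segments
   and a constant rhythm occupies one bin instead of spuriously filling an
   auto-scaled grid; out-of-range points land in the nearest edge bin so
   every point is counted exactly once. The RR range covers 30–250 bpm; the
   dRR range is ± half the RR span.
3. **Disorganization index.** The fraction of bins that are "full"
   (occupancy ≥ `af_full_bin_min_count`, default 1 — "full" is otherwise
   undefined, and ≥ 1 is the most sensitive choice). The index lies in
   [0, 1] and grows with rhythm irregularity.

A segment is flagged AF when its index strictly exceeds `af_threshold`.
The default, 0.0406, was derived once by maximising Youden's J over 200
sinus and 200 AF-like seeded synthetic 75 s segments
(`inst/scripts/derive_af_threshold.R`); on that suite the two populations
are fully separated (sinus maximum 0.017, AF minimum 0.064). The value is a
property of this generator pair, not a clinically validated operating
point — on real data it should be re-derived against reference annotations.
A trailing partial segment is analysed only when it is the sole segment.

Time-domain HRV indices are reported alongside: mean heart rate
(60/mean RR), SDNN, max−min RR, and the triangular index at the
conventional 1/128 s histogram bin width.

## Beat template

Beats are windowed over 40% of the mean cycle before the R wave and 60%
after. The global mean RR (valid intervals) defines the cycle so all
windows share one length and can be averaged sample-wise; per-beat cycles
would give unequal windows. Windows running past the record bounds or
touching masked samples are dropped, never padded. The central 10%-of-cycle
QRS segment of each window is Pearson-correlated against the pointwise
*median* QRS segment — the median reference is robust to a minority of
ectopic or corrupt beats, whereas correlating against a mean would let a
large artifact drag the reference; mean pairwise correlation is available
as an alternative (`template_reference = "pairwise_mean"`). Beats
correlating strictly above 99.5% are averaged pointwise. If fewer than two
beats pass, the single best beat is returned with a warning. Averaging N
beats with independent noise σ leaves residual noise σ/√N, and the gate is
monotone: raising the threshold never adds contributors.

## The synthetic generator

`synth_ecg()` produces device-like records with exact ground truth. Beat
morphology is a fixed sum of five Gaussians (P, Q, R, S, T; 1 mV R peak) —
a standard synthetic-ECG construction; any beat-like waveform exercises the
chain, and no claim of morphological realism is made. Rhythms: sinus (RR
Gaussian with configurable mean rate and jitter, truncated at 0.25 s),
AF-like (RR i.i.d. uniform on [0.4, 1.0] s — a deliberate simplification
reproducing the serially uncorrelated, dispersed Poincaré cloud of AF, not
its physiology), bigeminy-like alternation (0.6/1.0 s), and a sinus rhythm
with one injected 3.5 s pause. Noise follows the classes above: sinusoidal
drift (default 0.3 Hz), a 50 Hz tone, 20 Hz-high-passed white EMG noise
specified by RMS amplitude, Poisson-placed 0.5 s bursts, and the 16 mV DC
offset. The RNG stream is private and fully determined by the spec's seed.

Default study conditions used throughout the tests: 120 s records at
250 Hz spanning 50–110 bpm with EMG at 20 dB SNR (10 dB for the stress
case) for detector metrics; 200 + 200 seeded 75 s segments for the AF
index; 100-replicate simulations for averaging statistics. These sizes give
stable Monte-Carlo estimates while keeping the default suite around a
minute of compute.

**What passing tests do and do not show.** The generator's beats are
identical up to noise, its rhythms are stationary, and its noise is
synthetic and mostly stationary; real recordings have beat-to-beat
morphology variation, ectopy, non-stationary artifacts and genuine AF
dynamics. Green tests therefore establish that the algorithms implement
their definitions and behave correctly under controlled conditions — they
do not establish clinical sensitivity or specificity, which can only be
measured against annotated patient data that this package deliberately does
not ship.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses odd-reflection padding (min(n−1, fs) samples)
  to suppress edge transients; stages are exact on constants to well below
  1e-9.
* The feature threshold falls back to ∞ when the feature is degenerate
  (empty valid set), yielding zero zones; an all-zero feature yields zero
  zones because the comparison is strict.
* Correlation of zero-variance QRS segments is defined as 1 for identical
  segments and 0 otherwise, instead of NaN.
* CSV round-trips use 17 significant digits, so read(write(x)) is exact
  for doubles.
* Quantities derived in seconds are converted to samples by `round()`, and
  all algorithm parameters are specified in seconds or fractions, so
  behaviour is sampling-rate independent.

## Known limitations

* Single-channel only; no multi-lead fusion and no beat-type
  classification (normal vs ectopic) — the template gate simply excludes
  discordant beats.
* EMG suppression relies on the 75 Hz low-pass alone; heavy muscle noise
  overlapping the QRS band degrades detection (by design, morphology
  preservation is prioritised).
* The AF threshold is calibrated on synthetic rhythms (see above).
* Frequency-domain and nonlinear HRV measures, wave delineation, and ABP
  analysis are out of scope; ABP values are carried as metadata only.
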