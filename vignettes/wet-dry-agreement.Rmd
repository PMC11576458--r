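---
title: "Comparing wet and dry EEG: simulation, pipeline and agreement methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing wet and dry EEG: simulation, pipeline and agreement methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eegagree` implements, end to end, the analysis chain used to ask whether a
multipin dry-electrode EEG system can replace a conventional gel-based
("wet") system for two families of measures: the mismatch negativity (MMN)
evoked by a passive auditory oddball paradigm (in time and in the
time-frequency domain), and sensor-level resting-state connectivity (phase
lag index and minimum-spanning-tree diameter). Because real paired
recordings of this kind cannot be redistributed, the package ships a
synthetic-data generator with known ground truth; every processing stage is
validated against injected effects rather than against any particular human
dataset. This vignette documents the models, the parameter choices, and the
design decisions that were genuinely open.

## The synthetic session

A simulated subject contributes, per system, an oddball task recording and a
resting-state recording, both sampled at 1,024 Hz on idealized cap layouts
(61 scalp + 3 periocular + 2 mastoid channels for the wet cap with 10-10
labels; 62 scalp + 2 periocular + 2 mastoid channels on a near-equidistant
numeric grid for the dry cap, whose fronto-central analysis site is `3Z` and
whose frontal references `1L`/`1LD` serve the bipolar EOG derivation).
Positions come from an inverse azimuthal-equidistant projection on the unit
sphere: they preserve neighbourhood topology (what spherical-spline
interpolation and blink propagation need) without claiming any
manufacturer's geometry.

The oddball block follows the study design exactly: 612 standard tones and
102 + 102 deviants (816 experimental tones at 12.5% deviant probability per
type), a stimulus-onset asynchrony of 1.555 s, 10 habituation standards
before the block, and a pseudo-randomization that keeps 2-4 standards
between consecutive deviants. The generator samples inter-deviant gaps
uniformly from {2, 3, 4} and repairs the total by seeded single-step
decrements, with leftover standards split between a lead-in and a tail run;
an independent checker (`validate_oddball_sequence()`) verifies every
constraint, and the test-suite runs it on every generated sequence.

Signal content:

* **Background**: 1/f-shaped Gaussian noise (spectral exponent 1), scaled to
  10 µV RMS for the wet and 20 µV RMS for the dry system. The 2:1 ratio
  reproduces the *direction* of the reported wet/dry SNR difference without
  claiming its exact size.
* **Obligatory response**: every tone adds a difference-of-Gaussians
  waveform (N1-like -2 µV trough at 100 ms, P2-like +1.5 µV peak at 200 ms)
  at fronto-central channels with graded gains.
* **Mismatch component**: deviants additionally add a Gaussian negativity
  (default -3.5 µV peaking at 125 ms, full width 50 ms — i.e. a value
  typical of healthy-adult MMN) plus a 4-8 Hz burst at 100-300 ms whose
  power is calibrated to sit `theta_burst_gain` dB (default +3 dB) above the
  channel's own theta noise floor.
* **Artifacts**: blinks arrive at 0.2/s as 300 ms half-sines of ~100 µV on
  the vertical EOG, propagated to frontal scalp channels with gain 0.3
  decaying with distance from the eyes; dry recordings additionally receive
  step ("jump") artifacts of 200-500 µV, 0.5-2 s long, at 2/min — the
  signature of intermittent electrode contact.

Rest data sums, per scalp channel, four narrow-band noise oscillators
(delta 0.5-4, theta 4-8, alpha 8-13, beta 13-20 Hz; alpha-dominant
amplitudes) over a weak 1/f floor. Selected channel pairs receive a
constant-phase-lagged copy of the sender's band component mixed with
independent noise, so the pairwise phase lag index has a known target that
grows monotonically with the mixing weight. Lags must lie strictly inside
(-pi, pi); a zero lag is a valid input that produces *zero* PLI despite
perfect coherence — the index only counts lead/lag asymmetry.

Everything is reproducible: each operation takes a seed, derived seeds keep
stages independent, and regenerating with the same seed is bit-identical.
What the generator does *not* model: volume conduction through a head model
(couplings are placed directly on channels), muscle or line-noise artifacts,
heterogeneous per-subject anatomy, and the dry system's proprietary contact
"quality index". Passing recovery tests therefore demonstrate that the
*pipeline* is correct and unbiased on signals of realistic scale and
spectrum — not that it would be robust to every pathology of real data.

## Preprocessing

The chain runs in a fixed order: mastoid-average re-reference, automated
bad-channel flagging, 0.1-25 Hz band-pass, epoching (-0.1 to 0.5 s task
epochs; 8 s rest epochs), resampling to 512 Hz, bipolar EOG derivation, ICA
with EOG-correlation rejection, spherical-spline interpolation of the
flagged channels, and peak-to-peak trial rejection. Choices worth spelling
out:

* **Filter realization.** Zero-phase FIR (Hamming window) applied by FFT
  convolution with reflection padding and group-delay compensation, as a
  high-pass/low-pass cascade so the two edges can have different transition
  widths (0.1 Hz at 0.1 Hz; 6 Hz at 25 Hz). Kernel length is 3.3 /
  transition-bandwidth seconds, capped at a third of the signal for short
  inputs. 50 Hz mains falls an octave above the upper edge and is attenuated
  by far more than 20 dB, so no notch filter is needed.
* **Epoch convention.** Half-open `[tmin, tmax)`: a -0.1 to 0.5 s epoch at
  1,024 Hz has exactly 614 samples, and resampling to 512 Hz exactly 307.
  The convention is asserted everywhere times are converted to samples.
* **Bad channels.** The study marked channels by visual inspection; the
  package substitutes an automated rule — RMS below 0.1 µV (dead) or robust
  z of log-RMS beyond 5 (artifact) — with both thresholds configurable.
  Interpolation uses Perrin-style spherical splines (order m = 4, Legendre
  series to degree 7, ridge 1e-5): constants are reproduced exactly, and
  leave-one-out error on smooth dipolar fields stays below 15%.
* **ICA.** A compact symmetric FastICA (tanh contrast) on PCA-whitened good
  scalp channels, 15 components by default, fitted on the kept epochs
  concatenated in time, with a seeded initial rotation so runs are
  deterministic. Components whose activations correlate with the bipolar
  vertical or horizontal EOG above |r| = 0.2 are subtracted; the PCA
  residual is kept, so a threshold of 1 reconstructs the input exactly.
  The EOG reference is restricted to the 1-10 Hz blink band before
  correlating — standard practice in ICA-EOG detection, because unfiltered
  EOG is dominated by slow drift whose tiny effective sample size would make
  a fixed 0.2 threshold fire on noise. Note also that the horizontal EOG is
  derived against a scalp electrode (F7 / 1LD), so on very small montages a
  component can share variance with it by construction; the rejection rule
  operates as intended on the full 61/62-channel layouts.
* **Trial rejection.** The published peak-to-peak threshold of "150 mV" is
  kept as the literal function default (0.15 V) — but that value is almost
  certainly a unit typo, since scalp EEG never reaches hundreds of
  millivolts; the pipeline configuration therefore defaults to the 150 µV
  preset (`ptp_uv_preset()`), which actually removes the simulated jump
  artifacts.
* **Inclusion.** A subject enters the task analysis only with more than 70%
  of trials retained *and* a plus-minus SNR above 1 in both systems; rest
  analyses only require complete rest data, so the rest sample can be
  larger than the task sample.

## MMN, theta power and SNR

ERPs average the kept trials per condition after excluding habituation
standards and the standard immediately following each deviant, then
baseline-correct with the -0.1 to 0 s window. Both deviant types are pooled
into one deviant condition (the study reports a single MMN; per-type
analysis stays available behind a flag), and trial counts are equalized
across conditions — and, via `n_per_condition`, across systems — by seeded
subsampling. The mismatch wave is deviant minus standard at FCz (wet) or 3Z
(dry); the window statistic is its 100-150 ms mean, and the "peak" is the
most negative sample in that window (the component being a negativity;
ties resolve to the earliest sample, and an absolute-magnitude mode is
available).

The plus-minus SNR divides the RMS of the deviant average restricted to the
analysis window by the RMS of the same average computed after flipping the
polarity of every other kept trial (the 2nd, 4th, ...), which cancels
time-locked activity and leaves the noise level. Identical trials with an
even count produce a zero noise estimate, returned as `Inf` with a warning.
Under pure noise both numerator and denominator estimate the same quantity
and the ratio centres on 1 — the property the inclusion threshold SNR > 1
relies on.

Time-frequency maps use complex Morlet wavelets from 1 to 18 Hz in 1 Hz
steps, cycles increasing linearly from 3 to 10, amplitude normalization
`sigma_t^(-1/2) pi^(-1/4)`, wavelets truncated at ±3 sigma_t, power sampled
every 0.05 s. Task data is re-epoched to ±1.2 s around onsets for this
stage — the ERP epochs are too short for a 1 Hz wavelet — and grid points
closer to an epoch edge than one wavelet half-length are flagged per
frequency and excluded from every window statistic (at 1-2 Hz that excludes
the whole epoch; the theta band is unaffected). Baseline correction is
`10*log10(power / mean baseline power)` over -600 to -300 ms, which makes
the maps invariant to global gain differences between systems — the reason
a dB measure is the right one for a wet/dry comparison. Theta power is the
mean over the 4-8 Hz bins and 100-300 ms (both inclusive).

## Resting-state connectivity

Rest epochs are re-referenced to the common average, band-passed per band
with a zero-phase 4th-order Butterworth (1 s reflection padding), and
Hilbert-transformed. The phase lag index of a pair is the absolute mean
sign of the wrapped instantaneous phase difference; exact zero differences
contribute 0, and the first and last 0.5 s of each epoch's phase series are
discarded against Hilbert edge effects. Pairs are averaged within an epoch
first and then across epochs (upper triangle only), giving the subject's
scalar mean PLI per band.

For the tree metrics, PLI is converted to a distance — `1 - PLI` by
default (bounded, defined at zero PLI), with `1/PLI` available to mirror
older tooling; both are strictly decreasing, so they induce identical
minimum spanning trees, which the tests assert. The MST is built by
Kruskal's algorithm with lexicographic tie-breaking, and the diameter `d`
(longest within-tree path in links, by BFS from every node) is normalized
by the link count: `D = d / M`, `M = N - 1`. No attempt is made to match
channels between the wet and dry layouts: both summaries are global
scalars, so the comparison is layout-agnostic by construction.

## Agreement statistics

The wet system is the reference, so Bland-Altman differences are
`wet - dry` (a negative bias means the dry system overestimates); the
convention is recorded in every output because prose and tables in this
literature are not always consistent about it. Bias is the mean difference;
limits of agreement are bias ± 1.96 SD (the exact-t multiplier is
available); the bias CI uses `t(0.975, n-1) * SD / sqrt(n)` and the LoA CIs
`t(0.975, n-1) * SD * sqrt(3/n)`; the bias is called significant when its
CI excludes zero. Zero-variance differences are legal and collapse all
intervals onto the bias.

Condition effects use a fully within-subject 2x2 ANOVA (system x tone),
each effect tested against its own effect-by-subject error term with
partial eta squared as effect size; the sums of squares decompose exactly
and are cross-checked against `aov()` with an `Error()` stratum. Follow-ups
are paired t-tests (one- or two-sided, Bonferroni-corrected) with paired
Cohen's d (`mean(diff)/sd(diff)`; labels: negligible < 0.2 ≤ small < 0.5 ≤
moderate < 0.8 ≤ large), and a Wilcoxon signed-rank alternative with exact
permutation p-values up to n = 25 (no ties) and a continuity-corrected
normal approximation beyond. A type-I calibration under the global null at
n = 23 holds all three tests inside the binomial band around 5%.

## Orchestration and problem sizes

`run_pipeline()` chains the stages per subject and system, equalizes trial
counts across systems, applies the inclusion rule, and writes per-subject
and group CSVs plus a JSON run report; a manifest keyed by a configuration
hash makes reruns incremental (deleting a stage's outputs reruns only that
stage; changing the configuration reruns everything). The same seed always
reproduces byte-identical CSVs on one platform.

The shipped defaults are the full study conditions (23 subjects, 816-tone
blocks, 5 min rest). The test-suite and examples run the same code on
reduced designs — three-subject runs, 12-48 standards, 16-32 s of rest,
one connectivity band — chosen so the whole suite exercises every stage,
including two full end-to-end parameter-recovery studies (20 subjects for
the MMN slope; a 5-level coupling grid for PLI), at desk scale. Estimated
window means are compared against the injected template's own window mean,
i.e. against what a perfect pipeline would report, so the recovery slope
has an exact target of 1.

Known limitations: no head-model leakage (so PLI's insensitivity to
volume conduction is asserted only at the level of zero-lag coupling); ICA
components are rejected by EOG correlation only; the dry cap's geometry and
impedance behaviour are stylized; and group-level numbers from any real
wet/dry study are not reproduced here — the package validates procedures,
not population values.
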