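---
title: "Methods: whisking kinematics and neural activity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whisking kinematics and neural activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskephys)
```

This vignette documents the models, conventions and numerical choices behind
`whiskephys`, in the spirit of a methods section: what each stage assumes,
which parameters matter, and where the design was genuinely open.

## Whisker kinematic decomposition

Rodent whisking is well described as a rhythmic carrier riding on slow
envelope variables. The whisker angle $\theta(t)$ (degrees, 500 Hz video) is
modelled as

$$\theta(t) \approx \theta_{mid}(t) + \theta_{amp}(t)\,\cos\varphi(t),$$

where $\varphi$ is the whisk-cycle phase ($\varphi = 0$ at peak protraction,
$\pm\pi$ at the end of retraction), $\theta_{amp}$ half the
protraction–retraction excursion, and $\theta_{mid}$ its center. The phase
is obtained from the analytic signal (Hilbert transform) of the 4–25 Hz
band-passed angle; the band-pass is a 2nd-order Butterworth applied
forward–backward (`signal::filtfilt`), i.e. zero-phase with an effective
4th-order rolloff, with reflection padding against edge transients.
Zero-phase filtering is not optional: any group delay would shift the
detected $\varphi=0$ events off the true protraction peaks.

Amplitude and midpoint are evaluated *on the raw angle* at the phase events
($\varphi = 0$ and $\pm\pi$) and linearly interpolated between events; the
decomposition therefore reconstructs the raw trace, not the band-passed one.
Phase events are detected as crossings of the unwrapped phase through
multiples of $\pi$ rather than as raw-trace extrema; on clean sinusoids the
two coincide to within one sample, and the phase-based detector is robust to
noise riding on the extrema. The setpoint $\theta_{set}$ is a zero-phase
low-pass of the raw angle at 6 Hz; this filter uses twice the band-pass
order (effective 8th order) because an 8–12 Hz whisking fundamental sits
close above the 6 Hz cutoff and must not ripple through.

Degenerate inputs are flagged rather than silently processed: a trace with
essentially no oscillatory energy yields `degenerate = TRUE` from
`hilbert_phase()`, and fewer than two phase events marks amplitude and
midpoint undefined.

### Epoch segmentation and the onset rule

Sweeps are tiled greedily with the longest qualifying window (3, then 2,
then 1 s). A window is *whisking* when the band-passed envelope stays above
2.5° throughout, *quiet* when it stays below 1° throughout; intermediate
windows stay unlabelled and the scan advances by 0.5 s. The two envelope
thresholds and the greedy longest-first rule are this package's concrete
reading of "continuous rhythmic movement" vs "no movement"; both are
configuration fields.

The whisking onset is the first sample exceeding 1° above baseline. The
baseline is defined here as the median raw angle over the immediately
preceding quiet window — a choice the onset rule needs but that is otherwise
open. The crossing search walks *backwards* from the whisking-epoch start to
the last sub-threshold sample and then forward: slow pre-bout movement (for
example a setpoint ramp) can begin inside the preceding low-envelope window,
and the onset must be the crossing that belongs to this movement, not the
epoch boundary.

## Spike analysis

Cell-type classification thresholds the mean-waveform trough-to-peak time at
0.4 ms (below: fast-spiking) and 0.5 ms (above: regular-spiking);
intermediate units are excluded. Whisking modulation compares per-epoch
firing rates between quiet and whisking epochs with a Wilcoxon rank-sum test
per unit (the package's choice of two-sample test, consistent with the
nonparametric convention used throughout), requiring at least 5 epochs per
label, with Benjamini–Hochberg correction across the units of a session
(the correction family is the session; this is logged, since "family" could
also be read per figure or per experiment).

Rate Z-scores use the mean and *descriptive* (population, $/n$) SD of the
2 s-bin rates; with the descriptive SD the standardization identities are
exact (alternating two-level bins give $Z=\pm1$; $\mathrm{SD}(Z)=1$). PETHs
standardize 200 ms-bin rates with that same mean/SD, smooth with a Gaussian
kernel of SD one bin, and subtract the mean over −1.0…−0.2 s before onset.
The smoothing SD is a configuration field; one bin (200 ms) is the default.

## Tuning curves and the two-step significance test

Only whisking-epoch samples enter tuning — phase is meaningless when the
whisker is still. Each variable is cut into 50 equal-probability bins
(edges halfway between adjacent order statistics, so per-bin counts differ
by at most one sample; heavy ties merge bins and set a flag). The rate in a
bin is spikes-in-bin over time-in-bin.

The response samples of the significance test are *bin visits*: maximal runs
of consecutive samples in one bin, each with a rate (spikes/duration). Step
1 is a one-way ANOVA of visit rates across bins at $\alpha = 0.05$; only
units passing it proceed to step 2, which permutes the visit responses
across bin labels 1,000 times, recomputes the ANOVA F each time, and calls
the unit tuned when the observed F exceeds the 95th percentile of the
shuffled distribution. Permuting visit-to-bin assignment is the standard
reading of "shuffling the responses"; it preserves the per-bin sample-size
structure. The same group-sum F computation is used for the observed and
every shuffled labelling (a unit test pins it to `stats::oneway.test`), and
the permutation exploits sparsity: only visits containing spikes contribute
to permuted group sums, making 1,000 shuffles cheap even with $10^5$ visits.
Units averaging fewer than two visits per bin are untestable and flagged.

Smoothing uses penalized regression splines (`mgcv`), cyclic for phase,
cubic otherwise, weighted by bin occupancy, with smoothness chosen by GCV
and predictions floored at zero. This is a deterministic, testable stand-in
for free-knot Bayesian adaptive regression splines: the downstream contract
is only a smooth nonnegative curve exposing max, min and argmax, so a
faithful BARS backend could be slotted in without touching any consumer.

Modulation depth is $(\max - \min)/\text{baseline}$ with the baseline
defined as the unit's mean quiet-epoch rate (the depth formula needs *some*
baseline; quiet-epoch rate is the natural one, and zero-baseline units are
flagged rather than divided by zero). The modulation index
$(\max - \min)/(\max + \min)$ is scale-free; for a von Mises rate profile
with concentration $\kappa$ its analytic value is $\tanh(\kappa)$, which the
recovery tests use as ground truth.

## Membrane potential

Action potentials are detected where $dV/dt > 10$ V/s with a 2 ms
refractory merge, and excised from 1 ms before to 4 ms after the peak by
linear interpolation. Subthreshold statistics (means, variances, spectra)
are computed on the cleaned trace; spike excision is necessary for unbiased
means and is performed before the variance (whether variance precedes or
follows AP removal is open; cleaned-first is logged). Slow-wave amplitude is
the trapezoid integral over 1–5 Hz of magnitude spectra of non-overlapping
2 s segments (no taper — magnitudes of plain segments — matching the plain
"FFT magnitudes of 2 s segments" convention; scaled so a sinusoid of
amplitude $a$ mV shows a line of height $a$).

Phase-locked $V_m$ averages the cleaned trace in 64 equal-width phase bins
over whisking samples (the bin count for this average is a package choice);
depth is the peak-to-trough of the averaged trace. Its null distribution
comes from circular shifts: each shuffle rotates every whisking epoch's
$V_m$ segment by an independent uniform offset — preserving the trace's
autocorrelation while breaking the phase alignment — and the p-value is the
fraction of shuffled depths at or above the observed one. Fewer than 100
shuffles triggers a resolution warning. Liquid junction potential is not
corrected, and no offset is applied anywhere.

## LFP and current source density

LFP preprocessing is anti-aliased decimation plus a zero-phase 100 Hz
low-pass (1 kHz target for spectra, 3 kHz for CSD). Spectra are Welch
averages of Hann-tapered 2 s periodograms from epochs of at least 2 s,
divided by the peak of the averaged light-off spectrum, so the normalized
light-off peak is exactly 1. The divisor pools all light-off segments of the
session (the normalization reference could also be read per state; pooled is
logged).

CSD is the discrete second spatial derivative of the touch-triggered average
along one probe column (odd or even channel numbers — the two-column probe
geometry makes within-column spacing uniform), *negated* so that current
sinks are negative and sources positive:
$\mathrm{CSD}_i = -(V_{i-1} - 2V_i + V_{i+1})/\Delta z^2$, in mV/mm², with
boundary channels duplicate-padded. The sign is the physiological
convention: a sink draws current from the extracellular space and produces a
negative LFP deflection, whose plain second derivative at the spatial peak
is positive; the negation makes "sink" and "negative" coincide. CSD of any
depth-affine potential profile is identically zero at interior channels.

Layer-4 localization computes three per-channel criteria on the
touch-triggered average: shortest LFP peak latency (among channels whose
peak amplitude reaches 20% of the maximum, so flat channels cannot win on
noise), largest negative peak amplitude, and earliest CSD sink onset (first
crossing of 20% of the channel's peak negative CSD after touch — "onset"
needs an operational definition and this is it). Criteria agreeing
unanimously decide; otherwise a majority vote with ties broken toward the
amplitude criterion, and a disagreement flag is set either way. The winning
channel is anchored at a 500 µm subpial depth and layer boundaries are read
from an editable depth table shipped as configuration (default values are
standard mouse barrel-cortex laminar depths).

## Condition comparisons and orchestration

`compare_conditions()` checks normality of the paired differences
(Shapiro–Wilk at 0.05 — the package's choice of normality test) and applies
a paired t test when Gaussian, a Wilcoxon signed-rank test otherwise;
identical conditions short-circuit to $p = 1$. Light-off trials always
precede light-on trials in session layouts; the order is metadata, never
randomized, because the opsin kinetics outlast a trial.

`run_session()` chains generator → kinematics → epochs → spike
classification → tuning → $V_m$ → laminar stages over a synthetic session
and writes all result tables; with a fixed seed the output is byte-identical
across runs (no timestamps enter any output, and every random stream is
derived from the configured seed plus a stage label).

## The synthetic-data generator: what it does and does not emulate

The generator reproduces the statistical structure the analyses assume:
cosine whisking bouts within 4–25 Hz with scheduled amplitude and midpoint
(so phase, amplitude and midpoint ground truth are analytic, independent of
the pipeline's own Hilbert machinery); inhomogeneous-Poisson spiking with a
von Mises phase factor normalized by $I_0(\kappa)$ so the time-averaged
factor is 1 and the baseline rate stays interpretable regardless of tuning
sharpness; per-sample Poisson counts on the 500 Hz grid with uniform
within-sample jitter (exact for rates constant within a sample, which these
are by construction); $V_m$ as rest + state-dependent band-limited 1–5 Hz
noise + whisking depolarization + phase-locked cosine + white noise, with
state transitions smoothed over 50 ms so no artificial voltage step mimics
an action-potential $dV/dt$; and touch-evoked laminar dipoles with Gaussian
spatial amplitude decay and linear latency growth away from the layer-4
channel, over pink-ish background noise.

It deliberately does not emulate: non-sinusoidal whisk-cycle asymmetry
(real protraction is slower than retraction), spike-history dependence
(refractoriness, bursting), slow non-stationarities in rate or $V_m$,
conductance-based opsin kinetics (light-on suppression is a constant
multiplicative factor per sweep — no published quantitative time course per
epoch exists, so none is guessed), electrode drift, or correlated noise
across probe channels. Passing recovery tests on generator data therefore
demonstrates correctness of the estimators under the model the analyses
assume, not robustness to every pathology of real recordings.

## Problem sizes and numerical conventions

Validation cohorts are sized to be decisive yet desk-scale: 500 untuned
units (5 Hz, 300 s of whisking) for type-I calibration of the tuning test;
100 seeded units at $\kappa = 2$ for power and recovery; 500 spike-free
$V_m$ runs with 200 circular shuffles each for null calibration of the
phase-lock test (200 shuffles give p-resolution 0.005, ample to measure a
5% rejection rate; per-cell analyses default to 1,000); 100 noisy laminar
sessions at signal-to-noise 5 for localization robustness. Synthetic $V_m$
is generated at 2 kHz in these cohorts — every analyzed $V_m$ phenomenon
lives below 100 Hz, and real recordings at 10 kHz or more only oversample
it. Seeds are derived per stream from a master seed plus a stage label and
stay below $2^{31}$.

## Known limitations

- The spline smoother is a stand-in for free-knot BARS; very sharp tuning
  peaks (width ≪ one bin) will be attenuated by any fixed-basis smoother.
- Equal-probability binning assumes enough distinct variable values; heavily
  quantized variables merge bins (flagged).
- The CSD is the plain second-difference estimator; inverse methods (iCSD,
  kCSD) are out of scope.
- Two-photon-targeted or multi-whisker kinematics, video tracking itself,
  and spike sorting are upstream of this package: it starts from angle
  traces and sorted spike times.
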