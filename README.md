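# whiskephys

Quantifying whisking-related neural activity in awake rodent
electrophysiology.

When a mouse sweeps its whiskers (4–25 Hz "whisking" bouts interleaved with
quiet wakefulness), neurons in the whisker sensorimotor system change their
firing rates, lock to the whisk cycle, and shift their subthreshold membrane
potential. `whiskephys` implements, as a tested and reusable R pipeline, the
standard analysis chain for such experiments:

- **Whisker kinematics.** The whisker angle θ(t) (degrees, 500 Hz video) is
  band-pass filtered to 4–25 Hz and decomposed via the Hilbert transform into
  phase φ(t) (φ = 0 at peak protraction, φ = ±π at the end of retraction),
  amplitude θ_amp(t) = (θ_{φ=0} − θ_{φ=±π})/2, midpoint
  θ_mid(t) = θ_{φ=±π} + (θ_{φ=0} − θ_{φ=±π})/2 (linearly interpolated between
  phase events), and setpoint θ_set(t) (6 Hz low-pass). Sweeps are tiled into
  quiet and whisking epochs (3/2/1 s windows) and the whisking onset is the
  first sample exceeding 1° above the preceding quiet baseline. The original
  trace is recovered as θ̂(t) = θ_mid(t) + θ_amp(t)·cos φ(t).
- **Spike analysis.** Sorted units are classified regular-spiking vs
  fast-spiking by waveform trough-to-peak time (RS > 0.5 ms, FS < 0.4 ms,
  intermediate excluded), and whisking-excited / whisking-inhibited /
  non-modulated (W-Exc / W-Inh / NM) by comparing per-epoch rates (Wilcoxon
  rank-sum, Benjamini–Hochberg corrected across units). Rates are Z-scored in
  2 s bins; onset-aligned PETHs use 200 ms bins, Gaussian smoothing and a
  −1.0…−0.2 s baseline. Light-on optogenetic suppression is summarized by
  (ON − OFF)/(ON + OFF).
- **Tuning curves.** Firing rate versus phase / amplitude / midpoint in 50
  equal-probability bins, smoothed by penalized (cyclic) regression splines;
  significance by a two-step procedure — one-way ANOVA at α = 0.05, then a
  1,000-iteration shuffle of the responses with a 95th-percentile F
  criterion. Modulation depth = (max − min)/baseline, modulation index =
  (max − min)/(max + min).
- **Membrane potential.** AP detection and excision, per-epoch V_m mean /
  variance / AP rate, 1–5 Hz slow-wave FFT band integrals over 2 s segments,
  and whisking phase-locked V_m (peak-to-trough depth of the phase-averaged
  trace) with a circular-shift permutation null.
- **LFP / CSD.** 100 Hz low-pass preprocessing, state-dependent Welch
  spectra normalized to the light-off peak, current source density
  (second spatial derivative along depth, sinks negative) of touch-triggered
  averages, and layer-4 localization by three criteria (shortest peak
  latency, largest amplitude, earliest CSD sink onset), anchored at a 500 µm
  subpial depth.
- **Synthetic data with ground truth.** Generators for whisker traces
  (scheduled cosine bouts), inhomogeneous-Poisson spike trains (von Mises
  phase tuning with unit-mean normalization, whisking gain, linear
  amplitude/midpoint modulation, light suppression), V_m traces (state-
  dependent 1–5 Hz slow wave, whisking depolarization, phase locking), and
  touch-evoked laminar LFP dipoles — every generating parameter is stored so
  downstream statistics can be validated against truth.

## Worked example

```r
library(whiskephys)

# a 60 s sweep with three whisking bouts, fully known ground truth
bouts <- data.frame(start_s = c(5, 20, 35), end_s = c(15, 30, 45),
                    freq_hz = c(10, 8, 12), amplitude_deg = c(10, 8, 12),
                    midpoint_deg = c(15, 12, 18))
sim    <- simulate_whisker_trace(whisk_gen_params(60, bout_schedule = bouts, seed = 7))
decomp <- decompose_whisking(sim$trace)
epochs <- segment_epochs(sim$trace, decomp = decomp)
decomp
#> kinematic_decomposition: 30000 samples at 500 Hz, 728 protraction / 735 retraction events
epochs
#> epoch_set (sweep 1): 11 quiet, 12 whisking

# a phase-tuned, whisking-excited unit
unit <- simulate_spike_train(decomp, sim$truth$whisking,
          tuning_ground_truth(baseline_rate = 6, whisking_gain = 2,
                              phase_kappa = 1.5, preferred_phase = 0.8),
          seed = 11, unit_id = "u01")
mod <- classify_whisk_modulation(unit, epochs)
mod[, c("unit_id", "category", "w_delta_ap", "q_bh")]
#>   unit_id category w_delta_ap         q_bh
#> 1     u01    W-Exc   1.480744 0.0001316241

design <- tuning_design(decomp, epochs, "phase")
tuning_curve(unit, design, baseline_rate = mod$quiet_rate_hz, seed = 11)
#> tuning_result: unit u01, variable phase
#>   tuned: TRUE (ANOVA p = 3.1e-36, shuffle p = 0, F = 6.01)
#>   rate range [1.16, 29.25] Hz, depth 4.49, index 0.92, preferred 0.859
```

The unit is recovered as whisking-excited (its Z-scored rate rises by ~1.5
during whisking, W-ΔAP) and significantly phase-tuned; the smoothed tuning
curve peaks at phase 0.859 rad, close to the generating preferred phase of
0.8 rad, and the modulation index 0.92 approaches the analytic value
tanh(κ) ≈ 0.905 for κ = 1.5.

`run_session(whiskephys_config(), out_dir)` chains every stage — kinematics,
epoch segmentation, unit classification, tuning, V_m statistics, and laminar
L4 localization — over a fully synthetic session and writes the result
tables (CSV/JSON) deterministically for a fixed seed.

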