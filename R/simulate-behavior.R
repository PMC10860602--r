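# Ground-truth generators: whisker kinematics and spike trains.
# These emulate the statistical structure the analysis stages assume --
# rhythmic 4-25 Hz whisking bouts between quiet periods, and spiking with
# phase / amplitude / midpoint tuning, whisking-state gain and light-on
# suppression -- with the generating parameters stored alongside so every
# downstream statistic can be checked against truth.

#' Whisker-trace simulation parameters
#'
#' @param sweep_duration Sweep length in seconds.
#' @param sample_rate Frame rate in Hz (default 500).
#' @param bout_schedule Data frame with columns `start_s`, `end_s`,
#'   `freq_hz` (whisk frequency, within the 4-25 Hz whisking band),
#'   `amplitude_deg`, `midpoint_deg`; bouts must be non-overlapping and lie
#'   within the sweep.
#' @param baseline_deg Resting whisker angle outside bouts (degrees).
#' @param quiet_noise_sd SD of Gaussian angle noise outside bouts (degrees).
#' @param phase0 Cosine phase at each bout start (radians).
#' @param seed Integer seed.
#' @return List of class `whisk_gen_params`.
#' @export
whisk_gen_params <- function(sweep_duration, sample_rate = 500,
                             bout_schedule = data.frame(), baseline_deg = 10,
                             quiet_noise_sd = 0.2, phase0 = 0, seed = 1L) {
  bs <- as.data.frame(bout_schedule)
  if (nrow(bs)) {
    need <- c("start_s", "end_s", "freq_hz", "amplitude_deg", "midpoint_deg")
    stopifnot(all(need %in% names(bs)))
    bs <- bs[order(bs$start_s), , drop = FALSE]
    if (any(bs$start_s < 0) || any(bs$end_s > sweep_duration)) {
      stop("bouts must lie within the sweep")
    }
    if (any(bs$end_s <= bs$start_s)) stop("bout end must exceed bout start")
    if (nrow(bs) > 1L && any(bs$start_s[-1L] < bs$end_s[-nrow(bs)])) {
      stop("bouts must be non-overlapping")
    }
    if (any(bs$freq_hz < 4 | bs$freq_hz > 25)) {
      stop("whisk frequencies must lie in the 4-25 Hz whisking band")
    }
    if (any(bs$amplitude_deg < 0)) stop("bout amplitudes must be nonnegative")
  }
  structure(list(sweep_duration = sweep_duration, sample_rate = sample_rate,
                 bout_schedule = bs, baseline_deg = baseline_deg,
                 quiet_noise_sd = quiet_noise_sd, phase0 = phase0,
                 seed = as.integer(seed)),
            class = "whisk_gen_params")
}

#' Simulate a whisker angle trace with known kinematic ground truth
#'
#' Inside each bout the angle is
#' `midpoint + amplitude * cos(2 pi f (t - start) + phase0)`; outside bouts
#' it is the baseline plus Gaussian noise. The true per-sample phase
#' (argument of the cosine, wrapped to (-pi, pi]), amplitude, midpoint and
#' whisking mask are returned so that recovery tests compare against an
#' analytic truth rather than against the pipeline's own Hilbert output.
#'
#' @param params A [whisk_gen_params()].
#' @return List with `trace` (a [whisker_trace()]) and `truth` (per-sample
#'   phase/amplitude/midpoint, logical `whisking`, and the bout schedule).
#' @export
simulate_whisker_trace <- function(params) {
  stopifnot(inherits(params, "whisk_gen_params"))
  fs <- params$sample_rate
  n <- as.integer(round(params$sweep_duration * fs))
  t <- (seq_len(n) - 1L) / fs
  set.seed(derive_seed(params$seed, "whisker"))
  angle <- rep(params$baseline_deg, n) +
    if (params$quiet_noise_sd > 0) stats::rnorm(n, 0, params$quiet_noise_sd) else 0
  true_phase <- rep(NA_real_, n)
  true_amp <- rep(0, n)
  true_mid <- rep(params$baseline_deg, n)
  whisking <- logical(n)
  bs <- params$bout_schedule
  for (i in seq_len(nrow(bs))) {
    idx <- which(t >= bs$start_s[i] & t < bs$end_s[i])
    arg <- 2 * pi * bs$freq_hz[i] * (t[idx] - bs$start_s[i]) + params$phase0
    angle[idx] <- bs$midpoint_deg[i] + bs$amplitude_deg[i] * cos(arg)
    true_phase[idx] <- wrap_angle(arg)
    true_amp[idx] <- bs$amplitude_deg[i]
    true_mid[idx] <- bs$midpoint_deg[i]
    whisking[idx] <- TRUE
  }
  list(trace = whisker_trace(angle, fs),
       truth = list(phase = true_phase, amplitude = true_amp,
                    midpoint = true_mid, whisking = whisking,
                    bout_schedule = bs, time_s = t))
}

#' Tuning ground truth for a simulated unit
#'
#' @param baseline_rate Mean rate (Hz) with all modulations at 1.
#' @param whisking_gain Multiplicative rate gain during whisking (>1 behaves
#'   like a whisking-excited unit, <1 whisking-inhibited, 1 non-modulated).
#' @param phase_kappa von Mises concentration of phase tuning (0 = untuned).
#' @param preferred_phase Preferred whisking phase (radians).
#' @param amp_slope,mid_slope Linear rate modulation (per degree) by whisking
#'   amplitude and midpoint.
#' @param light_suppression Fraction in \[0, 1\] multiplying the rate as
#'   `1 - light_suppression` during light-on sweeps.
#' @return List of class `tuning_ground_truth`.
#' @export
tuning_ground_truth <- function(baseline_rate = 5, whisking_gain = 1,
                                phase_kappa = 0, preferred_phase = 0,
                                amp_slope = 0, mid_slope = 0,
                                light_suppression = 0) {
  stopifnot(baseline_rate >= 0, whisking_gain >= 0, phase_kappa >= 0,
            light_suppression >= 0, light_suppression <= 1)
  structure(list(baseline_rate = baseline_rate, whisking_gain = whisking_gain,
                 phase_kappa = phase_kappa, preferred_phase = preferred_phase,
                 amp_slope = amp_slope, mid_slope = mid_slope,
                 light_suppression = light_suppression),
            class = "tuning_ground_truth")
}

# Rate profile lambda(t) in Hz implied by a tuning ground truth over a
# decomposed sweep. The von Mises phase factor is normalized by I0(kappa) so
# its time average over uniform phase is 1, keeping baseline_rate the mean
# rate regardless of tuning sharpness.
tuning_rate_profile <- function(truth, decomp, whisking, light_on = FALSE) {
  lambda <- rep(truth$baseline_rate, length(whisking))
  lambda[whisking] <- lambda[whisking] * truth$whisking_gain
  if (truth$phase_kappa > 0) {
    ph <- decomp$phase
    ok <- whisking & !is.na(ph)
    lambda[ok] <- lambda[ok] *
      exp(truth$phase_kappa * cos(ph[ok] - truth$preferred_phase)) /
      besselI(truth$phase_kappa, 0)
  }
  if (truth$amp_slope != 0 || truth$mid_slope != 0) {
    lin <- 1 + truth$amp_slope * ifelse(is.na(decomp$amplitude), 0, decomp$amplitude) +
      truth$mid_slope * ifelse(is.na(decomp$midpoint), 0, decomp$midpoint)
    if (any(lin < 0)) {
      warning("linear amplitude/midpoint modulation drove the rate negative; floored at 0")
      lin[lin < 0] <- 0
    }
    lambda <- lambda * lin
  }
  if (light_on) lambda <- lambda * (1 - truth$light_suppression)
  lambda
}

#' Simulate a spike train with known tuning
#'
#' Spikes are drawn from an inhomogeneous Poisson process whose rate is the
#' product of the baseline rate, the whisking-state gain, a von Mises phase
#' factor (normalized so its time average is 1), a linear amplitude/midpoint
#' factor floored at zero, and the light-on suppression factor. The rate is
#' evaluated per sample on the kinematic grid; counts are Poisson per sample
#' and spike times jittered uniformly within the sample.
#'
#' @param decomp Kinematic decomposition of the sweep (truth-based or
#'   pipeline-based), supplying `phase`, `amplitude`, `midpoint`.
#' @param whisking Logical per-sample whisking mask.
#' @param truth A [tuning_ground_truth()].
#' @param light_on Logical: light-on sweep?
#' @param seed Integer seed.
#' @param unit_id Identifier for the resulting unit.
#' @param trough_to_peak_ms Waveform trough-to-peak time used to synthesize
#'   the mean waveform (default 0.7, a regular-spiking width).
#' @return A [spike_unit()] whose `truth` field carries the generating
#'   parameters and the per-sample rate profile `lambda_hz`.
#' @export
simulate_spike_train <- function(decomp, whisking, truth, light_on = FALSE,
                                 seed = 1L, unit_id = "u1",
                                 trough_to_peak_ms = 0.7) {
  stopifnot(inherits(truth, "tuning_ground_truth"),
            length(whisking) == length(decomp$phase))
  fs <- decomp$sample_rate
  lambda <- tuning_rate_profile(truth, decomp, whisking, light_on)
  set.seed(derive_seed(seed, paste0("spikes-", unit_id)))
  counts <- stats::rpois(length(lambda), lambda / fs)
  idx <- rep(seq_along(counts), counts)
  times <- sort((idx - 1L + stats::runif(length(idx))) / fs)
  wf <- synth_waveform(trough_to_peak_ms)
  unit <- spike_unit(unit_id = unit_id, spike_times = times,
                     sweep_duration = length(lambda) / fs,
                     waveform = wf$waveform, waveform_rate = wf$sample_rate)
  unit$truth <- c(unclass(truth), list(lambda_hz = lambda, light_on = light_on))
  unit
}

# Stereotyped extracellular mean waveform with a prescribed trough-to-peak
# time, sampled at 30 kHz: a narrow negative trough followed by a slower
# positive after-peak.
synth_waveform <- function(trough_to_peak_ms, sample_rate = 30000) {
  t <- seq(-1.5e-3, 2.5e-3, by = 1 / sample_rate)
  ttp <- trough_to_peak_ms / 1000
  w <- -exp(-(t / 2e-4)^2) + 0.45 * exp(-((t - ttp) / (0.6 * ttp))^2)
  list(waveform = w, sample_rate = sample_rate, time_s = t)
}
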