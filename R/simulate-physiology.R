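# Ground-truth generators: whole-cell membrane potential and laminar LFP.

#' Membrane-potential ground truth
#'
#' Parameters of the simulated subthreshold dynamics: a 1-5 Hz slow-wave
#' component whose SD drops during whisking, a whisking depolarization, a
#' whisking phase-locked cosine, broadband noise, and stereotyped action
#' potentials inserted at threshold crossings.
#'
#' @param rest_vm Resting potential (mV).
#' @param slow_wave_band Slow-wave band (Hz), default 1-5.
#' @param slow_wave_sd_quiet,slow_wave_sd_whisk SD (mV) of the band-limited
#'   slow wave in quiet / whisking states; whisking must not exceed quiet
#'   (the regime the analysis assumes).
#' @param whisk_depol Depolarization added during whisking (mV).
#' @param phase_lock_amp Amplitude (mV) of phase-locked Vm modulation.
#' @param phase_lock_pref Most depolarized whisking phase (radians).
#' @param noise_sd Broadband white-noise SD (mV).
#' @param spike_threshold Threshold (mV) above which an action potential is
#'   inserted; must exceed `rest_vm`. Set high to obtain a spike-free cell.
#' @param seed Integer seed.
#' @return List of class `vm_ground_truth`.
#' @export
vm_ground_truth <- function(rest_vm = -60, slow_wave_band = c(1, 5),
                            slow_wave_sd_quiet = 3, slow_wave_sd_whisk = 1,
                            whisk_depol = 3, phase_lock_amp = 1,
                            phase_lock_pref = 0, noise_sd = 0.5,
                            spike_threshold = -20, seed = 1L) {
  if (slow_wave_sd_whisk > slow_wave_sd_quiet) {
    stop("whisking slow-wave SD must not exceed the quiet SD")
  }
  if (spike_threshold <= rest_vm) stop("spike threshold must exceed rest_vm")
  structure(list(rest_vm = rest_vm, slow_wave_band = slow_wave_band,
                 slow_wave_sd_quiet = slow_wave_sd_quiet,
                 slow_wave_sd_whisk = slow_wave_sd_whisk,
                 whisk_depol = whisk_depol, phase_lock_amp = phase_lock_amp,
                 phase_lock_pref = phase_lock_pref, noise_sd = noise_sd,
                 spike_threshold = spike_threshold, seed = as.integer(seed)),
            class = "vm_ground_truth")
}

# Band-limited unit-SD Gaussian noise via frequency-domain masking.
bandlimited_noise <- function(n, sample_rate, band) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1L) * sample_rate / n
  f <- pmin(f, sample_rate - f)            # two-sided frequency axis
  mask <- as.numeric(f >= band[1] & f <= band[2])
  y <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE) / n)
  s <- stats::sd(y)
  if (s == 0) rep(0, n) else y / s
}

#' Simulate a whole-cell membrane-potential trace
#'
#' Vm is the resting potential plus band-limited (1-5 Hz) slow-wave noise
#' whose SD switches between quiet and whisking values, a whisking
#' depolarization, a whisking phase-locked cosine, and broadband white
#' noise. Stereotyped 2 ms action-potential waveforms are inserted where the
#' subthreshold trace crosses the spike threshold. All noiseless components
#' and the inserted spike times are retained as ground truth.
#'
#' @param decomp Kinematic decomposition supplying the whisking phase (or
#'   the generator truth phase); must be on the Vm time base or resampled.
#' @param whisking Logical per-sample whisking mask on the Vm time base.
#' @param truth A [vm_ground_truth()].
#' @param sample_rate Vm sampling rate in Hz.
#' @param phase Optional per-sample phase (radians) on the Vm time base;
#'   defaults to `decomp$phase` resampled by index if lengths differ.
#' @return A [vm_recording()] whose `truth` field stores the generating
#'   parameters, the noiseless subthreshold components, and inserted spike
#'   times.
#' @export
simulate_vm_trace <- function(decomp, whisking, truth, sample_rate = 10000,
                              phase = NULL) {
  stopifnot(inherits(truth, "vm_ground_truth"))
  n <- length(whisking)
  if (is.null(phase)) {
    phase <- decomp$phase
    if (length(phase) != n) {
      phase <- stats::approx(seq(0, 1, length.out = length(phase)),
                             unwrap_phase(phase),
                             xout = seq(0, 1, length.out = n))$y
      phase <- wrap_angle(phase)
    }
  }
  set.seed(derive_seed(truth$seed, "vm"))
  sw_sd <- ifelse(whisking, truth$slow_wave_sd_whisk, truth$slow_wave_sd_quiet)
  slow <- if (max(sw_sd) > 0) {
    bandlimited_noise(n, sample_rate, truth$slow_wave_band) * sw_sd
  } else rep(0, n)
  # state transitions are smoothed over ~50 ms so the generated Vm has no
  # instantaneous steps (which would mimic action-potential dV/dt)
  k <- max(1L, as.integer(round(0.05 * sample_rate)))
  wsm <- as.numeric(stats::filter(c(rep(whisking[1L], k), as.numeric(whisking),
                                    rep(whisking[n], k)),
                                  rep(1 / (2 * k + 1), 2 * k + 1),
                                  sides = 2))[(k + 1L):(k + n)]
  depol <- wsm * truth$whisk_depol
  locked <- ifelse(is.finite(phase),
                   wsm * truth$phase_lock_amp * cos(phase - truth$phase_lock_pref), 0)
  white <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else 0
  sub <- truth$rest_vm + slow + depol + locked + white

  vm <- sub
  cross <- which(sub[-1L] >= truth$spike_threshold &
                 sub[-length(sub)] < truth$spike_threshold) + 1L
  # enforce a 5 ms minimum separation between inserted spikes
  ap_idx <- integer(0)
  gap <- as.integer(round(0.005 * sample_rate))
  for (i in cross) if (!length(ap_idx) || i - ap_idx[length(ap_idx)] > gap) {
    ap_idx <- c(ap_idx, i)
  }
  spike_len <- max(2L, as.integer(round(0.002 * sample_rate)))
  half <- spike_len %/% 2L
  shape <- 70 * exp(-((seq_len(spike_len) - half) / (spike_len / 6))^2)
  for (i in ap_idx) {
    rng <- i:min(n, i + spike_len - 1L)
    vm[rng] <- vm[rng] + shape[seq_along(rng)]
  }
  rec <- vm_recording(vm, sample_rate)
  rec$truth <- c(unclass(truth),
                 list(subthreshold = sub, slow_wave = slow, depol = depol,
                      phase_locked = locked, ap_times = (ap_idx - 1L) / sample_rate,
                      whisking = whisking, phase = phase))
  rec
}

#' Laminar-probe ground truth
#'
#' @param n_channels Number of probe channels (default 32, two interleaved
#'   depth columns of 16).
#' @param channel_spacing Vertical spacing in um between successive sites of
#'   the full array (within one odd/even column the spacing doubles).
#' @param true_l4_channel Index (1-based, full array) of the layer-4 center.
#' @param touch_times Active-touch event times (s).
#' @param sink_latency_gradient Response latency increase per channel away
#'   from the layer-4 center (ms per channel).
#' @param sink_amplitude Peak negative deflection at the layer-4 center (mV).
#' @param sink_width_channels Spatial Gaussian width of the dipole (channels).
#' @param noise_sd Background noise SD (mV); 0 for a noiseless session.
#' @param duration Session length (s).
#' @param sample_rate LFP sampling rate (Hz).
#' @param seed Integer seed.
#' @return List of class `laminar_ground_truth`.
#' @export
laminar_ground_truth <- function(n_channels = 32L, channel_spacing = 25,
                                 true_l4_channel = 15L, touch_times = c(0.5, 1.5, 2.5),
                                 sink_latency_gradient = 0.8, sink_amplitude = 0.5,
                                 sink_width_channels = 2.5, noise_sd = 0,
                                 duration = NULL, sample_rate = 3000,
                                 seed = 1L) {
  if (is.null(duration)) {
    duration <- if (length(touch_times)) max(touch_times) + 0.5 else 2
  }
  if (true_l4_channel < 1L || true_l4_channel > n_channels) {
    stop("true_l4_channel must lie within the array")
  }
  if (length(touch_times) && (min(touch_times) < 0 || max(touch_times) > duration)) {
    stop("touch times must lie within the session")
  }
  structure(list(n_channels = as.integer(n_channels),
                 channel_spacing = channel_spacing,
                 true_l4_channel = as.integer(true_l4_channel),
                 touch_times = touch_times,
                 sink_latency_gradient = sink_latency_gradient,
                 sink_amplitude = sink_amplitude,
                 sink_width_channels = sink_width_channels,
                 noise_sd = noise_sd, duration = duration,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "laminar_ground_truth")
}

#' Simulate touch-evoked laminar LFP
#'
#' Each touch evokes a spatiotemporal dipole: the largest and earliest
#' negative deflection at the true layer-4 channel, with amplitude decaying
#' (spatial Gaussian) and latency growing linearly with channel distance.
#' Background noise is pink-ish (1/sqrt(f)-shaped). The noiseless field is
#' stored as ground truth.
#'
#' @param truth A [laminar_ground_truth()].
#' @return A [laminar_session()] with the `truth` field attached.
#' @export
simulate_laminar_lfp <- function(truth) {
  stopifnot(inherits(truth, "laminar_ground_truth"))
  fs <- truth$sample_rate
  n <- as.integer(round(truth$duration * fs))
  nc <- truth$n_channels
  t <- (seq_len(n) - 1L) / fs
  dist <- abs(seq_len(nc) - truth$true_l4_channel)
  amp <- truth$sink_amplitude * exp(-(dist / truth$sink_width_channels)^2 / 2)
  lat <- dist * truth$sink_latency_gradient / 1000
  pulse_sd <- 0.004                       # s; ~10 ms-wide touch response
  field <- matrix(0, nrow = nc, ncol = n)
  for (tt in truth$touch_times) {
    for (ch in seq_len(nc)) {
      center <- tt + 0.008 + lat[ch]
      field[ch, ] <- field[ch, ] - amp[ch] * exp(-((t - center) / pulse_sd)^2 / 2)
    }
  }
  lfp <- field
  if (truth$noise_sd > 0) {
    set.seed(derive_seed(truth$seed, "lfp"))
    f <- (seq_len(n) - 1L) * fs / n
    f <- pmin(f, fs - f)
    shape <- ifelse(f > 0, 1 / sqrt(pmax(f, 1)), 0)
    for (ch in seq_len(nc)) {
      x <- stats::rnorm(n)
      y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE) / n)
      lfp[ch, ] <- lfp[ch, ] + truth$noise_sd * y / stats::sd(y)
    }
  }
  depths <- 100 + (seq_len(nc) - 1L) * truth$channel_spacing
  ses <- laminar_session(lfp, channel_depths = depths, sample_rate = fs,
                         touch_times = truth$touch_times)
  ses$truth <- c(unclass(truth), list(field = field, channel_depths = depths))
  ses
}
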