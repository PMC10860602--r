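# Ground-truth generators: whisker traces, spike trains, Vm, laminar LFP.

test_that("whisker generator builds the scheduled bouts exactly", {
  bs <- data.frame(start_s = 2, end_s = 6, freq_hz = 10,
                   amplitude_deg = 10, midpoint_deg = 15)
  p <- whisk_gen_params(10, bout_schedule = bs, quiet_noise_sd = 0, seed = 1)
  sim <- simulate_whisker_trace(p)
  # value at a bout peak (phase0 = 0 at bout start) is midpoint + amplitude
  i_peak <- which.min(abs(sim$truth$time_s - 2.2))   # 2 full cycles in
  expect_equal(sim$trace$angle[i_peak], 25, tolerance = 1e-9)
  expect_true(all(sim$trace$angle[sim$truth$time_s < 2] == 10))

  flat <- simulate_whisker_trace(whisk_gen_params(5, quiet_noise_sd = 0))
  expect_true(all(flat$trace$angle == 10))

  # dominant DFT component of the bout segment sits at the bout frequency
  seg <- sim$trace$angle[sim$truth$whisking]
  seg <- seg - mean(seg)
  sp <- Mod(stats::fft(seg))[seq_len(length(seg) %/% 2)]
  f_axis <- (seq_along(sp) - 1) * 500 / length(seg)
  expect_lt(abs(f_axis[which.max(sp)] - 10), 0.3)
})

test_that("invalid bout schedules are rejected", {
  bad_overlap <- data.frame(start_s = c(1, 3), end_s = c(4, 6), freq_hz = 10,
                            amplitude_deg = 5, midpoint_deg = 10)
  expect_error(whisk_gen_params(10, bout_schedule = bad_overlap), "non-overlapping")
  bad_freq <- data.frame(start_s = 1, end_s = 2, freq_hz = 30,
                         amplitude_deg = 5, midpoint_deg = 10)
  expect_error(whisk_gen_params(10, bout_schedule = bad_freq), "4-25")
  bad_range <- data.frame(start_s = 8, end_s = 12, freq_hz = 10,
                          amplitude_deg = 5, midpoint_deg = 10)
  expect_error(whisk_gen_params(10, bout_schedule = bad_range), "within the sweep")
})

test_that("homogeneous Poisson units hit the nominal rate", {
  ses <- make_whisking_session(dur = 100, seed = 2)
  tr <- tuning_ground_truth(baseline_rate = 5)
  u <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking, tr, seed = 3)
  n <- length(u$spike_times)
  se <- sqrt(5 * 100)
  expect_lt(abs(n - 500), 3 * se)
})

test_that("light-on suppression scales the rate by the stated factor", {
  ses <- make_whisking_session(dur = 100, seed = 4)
  quiet_mask <- rep(FALSE, length(ses$decomp$phase))   # quiet only: no gains
  tr <- tuning_ground_truth(baseline_rate = 10, light_suppression = 0.95)
  u <- simulate_spike_train(ses$decomp, quiet_mask, tr, light_on = TRUE, seed = 5)
  # oracle: mean of the returned rate profile
  lam_mean <- mean(u$truth$lambda_hz)
  expect_equal(lam_mean, 0.5, tolerance = 1e-9)
  n <- length(u$spike_times)
  expect_lt(abs(n - 50), 4 * sqrt(50))
})

test_that("phase-tuned spikes concentrate at the preferred phase", {
  ses <- make_whisking_session(dur = 300, seed = 6)
  tr <- tuning_ground_truth(baseline_rate = 5, phase_kappa = 2,
                            preferred_phase = 1)
  u <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking, tr, seed = 7)
  idx <- pmax(1L, floor(u$spike_times * 500) + 1L)
  spike_phase <- ses$decomp$phase[idx]
  # oracle: circular mean of the rate-weighted phase distribution
  lam <- u$truth$lambda_hz
  oracle <- Arg(sum(lam * exp(1i * ses$decomp$phase), na.rm = TRUE))
  expect_lt(abs(circ_diff(circ_mean(spike_phase), 1)), 0.2)
  expect_lt(abs(circ_diff(circ_mean(spike_phase), oracle)), 0.2)
})

test_that("spike counts match the rate integral within 4 SE across seeds", {
  ses <- make_whisking_session(dur = 120, seed = 8)
  tr <- tuning_ground_truth(baseline_rate = 6, whisking_gain = 2,
                            phase_kappa = 1, preferred_phase = 0.5)
  for (seed in 1:4) {
    u <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking, tr, seed = seed)
    expected <- sum(u$truth$lambda_hz) / 500
    expect_lt(abs(length(u$spike_times) - expected), 4 * sqrt(expected))
  }
})

test_that("generators are bit-reproducible for a fixed seed", {
  p <- whisk_gen_params(10, bout_schedule = data.frame(
    start_s = 2, end_s = 8, freq_hz = 11, amplitude_deg = 9, midpoint_deg = 14),
    seed = 42)
  expect_identical(simulate_whisker_trace(p), simulate_whisker_trace(p))
  ses <- make_whisking_session(dur = 20, seed = 9)
  tr <- tuning_ground_truth(baseline_rate = 8, phase_kappa = 1)
  u1 <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking, tr, seed = 11)
  u2 <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking, tr, seed = 11)
  expect_identical(u1$spike_times, u2$spike_times)
  vt <- vm_ground_truth(seed = 12)
  m <- resample_to(ses$sim$truth$whisking, 20 * 2000)
  ph <- resample_to(ses$sim$truth$phase, 20 * 2000)
  v1 <- simulate_vm_trace(NULL, m, vt, sample_rate = 2000, phase = ph)
  v2 <- simulate_vm_trace(NULL, m, vt, sample_rate = 2000, phase = ph)
  expect_identical(v1$vm, v2$vm)
  lt <- laminar_ground_truth(noise_sd = 0.05, seed = 13)
  expect_identical(simulate_laminar_lfp(lt)$lfp, simulate_laminar_lfp(lt)$lfp)
})

test_that("Vm generator produces the requested subthreshold structure", {
  n <- 20 * 2000
  mask <- rep(c(FALSE, TRUE), each = n / 2)
  phase <- wrap_angle(2 * pi * 10 * (seq_len(n) - 1) / 2000)
  # all modulation off, no noise -> constant at rest
  vt0 <- vm_ground_truth(slow_wave_sd_quiet = 0, slow_wave_sd_whisk = 0,
                         whisk_depol = 0, phase_lock_amp = 0, noise_sd = 0)
  r0 <- simulate_vm_trace(NULL, mask, vt0, sample_rate = 2000, phase = phase)
  expect_true(all(r0$vm == -60))

  # pure phase locking: peak-to-trough of the phase average is 2 x amplitude
  vt1 <- vm_ground_truth(slow_wave_sd_quiet = 0, slow_wave_sd_whisk = 0,
                         whisk_depol = 0, phase_lock_amp = 2, noise_sd = 0)
  r1 <- simulate_vm_trace(NULL, mask, vt1, sample_rate = 2000, phase = phase)
  pl <- phase_locked_vm(r1, phase, mask)
  expect_equal(pl$depth_mv, 4, tolerance = 0.01)

  # slow-wave SD contrast appears in the 1-5 Hz band integrals
  vt2 <- vm_ground_truth(slow_wave_sd_quiet = 4, slow_wave_sd_whisk = 1,
                         whisk_depol = 0, phase_lock_amp = 0, noise_sd = 0,
                         seed = 3)
  r2 <- simulate_vm_trace(NULL, mask, vt2, sample_rate = 2000, phase = phase)
  ep <- structure(list(epochs = data.frame(
    label = c("quiet", "whisking"), start_s = c(0, 10), end_s = c(10, 20),
    onset_s = NA), sweep_id = 1), class = "epoch_set")
  fb <- vm_band_fft(detect_and_clean_spikes(r2), ep)
  ratio <- fb$band_integral$quiet / fb$band_integral$whisking
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.6)
})

test_that("laminar generator places the sink at the true layer-4 channel", {
  lt <- laminar_ground_truth(noise_sd = 0, true_l4_channel = 15)
  ses <- simulate_laminar_lfp(lt)
  # channel with the minimum LFP value at the response peak
  expect_equal(which(ses$lfp == min(ses$lfp), arr.ind = TRUE)[1, "row"],
               c(row = 15))
  # independent finite-difference oracle on the analytic noiseless field:
  # most negative -d2V/dz2 among interior odd-column channels at the peak
  odd <- seq(1, 31, by = 2)
  tpk <- which.min(ses$truth$field[15, ])
  v <- ses$truth$field[odd, tpk]
  d2 <- -(v[1:14] - 2 * v[2:15] + v[3:16])
  expect_equal(odd[1 + which.min(d2)], 15)
})

test_that("a touch-free laminar session fails localization gracefully", {
  lt <- laminar_ground_truth(noise_sd = 0.05, touch_times = numeric(0),
                             duration = 2)
  ses <- simulate_laminar_lfp(lt)
  loc <- locate_layer4(ses)
  expect_true(loc$failed)
  expect_true(is.na(loc$l4_channel))
})
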