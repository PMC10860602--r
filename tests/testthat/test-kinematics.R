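# Whisker kinematic decomposition and epoch segmentation.

fs <- 500

test_that("band-pass keeps in-band and rejects out-of-band components", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  in_band <- whisker_trace(sin(2 * pi * 10 * t), fs)
  out_band <- whisker_trace(sin(2 * pi * 0.5 * t), fs)
  y_in <- bandpass_whisker(in_band)$angle
  y_out <- bandpass_whisker(out_band)$angle
  core <- seq(2 * fs, 8 * fs)   # away from edges
  expect_gt(max(abs(y_in[core])), 0.95)
  expect_lt(max(abs(y_in[core])), 1.05)
  expect_lt(max(abs(y_out[core])), 0.1)

  mix <- whisker_trace(sin(2 * pi * 10 * t) + 2 * sin(2 * pi * 0.5 * t), fs)
  y_mix <- bandpass_whisker(mix)$angle
  oracle <- dft_mask_oracle(mix$angle, fs, 4, 25)
  expect_gt(stats::cor(y_mix[core], sin(2 * pi * 10 * t)[core]), 0.99)
  expect_gt(stats::cor(y_mix[core], oracle[core]), 0.99)
})

test_that("band-pass rejects traces shorter than 1 s", {
  expect_error(bandpass_whisker(whisker_trace(rnorm(100), fs)), "shorter")
})

test_that("Hilbert phase is zero at protraction peaks and tracks a chirp", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tr <- whisker_trace(cos(2 * pi * 8 * t), fs)
  hp <- hilbert_phase(tr)
  expect_false(hp$degenerate)
  core <- seq(fs, 9 * fs)
  expect_lt(max(abs(circ_diff(hp$phase[core], wrap_angle(2 * pi * 8 * t[core])))),
            0.03)
  # peaks of the cosine are at integer multiples of 1/8 s
  peaks <- which(abs(t %% (1 / 8)) < 1e-9 & t > 1 & t < 9)
  expect_lt(max(abs(hp$phase[peaks])), 0.05)

  flat <- hilbert_phase(whisker_trace(rep(3, 2 * fs), fs))
  expect_true(flat$degenerate)

  # chirp 6 -> 20 Hz: instantaneous phase = 2 pi (6 t + 0.7 t^2)
  f0 <- 6; k <- 1.4
  chirp_phase <- 2 * pi * (f0 * t + k * t^2 / 2)
  ch <- whisker_trace(cos(chirp_phase), fs)
  hpc <- hilbert_phase(ch)
  got <- unwrap_phase(hpc$phase[core])
  want <- chirp_phase[core]
  err <- got - want
  err <- err - mean(err)   # common 2 pi k offset from unwrapping origin
  expect_lt(max(abs(err)), 0.05)
})

test_that("decomposition recovers amplitude and midpoint from the defining formula", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  # protracted extreme 20 deg, retracted extreme 10 deg -> amp 5, mid 15
  tr <- whisker_trace(15 + 5 * cos(2 * pi * 10 * t), fs)
  d <- decompose_whisking(tr)
  core <- seq(2 * fs, 8 * fs)
  expect_lt(max(abs(d$amplitude[core] - 5)), 0.3)
  expect_lt(max(abs(d$midpoint[core] - 15)), 0.3)

  tr2 <- whisker_trace(15 + 10 * cos(2 * pi * 10 * t), fs)
  d2 <- decompose_whisking(tr2)
  expect_lt(max(abs(d2$amplitude[core] - 10)), 0.5)
  expect_lt(max(abs(d2$midpoint[core] - 15)), 0.5)
})

test_that("decomposition tracks a linearly ramping amplitude within 10% RMS", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  a_true <- 5 + 0.5 * t                  # 5 -> 10 deg
  tr <- whisker_trace(15 + a_true * cos(2 * pi * 10 * t), fs)
  d <- decompose_whisking(tr)
  core <- seq(fs, 9 * fs)
  rms <- sqrt(mean((d$amplitude[core] - a_true[core])^2))
  expect_lt(rms, 0.1 * mean(a_true))
})

test_that("too few phase events flags amplitude undefined", {
  tr <- whisker_trace(rep(12, 2 * fs), fs)
  d <- decompose_whisking(tr)
  expect_true(d$undefined_amplitude)
  expect_true(all(is.na(d$amplitude)))
})

test_that("setpoint is the slow envelope of the angle", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(compute_setpoint(whisker_trace(rep(12, length(t)), fs)),
               rep(12, length(t)), tolerance = 1e-6)
  sp <- compute_setpoint(whisker_trace(15 + 10 * cos(2 * pi * 10 * t), fs))
  core <- seq(2 * fs, 8 * fs)
  expect_lt(max(abs(sp[core] - 15)), 1)      # ripple < 10% of amplitude
  drift <- 3 * sin(2 * pi * 1 * t)
  tr <- whisker_trace(15 + drift + 8 * cos(2 * pi * 12 * t), fs)
  sp2 <- compute_setpoint(tr)
  oracle <- 15 + dft_mask_oracle(drift, fs, 0.2, 6)
  rms <- sqrt(mean((sp2[core] - oracle[core])^2))
  expect_lt(rms, 0.1 * sqrt(mean(drift^2)))
})

test_that("epoch segmentation labels quiet and whisking and finds the 1-degree onset", {
  n <- 10 * fs
  ang <- rep(10, n)
  t <- (seq_len(n) - 1) / fs
  bout <- t >= 5 & t < 10
  ang[bout] <- 15 + 10 * cos(2 * pi * 10 * (t[bout] - 5))
  tr <- whisker_trace(ang, fs)
  ep <- segment_epochs(tr)
  labs <- ep$epochs$label
  expect_true("quiet" %in% labs && "whisking" %in% labs)
  expect_true(all(ep$epochs$end_s[labs == "quiet"] <= 5.5))
  # oracle: direct scan of the noiseless trace for baseline + 1 crossing
  baseline <- 10
  truth_onset <- t[which(ang > baseline + 1)[1]]
  got <- ep$epochs$onset_s[labs == "whisking"][1]
  expect_lt(abs(got - truth_onset), 2 / fs + 1e-9)

  quiet <- segment_epochs(whisker_trace(rep(10, n) + 0.05 * sin(2 * pi * 7 * t), fs))
  expect_false("whisking" %in% quiet$epochs$label)
})

test_that("onset on a linear ramp sits at the first threshold crossing", {
  n <- 8 * fs
  t <- (seq_len(n) - 1) / fs
  ang <- rep(10, n)
  ramp <- t >= 3 & t < 4
  ang[ramp] <- 10 + 5 * (t[ramp] - 3)
  bout <- t >= 4
  ang[bout] <- 15 + 10 * cos(2 * pi * 10 * (t[bout] - 4))
  ep <- segment_epochs(whisker_trace(ang, fs))
  got <- ep$epochs$onset_s[ep$epochs$label == "whisking"][1]
  truth <- t[which(ang - 10 > 1)[1]]    # threshold definition, by direct scan
  expect_false(is.na(got))
  expect_lt(abs(got - truth), 2 / fs + 1e-9)
})

test_that("per-epoch summaries match analytic cycle statistics", {
  ses <- make_whisking_session(dur = 30, seed = 2, freqs = rep(10, 3),
                               amps = rep(10, 3), mids = rep(15, 3))
  # interior epoch: the first/last second of a sweep carries filter edge effects
  ses$epochs$epochs$start_s <- 1
  ses$epochs$epochs$end_s <- 29
  ks <- kinematic_summaries(ses$decomp, ses$epochs, ses$trace)
  expect_equal(nrow(ks), 1L)
  expect_lt(abs(ks$cycle_duration - 0.1), 1 / fs + 1e-9)
  # peak speed of A cos(2 pi f t) is 2 pi f A
  expect_lt(abs(ks$protraction_speed - 2 * pi * 10 * 10) / (2 * pi * 10 * 10), 0.05)
  expect_lt(abs(ks$retraction_speed - 2 * pi * 10 * 10) / (2 * pi * 10 * 10), 0.05)
  expect_lt(ks$midpoint_excursion, 1)   # constant-midpoint bout
})

test_that("reconstruction from the decomposition matches the raw trace", {
  ses <- make_whisking_session(dur = 20, seed = 3)
  rec <- reconstruct_whisker(ses$decomp, ses$trace)
  expect_lt(rec$rms_error, 0.1 * mean(ses$sim$truth$amplitude))
  # zero amplitude everywhere -> reconstruction equals the midpoint
  d0 <- ses$decomp
  d0$amplitude[] <- 0
  expect_equal(reconstruct_whisker(d0)$angle, d0$midpoint, tolerance = 1e-12)
})

test_that("amplitude is shift-invariant; midpoint and setpoint shift with the trace", {
  ses <- make_whisking_session(dur = 20, seed = 4)
  shifted <- ses$trace
  shifted$angle <- shifted$angle + 7
  d1 <- ses$decomp
  d2 <- decompose_whisking(shifted)
  core <- seq(2 * fs, 18 * fs)
  expect_lt(max(abs(d1$amplitude[core] - d2$amplitude[core])), 1e-6)
  expect_lt(max(abs((d2$midpoint[core] - d1$midpoint[core]) - 7)), 1e-6)
  expect_lt(max(abs((d2$setpoint[core] - d1$setpoint[core]) - 7)), 1e-6)
})

test_that("time reversal swaps protraction and retraction speeds on symmetric whisks", {
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  ang <- 15 + 10 * cos(2 * pi * 10 * t)
  tr_f <- whisker_trace(ang, fs)
  tr_r <- whisker_trace(rev(ang), fs)
  ep <- structure(list(epochs = data.frame(label = "whisking", start_s = 1,
                                           end_s = 11, onset_s = 1),
                       sweep_id = 1L), class = "epoch_set")
  kf <- kinematic_summaries(decompose_whisking(tr_f), ep, tr_f)
  kr <- kinematic_summaries(decompose_whisking(tr_r), ep, tr_r)
  expect_lt(abs(kf$protraction_speed - kr$retraction_speed) / kf$protraction_speed, 0.02)
  expect_lt(abs(kf$retraction_speed - kr$protraction_speed) / kf$retraction_speed, 0.02)
})

test_that("decomposition recovers generator bouts within 10% RMS across seeds", {
  for (seed in 1:3) {
    ses <- make_whisking_session(dur = 30, seed = seed)
    i <- which(ses$sim$truth$whisking)
    i <- i[i > 2 * fs & i < length(ses$decomp$phase) - 2 * fs]
    amp_rms <- sqrt(mean((ses$decomp$amplitude[i] - ses$sim$truth$amplitude[i])^2))
    mid_rms <- sqrt(mean((ses$decomp$midpoint[i] - ses$sim$truth$midpoint[i])^2))
    phase_rms <- sqrt(mean(circ_diff(ses$decomp$phase[i], ses$sim$truth$phase[i])^2))
    expect_lt(amp_rms, 0.1 * mean(ses$sim$truth$amplitude[i]))
    expect_lt(mid_rms, 0.1 * mean(ses$sim$truth$midpoint[i]))
    expect_lt(phase_rms, 0.35)
  }
})

test_that("protraction and retraction events alternate and sit at phase 0 / pi", {
  ses <- make_whisking_session(dur = 20, seed = 5)
  d <- ses$decomp
  expect_lt(max(abs(d$phase[d$protraction_events])), 0.15)
  expect_gt(min(abs(d$phase[d$retraction_events])), pi - 0.2)
  ev <- sort(c(d$protraction_events, d$retraction_events))
  kind <- ev %in% d$protraction_events
  expect_true(all(kind[-1] != kind[-length(kind)]))
})

test_that("inverted sign convention recovers the same amplitude", {
  ses <- make_whisking_session(dur = 20, seed = 6)
  inv <- ses$trace
  inv$angle <- -inv$angle
  d_inv <- decompose_whisking(inv, whiskephys_config(protraction_positive = FALSE))
  core <- seq(2 * fs, 18 * fs)
  expect_lt(max(abs(d_inv$amplitude[core] - ses$decomp$amplitude[core])), 1e-6)
  expect_lt(max(abs(d_inv$midpoint[core] + ses$decomp$midpoint[core])), 1e-6)
})
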