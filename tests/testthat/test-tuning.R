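# Equal-probability binning, tuning histograms, spline smoothing, the
# two-step shuffle significance test, and modulation statistics.

test_that("equal-probability bins hold equal counts within one sample", {
  set.seed(1)
  # uniform phase: edges near-evenly spaced
  ph <- runif(5000, -pi, pi)
  b <- equal_probability_bins(ph, 50, range = c(-pi, pi))
  expect_equal(b$n_bins, 50)
  expect_lt(max(abs(diff(b$edges) - 2 * pi / 50)), 4 / sqrt(5000))
  cnt <- table(cut(ph, b$edges))
  expect_lte(max(cnt) - min(cnt), 2)

  # 50 distinct values into 50 bins: exactly one per bin
  x <- sort(rnorm(50))
  b50 <- equal_probability_bins(x, 50)
  expect_true(all(table(cut(x, b50$edges)) == 1))

  # skewed distribution: counts within +/-1 of a brute-force sort-and-split
  sk <- rexp(3173)
  bs <- equal_probability_bins(sk, 50)
  cnt <- as.integer(table(cut(sk, bs$edges)))
  oracle <- diff(c(0, floor(seq_len(49) * 3173 / 50), 3173))  # explicit split
  expect_lte(max(abs(cnt - oracle)), 1)

  # heavy ties collapse edges and set the merged flag
  tied <- c(rep(1, 500), rep(2, 500))
  bt <- equal_probability_bins(tied, 50)
  expect_true(bt$merged)
  expect_lt(bt$n_bins, 50)
})

test_that("tuning histogram puts spikes in the occupied bins only", {
  ses <- make_whisking_session(dur = 120, seed = 2)
  des <- tuning_design(ses$decomp, ses$epochs, "phase")
  expect_equal(sum(des$occupancy_s), sum(is.finite(ses$decomp$phase[
    whiskephys:::epoch_mask(ses$epochs, "whisking", length(ses$decomp$phase), 500)])) / 500,
    tolerance = 1e-9)

  # homogeneous unit: every bin within 4 SE of the true rate
  u <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking,
                            tuning_ground_truth(baseline_rate = 8), seed = 3)
  h <- tuning_histogram(u$spike_times, des)
  se <- sqrt(8 / des$occupancy_s)
  expect_true(all(abs(h$raw_rates - 8) < 4.5 * se))

  # spikes manufactured only where phase falls in bin 7
  in7 <- which(des$sample_bin == 7L)
  st <- (in7[seq(1, length(in7), by = 4)] - 0.5) / 500
  h7 <- tuning_histogram(st, des)
  expect_true(all(h7$raw_rates[-7] == 0))
  expect_gt(h7$raw_rates[7], 0)

  # von Mises-tuned unit correlates with the generator rate profile
  ut <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking,
                             tuning_ground_truth(baseline_rate = 8, phase_kappa = 2,
                                                 preferred_phase = -1), seed = 4)
  ht <- tuning_histogram(ut$spike_times, des)
  lam_bin <- vapply(seq_len(des$n_bins), function(bb) {
    mean(ut$truth$lambda_hz[which(des$sample_bin == bb)])
  }, numeric(1))
  expect_gt(cor(ht$raw_rates, lam_bin), 0.9)
})

test_that("group-sum ANOVA F matches the reference implementation", {
  set.seed(5)
  y <- rnorm(400)
  g <- sample(1:8, 400, replace = TRUE)
  n_per <- tabulate(g, 8)
  gs <- as.numeric(rowsum(y, g))
  sst <- sum(y^2) - 400 * mean(y)^2
  f_mine <- whiskephys:::anova_f_stat(y, gs, n_per, sst, 400, 8)
  f_ref <- stats::oneway.test(y ~ factor(g), var.equal = TRUE)$statistic
  expect_equal(f_mine, unname(f_ref), tolerance = 1e-10)
})

test_that("spline smoothing preserves flat curves and locates peaks", {
  ses <- make_whisking_session(dur = 120, seed = 6)
  des <- tuning_design(ses$decomp, ses$epochs, "phase")
  flat <- smooth_tuning_curve(rep(5, des$n_bins), des)
  expect_lt(flat$max - flat$min, 0.05 * 5)

  shaped <- 5 + 4 * cos(des$bin_centers - 0.8)
  sm <- smooth_tuning_curve(shaped, des)
  bin_w <- 2 * pi / des$n_bins
  expect_lt(abs(circ_diff(sm$preferred, 0.8)), bin_w + 1e-9)

  zero <- smooth_tuning_curve(rep(0, des$n_bins), des)
  expect_true(zero$flat)
  expect_true(all(zero$y == 0))
})

test_that("smoothed peak recovers the preferred phase across seeded units", {
  ses <- make_whisking_session(dur = 300, seed = 7)
  des <- tuning_design(ses$decomp, ses$epochs, "phase")
  hits <- 0L
  n_runs <- 20L
  for (s in seq_len(n_runs)) {
    u <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking,
                              tuning_ground_truth(baseline_rate = 5, phase_kappa = 2,
                                                  preferred_phase = 1.2),
                              seed = 100 + s)
    sm <- smooth_tuning_curve(tuning_histogram(u$spike_times, des)$raw_rates, des)
    if (abs(circ_diff(sm$preferred, 1.2)) < 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_runs)
})

test_that("two-step test detects strong tuning and skips flat responses", {
  ses <- make_whisking_session(dur = 300, seed = 8)
  des <- tuning_design(ses$decomp, ses$epochs, "phase")
  u <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking,
                            tuning_ground_truth(baseline_rate = 10, phase_kappa = 2),
                            seed = 9)
  tt <- test_tuning(u$spike_times, des, seed = 10)
  expect_true(tt$tuned)
  expect_lte(tt$p_shuffle, 1 / 1000)

  # zero spikes: no variance across bins, ANOVA cannot fire
  t0 <- test_tuning(numeric(0), des, seed = 10)
  expect_false(t0$tuned)
  expect_true(is.na(t0$p_shuffle))   # shuffle step skipped

  # visits too sparse to test
  tiny <- make_whisking_session(dur = 2, seed = 11)
  ep1 <- tiny$epochs
  des_tiny <- tuning_design(tiny$decomp, ep1, "phase",
                            whiskephys_config(n_tuning_bins = 50L))
  if (des_tiny$n_visits / des_tiny$n_bins < 2) {
    expect_true(test_tuning(c(0.5, 1), des_tiny)$untestable)
  }
})

test_that("modulation depth and index follow their defining formulas", {
  curve <- list(max = 10, min = 2, preferred = 0.3, flat = FALSE)
  cs <- curve_statistics(curve, baseline_rate = 4)
  expect_equal(cs$modulation_depth, 2)
  expect_equal(cs$modulation_index, 8 / 12)
  flat <- curve_statistics(list(max = 5, min = 5, preferred = NA, flat = TRUE), 5)
  expect_equal(flat$modulation_depth, 0)
  expect_equal(flat$modulation_index, 0)
  nob <- curve_statistics(curve, baseline_rate = 0)
  expect_true(is.na(nob$modulation_depth))

  # index is scale-invariant; depth scales inversely with baseline
  for (c_scale in c(0.5, 2, 10)) {
    sc <- list(max = 10 * c_scale, min = 2 * c_scale, preferred = 0.3, flat = FALSE)
    expect_equal(curve_statistics(sc, 4)$modulation_index, 8 / 12)
  }
  expect_equal(curve_statistics(curve, 8)$modulation_depth,
               curve_statistics(curve, 4)$modulation_depth / 2)
})

test_that("modulation index of a generated unit matches the analytic value", {
  ses <- make_whisking_session(dur = 300, seed = 12)
  des <- tuning_design(ses$decomp, ses$epochs, "phase")
  kappa <- 2
  u <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking,
                            tuning_ground_truth(baseline_rate = 8, phase_kappa = kappa),
                            seed = 13)
  sm <- smooth_tuning_curve(tuning_histogram(u$spike_times, des)$raw_rates, des)
  cs <- curve_statistics(sm, 8)
  # analytic index of lambda(phase) = tanh(kappa)
  expect_lt(abs(cs$modulation_index - tanh(kappa)), 0.1)
})

test_that("preferred-phase shifts wrap consistently", {
  ident <- phase_shift_report(c(0.5, -1, 2), c(0.5, -1, 2))
  expect_true(all(ident$shift == 0))
  expect_equal(ident$p, 1)
  rot <- phase_shift_report(c(0, 1, -2), wrap_angle(c(0, 1, -2) + pi / 2))
  expect_true(all(abs(rot$shift - pi / 2) < 1e-12))
  # wrap equivalence against a brute-force wrapping table
  offs <- seq(-3.5, 3.5, by = 0.25)
  for (a in c(-3, -1, 0, 2)) {
    got <- phase_shift_report(rep(a, length(offs)), wrap_angle(a + offs))$shift
    oracle <- atan2(sin(offs), cos(offs))   # independent minimal-angle formula
    oracle[oracle == -pi] <- pi
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("tuning_curve bundles histogram, smoothing, test and statistics", {
  ses <- make_whisking_session(dur = 200, seed = 14)
  des <- tuning_design(ses$decomp, ses$epochs, "phase")
  u <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking,
                            tuning_ground_truth(baseline_rate = 6, phase_kappa = 1.5,
                                                preferred_phase = -0.7),
                            seed = 15)
  tr <- tuning_curve(u, des, baseline_rate = 6, seed = 16)
  expect_s3_class(tr, "tuning_result")
  expect_true(tr$tuned)
  expect_lt(abs(circ_diff(tr$preferred_value, -0.7)), 0.3)
  expect_gte(tr$modulation_index, 0)
  expect_lte(tr$modulation_index, 1)
  expect_output(print(tr), "tuned")
})

test_that("amplitude and midpoint tuning designs work on bout-structured sweeps", {
  ses <- make_whisking_session(dur = 200, seed = 17,
                               amps = c(4, 7, 10, 13, 9, 6),
                               mids = c(10, 13, 16, 19, 12, 15))
  for (v in c("amplitude", "midpoint")) {
    des <- tuning_design(ses$decomp, ses$epochs, v)
    u <- simulate_spike_train(ses$decomp, ses$sim$truth$whisking,
                              tuning_ground_truth(baseline_rate = 5,
                                                  amp_slope = if (v == "amplitude") 0.15 else 0,
                                                  mid_slope = if (v == "midpoint") 0.15 else 0),
                              seed = 18)
    h <- tuning_histogram(u$spike_times, des)
    # rate should increase with the variable: positive rank correlation
    expect_gt(cor(des$bin_centers, h$raw_rates, method = "spearman"), 0.5)
  }
})
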