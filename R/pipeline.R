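# Session orchestration: synthetic session -> kinematics -> spikes / tuning
# / Vm / LFP stages, light-off vs light-on comparisons, and a deterministic
# report bundle.

#' Compare paired values between light conditions
#'
#' Normality of the paired differences is checked with a Shapiro-Wilk test;
#' a paired t test is used when the differences look Gaussian, otherwise a
#' Wilcoxon signed-rank test. The chosen test, its p-value and summary
#' quartiles are all reported.
#'
#' @param values_off,values_on Paired numeric vectors (one value per item,
#'   e.g. per cell).
#' @param alpha Level of the normality check (default 0.05).
#' @return Object of class `condition_comparison`: `test` (`"paired-t"` or
#'   `"signed-rank"`), `normality_p`, `p`, and per-condition medians and
#'   quartiles.
#' @export
compare_conditions <- function(values_off, values_on, alpha = 0.05) {
  stopifnot(length(values_off) == length(values_on))
  ok <- is.finite(values_off) & is.finite(values_on)
  off <- values_off[ok]; on <- values_on[ok]
  if (length(off) < 2L) stop("need at least 2 complete pairs")
  d <- on - off
  norm_p <- if (length(unique(d)) < 3L) 0 else
    tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
  if (all(d == 0)) {
    test <- "signed-rank"; p <- 1
  } else if (norm_p > alpha) {
    test <- "paired-t"
    p <- stats::t.test(on, off, paired = TRUE)$p.value
  } else {
    test <- "signed-rank"
    p <- suppressWarnings(stats::wilcox.test(on, off, paired = TRUE)$p.value)
  }
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(test = test, normality_p = norm_p, p = p, n = length(off),
                 summary_off = qs(off), summary_on = qs(on),
                 median_difference = stats::median(d)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("condition_comparison (n = %d): %s, p = %.4g (normality p = %.3g)\n",
              x$n, x$test, x$p, x$normality_p))
  cat(sprintf("  OFF median %.3g [%.3g, %.3g]; ON median %.3g [%.3g, %.3g]\n",
              x$summary_off[2], x$summary_off[1], x$summary_off[3],
              x$summary_on[2], x$summary_on[1], x$summary_on[3]))
  invisible(x)
}

# Default synthetic session layout: a 60 s sweep (filming sweeps run about a
# minute) alternating quiet periods and whisking bouts (8-12 Hz, 8-14 deg).
default_bout_schedule <- function(sweep_duration = 60) {
  starts <- seq(4, sweep_duration - 6, by = 8)
  data.frame(start_s = starts, end_s = starts + 4,
             freq_hz = rep(c(8, 10, 12), length.out = length(starts)),
             amplitude_deg = rep(c(10, 8, 14), length.out = length(starts)),
             midpoint_deg = rep(c(15, 12, 18), length.out = length(starts)))
}

#' Run the full synthetic-session pipeline
#'
#' Generates one light-off and one light-on synthetic sweep (whisker trace,
#' a cohort of tuned/untuned units, one whole-cell Vm per condition, one
#' laminar LFP session), runs every analysis stage, and writes the result
#' tables to `out_dir`: kinematics and epochs CSVs, a per-unit results
#' table (cell class, whisking-modulation category, light-modulation
#' index), a per-unit phase-tuning table, Vm statistics, the layer-4
#' localization JSON, and a provenance record. Deterministic for a fixed
#' config seed.
#'
#' @param config A [whiskephys_config()].
#' @param out_dir Output directory (created if missing).
#' @param n_units Number of simulated units per condition.
#' @param sweep_duration Sweep length in seconds.
#' @return Invisibly, a list with the in-memory results.
#' @export
run_session <- function(config = whiskephys_config(), out_dir, n_units = 6L,
                        sweep_duration = 60) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- behavior (shared across conditions) -------------------------------
  wp <- whisk_gen_params(sweep_duration, bout_schedule = default_bout_schedule(sweep_duration),
                         seed = seed)
  sim <- simulate_whisker_trace(wp)
  trace <- sim$trace
  decomp <- decompose_whisking(trace, config)
  epochs <- segment_epochs(trace, config, decomp)
  write_whisker_csv(trace, file.path(out_dir, "whisker_trace.csv"))
  write_decomposition_csv(decomp, file.path(out_dir, "kinematics.csv"))
  write_epochs_csv(epochs, file.path(out_dir, "epochs.csv"))

  # --- units: alternating whisking-excited, -inhibited, untuned ----------
  gains <- rep(c(3, 0.4, 1), length.out = n_units)
  kappas <- rep(c(1.5, 0, 0.8), length.out = n_units)
  ttps <- rep(c(0.7, 0.3, 0.8), length.out = n_units)
  mask <- sim$truth$whisking
  units_off <- list(); units_on <- list()
  for (i in seq_len(n_units)) {
    tr <- tuning_ground_truth(baseline_rate = 6, whisking_gain = gains[i],
                              phase_kappa = kappas[i],
                              preferred_phase = wrap_angle(i * pi / 3),
                              light_suppression = 0.8)
    units_off[[i]] <- simulate_spike_train(decomp, mask, tr, light_on = FALSE,
                                           seed = seed + i, unit_id = sprintf("u%02d", i),
                                           trough_to_peak_ms = ttps[i])
    units_on[[i]] <- simulate_spike_train(decomp, mask, tr, light_on = TRUE,
                                          seed = seed + 1000L + i,
                                          unit_id = sprintf("u%02d", i),
                                          trough_to_peak_ms = ttps[i])
  }
  write_spikes_csv(units_off, file.path(out_dir, "spikes_off.csv"), sweep_id = "off")
  write_spikes_csv(units_on, file.path(out_dir, "spikes_on.csv"), sweep_id = "on")

  wmod <- classify_whisk_modulation(units_off, epochs, config)
  wmod$cell_class <- vapply(units_off, classify_cell_type, character(1),
                            config = config)
  rate_off <- vapply(units_off, function(u) length(u$spike_times) / u$sweep_duration,
                     numeric(1))
  rate_on <- vapply(units_on, function(u) length(u$spike_times) / u$sweep_duration,
                    numeric(1))
  wmod$light_mod_index <- mapply(light_modulation_index, rate_on, rate_off)
  utils::write.csv(wmod, file.path(out_dir, "unit_results.csv"), row.names = FALSE)

  design <- tuning_design(decomp, epochs, "phase", config)
  tun <- lapply(seq_len(n_units), function(i) {
    tr <- tuning_curve(units_off[[i]], design,
                       baseline_rate = wmod$quiet_rate_hz[i], config,
                       seed = seed + i)
    data.frame(unit_id = tr$unit_id, variable = tr$variable, tuned = tr$tuned,
               p_anova = tr$p_anova, p_shuffle = tr$p_shuffle,
               f_observed = tr$f_observed,
               modulation_depth = tr$modulation_depth,
               modulation_index = tr$modulation_index,
               preferred_value = tr$preferred_value)
  })
  tuning_tab <- do.call(rbind, c(tun, list(make.row.names = FALSE)))
  utils::write.csv(tuning_tab, file.path(out_dir, "tuning_results.csv"),
                   row.names = FALSE)

  # --- membrane potential, one cell per condition ------------------------
  vm_fs <- 2000
  nvm <- as.integer(sweep_duration * vm_fs)
  ridx <- pmin(length(mask), pmax(1L, ceiling(seq_len(nvm) * (length(mask) / nvm))))
  vm_mask <- mask[ridx]
  vm_phase <- sim$truth$phase[ridx]
  vm_rows <- list()
  for (cond in c("OFF", "ON")) {
    vt <- vm_ground_truth(whisk_depol = if (cond == "OFF") 3 else 1,
                          phase_lock_amp = 1.5,
                          seed = seed + ifelse(cond == "OFF", 7L, 8L))
    rec <- simulate_vm_trace(NULL, vm_mask, vt, sample_rate = vm_fs,
                             phase = vm_phase)
    rec$light_condition <- cond
    rec <- detect_and_clean_spikes(rec, config)
    st <- epoch_vm_stats(rec, epochs)
    fb <- vm_band_fft(rec, epochs, config)
    pl <- phase_locked_vm(rec, vm_phase, vm_mask, config)
    vm_rows[[cond]] <- data.frame(
      cell_id = rec$cell_id, condition = cond,
      d_vm = st$deltas$d_vm, d_ap = st$deltas$d_ap,
      d_variance = st$deltas$d_variance,
      band_integral_quiet = fb$band_integral$quiet,
      band_integral_whisk = fb$band_integral$whisking,
      pl_depth_mv = pl$depth_mv, pl_phase = pl$preferred_phase)
  }
  utils::write.csv(do.call(rbind, c(vm_rows, list(make.row.names = FALSE))),
                   file.path(out_dir, "vm_results.csv"), row.names = FALSE)

  # --- laminar LFP -------------------------------------------------------
  lt <- laminar_ground_truth(noise_sd = 0.02, seed = seed + 11L,
                             touch_times = c(0.5, 1.2, 1.9, 2.6))
  ses <- preprocess_lfp(simulate_laminar_lfp(lt), config$lfp_rate_csd,
                        config$lfp_cutoff)
  loc <- locate_layer4(ses, "odd", config)
  jsonlite::write_json(
    list(l4_channel = loc$l4_channel, l4_depth_um = loc$l4_depth_um,
         disagreement = loc$disagreement, votes = as.list(loc$votes),
         true_l4_channel = lt$true_l4_channel),
    file.path(out_dir, "l4_localization.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  cmp <- compare_conditions(rate_off, rate_on)

  jsonlite::write_json(
    list(schema_version = 1L, seed = seed,
         parameters = unclass(config)[order(names(unclass(config)))],
         n_units = n_units, sweep_duration_s = sweep_duration,
         stages = c("kinematics", "epochs", "spikes", "tuning", "vm", "lfp")),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  invisible(list(trace = trace, decomp = decomp, epochs = epochs,
                 units_off = units_off, units_on = units_on,
                 unit_results = wmod, tuning = tuning_tab,
                 vm = vm_rows, l4 = loc, comparison = cmp))
}
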