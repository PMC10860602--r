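# Single-unit spike analysis: waveform-based cell-type classification,
# rate Z-scoring, whisking-modulation classification with BH correction,
# onset-aligned Z-scored PETHs, and the light-modulation index.

#' Construct a sorted single unit
#'
#' @param unit_id Identifier.
#' @param spike_times Numeric vector of spike times (s), strictly increasing,
#'   within `[0, sweep_duration]`.
#' @param sweep_duration Sweep length (s).
#' @param waveform Mean spike waveform (mV samples), optional.
#' @param waveform_rate Waveform sampling rate (Hz).
#' @param depth Recording depth (um), optional.
#' @return Object of class `spike_unit`.
#' @export
spike_unit <- function(unit_id, spike_times, sweep_duration,
                       waveform = NULL, waveform_rate = NULL, depth = NA_real_) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = FALSE)) spike_times <- sort(spike_times)
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) > sweep_duration)) {
    stop("spike times must lie within the sweep")
  }
  structure(list(unit_id = unit_id, spike_times = spike_times,
                 sweep_duration = sweep_duration, waveform = waveform,
                 waveform_rate = waveform_rate, depth = depth),
            class = "spike_unit")
}

#' @export
print.spike_unit <- function(x, ...) {
  cat(sprintf("spike_unit %s: %d spikes over %.1f s (%.2f Hz)\n",
              format(x$unit_id), length(x$spike_times), x$sweep_duration,
              length(x$spike_times) / x$sweep_duration))
  invisible(x)
}

#' Trough-to-peak time of a mean waveform
#'
#' Measured from the waveform trough (global minimum) to the subsequent
#' peak (maximum after the trough).
#'
#' @param waveform Numeric vector (mean waveform).
#' @param sample_rate Waveform sampling rate (Hz).
#' @return Trough-to-peak time in ms.
#' @export
trough_to_peak <- function(waveform, sample_rate) {
  tr <- which.min(waveform)
  if (tr >= length(waveform)) return(NA_real_)
  pk <- tr + which.max(waveform[(tr + 1L):length(waveform)])
  (pk - tr) / sample_rate * 1000
}

#' Classify a unit as fast-spiking or regular-spiking
#'
#' Units with a trough-to-peak time below 0.4 ms are fast-spiking (FS,
#' putative interneurons); above 0.5 ms regular-spiking (RS, putative
#' pyramidal cells); intermediate widths are excluded.
#'
#' @param unit A [spike_unit()] with a waveform, or a bare trough-to-peak
#'   time in ms.
#' @param config A [whiskephys_config()].
#' @return One of `"FS"`, `"RS"`, `"excluded"`.
#' @export
classify_cell_type <- function(unit, config = whiskephys_config()) {
  ttp <- if (inherits(unit, "spike_unit")) {
    if (is.null(unit$waveform)) stop("unit has no waveform")
    trough_to_peak(unit$waveform, unit$waveform_rate)
  } else as.numeric(unit)
  if (is.na(ttp)) return("excluded")
  if (ttp < config$fs_max_trough_to_peak) "FS"
  else if (ttp > config$rs_min_trough_to_peak) "RS"
  else "excluded"
}

#' Z-score a unit's firing rate in fixed bins
#'
#' Rates are computed in 2 s bins over the sweep(s) and standardized by
#' their overall mean and SD.
#'
#' @param unit A [spike_unit()].
#' @param config A [whiskephys_config()].
#' @return List with `z` (per-bin Z-scores), `bin_edges`, `mean_rate_hz`,
#'   `sd_rate_hz`, and `unanalyzable` flag (SD of zero).
#' @export
zscore_rates <- function(unit, config = whiskephys_config()) {
  bw <- config$zscore_bin
  edges <- seq(0, unit$sweep_duration, by = bw)
  if (length(edges) < 3L) stop("need at least 2 full bins to Z-score rates")
  # spikes past the last full bin are dropped with the partial bin
  st <- unit$spike_times[unit$spike_times < edges[length(edges)]]
  counts <- graphics::hist(st, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  rates <- counts / bw
  m <- mean(rates)
  s <- sqrt(mean((rates - m)^2))   # descriptive (population) SD: alternating
                                   # two-level bins standardize to exactly +/-1
  if (s == 0) {
    return(list(z = rep(NA_real_, length(rates)), bin_edges = edges,
                mean_rate_hz = m, sd_rate_hz = 0, unanalyzable = TRUE))
  }
  list(z = (rates - m) / s, bin_edges = edges, mean_rate_hz = m,
       sd_rate_hz = s, unanalyzable = FALSE)
}

# Per-epoch firing rates (Hz) of one unit for a given epoch label.
epoch_rates <- function(unit, epochs, label) {
  ep <- epochs$epochs[epochs$epochs$label == label, , drop = FALSE]
  if (!nrow(ep)) return(numeric(0))
  vapply(seq_len(nrow(ep)), function(i) {
    sum(unit$spike_times >= ep$start_s[i] & unit$spike_times < ep$end_s[i]) /
      (ep$end_s[i] - ep$start_s[i])
  }, numeric(1))
}

#' Classify units by whisking modulation
#'
#' For each unit, per-epoch firing rates in quiet vs whisking epochs are
#' compared with a Wilcoxon rank-sum test; p-values are corrected across
#' units by the Benjamini-Hochberg procedure. Units with significantly
#' higher (lower) whisking rates are whisking-excited, W-Exc
#' (whisking-inhibited, W-Inh); the rest are non-modulated, NM. W-dAP is the
#' whisking-minus-quiet difference of the unit's mean Z-scored rate.
#'
#' @param units List of [spike_unit()]s recorded in the same session.
#' @param epochs An [segment_epochs()] result (or a list of them matching
#'   `units` when sweeps differ).
#' @param config A [whiskephys_config()]; `alpha` and `min_epochs_per_label`
#'   control the test.
#' @return Data frame with one row per unit: `unit_id`, `category`,
#'   `w_delta_ap`, `p_raw`, `q_bh`, `quiet_rate_hz`, `whisk_rate_hz`,
#'   `testable`.
#' @export
classify_whisk_modulation <- function(units, epochs, config = whiskephys_config()) {
  if (inherits(units, "spike_unit")) units <- list(units)
  per_unit_epochs <- if (inherits(epochs, "epoch_set")) {
    rep(list(epochs), length(units))
  } else epochs
  rows <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    eps <- per_unit_epochs[[i]]
    rq <- epoch_rates(u, eps, "quiet")
    rw <- epoch_rates(u, eps, "whisking")
    testable <- length(rq) >= config$min_epochs_per_label &&
      length(rw) >= config$min_epochs_per_label &&
      length(u$spike_times) > 0L
    p <- NA_real_
    if (testable) {
      p <- tryCatch(
        suppressWarnings(stats::wilcox.test(rw, rq, exact = FALSE)$p.value),
        error = function(e) NA_real_)
      if (is.na(p)) p <- 1   # identical samples: no evidence of modulation
    }
    zs <- zscore_rates(u, config)
    wdap <- NA_real_
    if (!zs$unanalyzable && length(u$spike_times) > 0L) {
      mids <- (zs$bin_edges[-1L] + zs$bin_edges[-length(zs$bin_edges)]) / 2
      zw <- zs$z[vapply(mids, function(m) any(
        eps$epochs$label == "whisking" & eps$epochs$start_s <= m &
          eps$epochs$end_s > m), logical(1))]
      zq <- zs$z[vapply(mids, function(m) any(
        eps$epochs$label == "quiet" & eps$epochs$start_s <= m &
          eps$epochs$end_s > m), logical(1))]
      if (length(zw) && length(zq)) wdap <- mean(zw) - mean(zq)
    }
    data.frame(unit_id = format(u$unit_id),
               quiet_rate_hz = if (length(rq)) mean(rq) else NA_real_,
               whisk_rate_hz = if (length(rw)) mean(rw) else NA_real_,
               w_delta_ap = wdap, p_raw = p, testable = testable)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$q_bh <- NA_real_
  tested <- which(res$testable & !is.na(res$p_raw))
  res$q_bh[tested] <- stats::p.adjust(res$p_raw[tested], method = "BH")
  res$category <- "NM"
  sig <- tested[res$q_bh[tested] < config$alpha]
  res$category[sig] <- ifelse(res$whisk_rate_hz[sig] > res$quiet_rate_hz[sig],
                              "W-Exc", "W-Inh")
  res[, c("unit_id", "category", "w_delta_ap", "p_raw", "q_bh",
          "quiet_rate_hz", "whisk_rate_hz", "testable")]
}

#' Onset-aligned Z-scored peri-event time histogram
#'
#' Spike rates in 200 ms bins around each whisking onset are Z-scored with
#' the unit's 2 s-bin rate mean and SD, averaged across onsets, smoothed
#' with a Gaussian kernel, and baseline-subtracted (the mean over -1.0 to
#' -0.2 s before onset).
#'
#' @param unit A [spike_unit()].
#' @param onsets Whisking onset times (s).
#' @param window Time window around onset (s), default `c(-2, 3)`.
#' @param config A [whiskephys_config()].
#' @return Object of class `zscored_peth`: `bin_centers` (s relative to
#'   onset), `z` (smoothed, baseline-subtracted), `z_raw`, `n_onsets`.
#' @export
build_peth <- function(unit, onsets, window = c(-2, 3),
                       config = whiskephys_config()) {
  bw <- config$peth_bin
  onsets <- onsets[!is.na(onsets)]
  onsets <- onsets[onsets + window[1] >= 0 &
                   onsets + window[2] <= unit$sweep_duration]
  if (!length(onsets)) stop("no onset with full pre/post window coverage")
  edges <- seq(window[1], window[2], by = bw)
  centers <- edges[-length(edges)] + bw / 2
  zs <- zscore_rates(unit, config)
  counts <- matrix(0, nrow = length(onsets), ncol = length(centers))
  for (i in seq_along(onsets)) {
    rel <- unit$spike_times - onsets[i]
    rel <- rel[rel >= window[1] & rel < window[2]]
    counts[i, ] <- graphics::hist(rel, breaks = edges, plot = FALSE,
                                  right = FALSE)$counts
  }
  rates <- colMeans(counts) / bw
  z <- if (zs$unanalyzable) rates * 0 else (rates - zs$mean_rate_hz) / zs$sd_rate_hz
  # Gaussian smoothing, SD in bins
  sd_b <- config$peth_smooth_sd
  half <- max(1L, ceiling(3 * sd_b))
  k <- stats::dnorm(seq(-half, half), sd = sd_b)
  k <- k / sum(k)
  zsm <- as.numeric(stats::filter(c(rep(z[1], half), z, rep(z[length(z)], half)),
                                  k, sides = 2))[(half + 1L):(half + length(z))]
  bl <- centers >= config$peth_baseline[1] & centers <= config$peth_baseline[2]
  zout <- zsm - mean(zsm[bl])
  structure(list(bin_centers = centers, z = zout, z_raw = z,
                 n_onsets = length(onsets), bin_width = bw,
                 baseline_window = config$peth_baseline),
            class = "zscored_peth")
}

#' @export
plot.zscored_peth <- function(x, ...) {
  graphics::plot(x$bin_centers, x$z, type = "s", xlab = "time from onset (s)",
                 ylab = "Z-scored rate", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Light-modulation index
#'
#' `(rate_on - rate_off) / (rate_on + rate_off)`: -1 for complete
#' suppression, 0 for no change, +1 for activity only during light-on.
#'
#' @param rate_on,rate_off Mean firing rates (Hz) in light-on / light-off
#'   sweeps.
#' @return Index in `[-1, 1]`, or `NA` when both rates are zero.
#' @export
light_modulation_index <- function(rate_on, rate_off) {
  stopifnot(rate_on >= 0, rate_off >= 0)
  if (rate_on + rate_off == 0) return(NA_real_)
  (rate_on - rate_off) / (rate_on + rate_off)
}
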