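# Subthreshold membrane-potential analysis: AP detection and excision,
# per-epoch statistics, 1-5 Hz FFT band integrals, and whisking
# phase-locked Vm modulation with a circular-shift null.

#' Construct a whole-cell membrane-potential recording
#'
#' @param vm Numeric vector of membrane potential (mV).
#' @param sample_rate Sampling rate (Hz).
#' @param light_condition `"OFF"` or `"ON"`.
#' @param cell_id Identifier.
#' @return Object of class `vm_recording` (with empty `ap_times` /
#'   `cleaned_vm` until [detect_and_clean_spikes()] is run).
#' @export
vm_recording <- function(vm, sample_rate, light_condition = "OFF", cell_id = "c1") {
  stopifnot(is.numeric(vm), sample_rate > 0)
  structure(list(vm = as.numeric(vm), sample_rate = sample_rate,
                 light_condition = light_condition, cell_id = cell_id,
                 ap_times = NULL, cleaned_vm = NULL),
            class = "vm_recording")
}

#' @export
print.vm_recording <- function(x, ...) {
  cat(sprintf("vm_recording %s (%s): %.1f s at %g Hz, mean %.1f mV",
              format(x$cell_id), x$light_condition,
              length(x$vm) / x$sample_rate, x$sample_rate, mean(x$vm)))
  if (!is.null(x$ap_times)) cat(sprintf(", %d APs", length(x$ap_times)))
  cat("\n")
  invisible(x)
}

#' Detect action potentials and excise them from the Vm trace
#'
#' APs are detected where dV/dt exceeds a threshold (default 10 V/s), with
#' detections closer than the refractory window merged; the AP peak is the
#' local Vm maximum after each crossing. The cleaned trace replaces the
#' window from 1 ms before to 4 ms after each peak by linear interpolation,
#' so subthreshold means, variances and spectra are not biased by spike
#' waveforms.
#'
#' @param rec A [vm_recording()].
#' @param config A [whiskephys_config()] (`dvdt_threshold` V/s,
#'   `spike_refractory` s, `spike_excision` s).
#' @return The recording with `ap_times` and `cleaned_vm` filled in.
#' @export
detect_and_clean_spikes <- function(rec, config = whiskephys_config()) {
  stopifnot(inherits(rec, "vm_recording"))
  fs <- rec$sample_rate
  v <- rec$vm
  n <- length(v)
  dvdt <- c(0, diff(v)) * fs / 1000          # V/s (v is mV)
  cross <- which(dvdt > config$dvdt_threshold)
  ap <- integer(0)
  refr <- as.integer(round(config$spike_refractory * fs))
  last <- -Inf
  for (i in cross) {
    if (i - last <= refr) next
    win <- i:min(n, i + refr)
    pk <- win[which.max(v[win])]
    ap <- c(ap, pk)
    last <- pk
  }
  cleaned <- v
  if (length(ap)) {
    a_off <- as.integer(floor(config$spike_excision[1] * fs))
    b_off <- as.integer(ceiling(config$spike_excision[2] * fs))
    bad <- logical(n)
    for (p in ap) {
      bad[max(1L, p + a_off):min(n, p + b_off)] <- TRUE
    }
    good <- which(!bad)
    cleaned[bad] <- stats::approx(good, v[good], xout = which(bad), rule = 2)$y
  }
  rec$ap_times <- (ap - 1L) / fs
  rec$cleaned_vm <- cleaned
  rec
}

#' Per-epoch membrane-potential statistics
#'
#' Mean and variance of the cleaned Vm and the AP rate in each quiet or
#' whisking epoch, plus whisking-minus-quiet deltas of the epoch means
#' (delta Vm, delta AP rate, delta variance).
#'
#' @param rec A [vm_recording()] after [detect_and_clean_spikes()].
#' @param epochs An [segment_epochs()] result.
#' @return List with `per_epoch` (data frame) and `deltas`.
#' @export
epoch_vm_stats <- function(rec, epochs) {
  stopifnot(inherits(rec, "vm_recording"))
  if (is.null(rec$cleaned_vm)) rec <- detect_and_clean_spikes(rec)
  fs <- rec$sample_rate
  n <- length(rec$vm)
  ep <- epochs$epochs
  rows <- lapply(seq_len(nrow(ep)), function(i) {
    a <- max(1L, as.integer(floor(ep$start_s[i] * fs)) + 1L)
    b <- min(n, as.integer(ceiling(ep$end_s[i] * fs)))
    seg <- rec$cleaned_vm[a:b]
    naps <- sum(rec$ap_times >= ep$start_s[i] & rec$ap_times < ep$end_s[i])
    data.frame(label = ep$label[i], start_s = ep$start_s[i], end_s = ep$end_s[i],
               mean_vm = mean(seg), vm_variance = stats::var(seg),
               ap_rate_hz = naps / (ep$end_s[i] - ep$start_s[i]),
               condition = rec$light_condition)
  })
  pe <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  mw <- pe[pe$label == "whisking", , drop = FALSE]
  mq <- pe[pe$label == "quiet", , drop = FALSE]
  deltas <- list(
    d_vm = if (nrow(mw) && nrow(mq)) mean(mw$mean_vm) - mean(mq$mean_vm) else NA_real_,
    d_ap = if (nrow(mw) && nrow(mq)) mean(mw$ap_rate_hz) - mean(mq$ap_rate_hz) else NA_real_,
    d_variance = if (nrow(mw) && nrow(mq)) {
      mean(mw$vm_variance) - mean(mq$vm_variance)
    } else NA_real_)
  list(per_epoch = pe, deltas = deltas)
}

#' FFT magnitude spectra and low-frequency band integral of Vm
#'
#' Magnitude spectra of non-overlapping 2 s segments (scaled so a sinusoid
#' of amplitude a mV shows a line of height a) are averaged per epoch
#' label, and the band integral taken over the slow-wave band (default
#' 1-5 Hz) by the trapezoid rule.
#'
#' @param rec A [vm_recording()] after cleaning.
#' @param epochs An [segment_epochs()] result.
#' @param config A [whiskephys_config()] (`vm_band`, `fft_segment`).
#' @return List with `freq`, per-label average `spectra`, and
#'   `band_integral` per label (mV x Hz).
#' @export
vm_band_fft <- function(rec, epochs, config = whiskephys_config()) {
  stopifnot(inherits(rec, "vm_recording"))
  if (is.null(rec$cleaned_vm)) rec <- detect_and_clean_spikes(rec, config)
  fs <- rec$sample_rate
  seg_n <- as.integer(round(config$fft_segment * fs))
  freq <- (seq_len(seg_n %/% 2L) - 1L) * fs / seg_n
  labels <- unique(epochs$epochs$label)
  spectra <- list(); band <- list()
  for (lab in labels) {
    ep <- epochs$epochs[epochs$epochs$label == lab, , drop = FALSE]
    mags <- list()
    for (i in seq_len(nrow(ep))) {
      a <- max(1L, as.integer(floor(ep$start_s[i] * fs)) + 1L)
      b <- min(length(rec$vm), as.integer(ceiling(ep$end_s[i] * fs)))
      nseg <- (b - a + 1L) %/% seg_n
      for (s in seq_len(nseg)) {
        x <- rec$cleaned_vm[(a + (s - 1L) * seg_n):(a + s * seg_n - 1L)]
        mags[[length(mags) + 1L]] <- 2 * Mod(stats::fft(x - mean(x)))[seq_along(freq)] / seg_n
      }
    }
    if (!length(mags)) next
    avg <- Reduce(`+`, mags) / length(mags)
    spectra[[lab]] <- avg
    inband <- freq >= config$vm_band[1] & freq <= config$vm_band[2]
    band[[lab]] <- trapz_integral(freq[inband], avg[inband])
  }
  list(freq = freq, spectra = spectra, band_integral = band)
}

#' Whisking phase-locked membrane potential
#'
#' Averages the cleaned Vm as a function of whisking phase over whisking
#' samples (64 equal-width phase bins). Modulation depth is the
#' peak-to-trough difference of the averaged trace; the most depolarized
#' phase is its argmax.
#'
#' @param rec A [vm_recording()] after cleaning.
#' @param phase Per-sample whisking phase (radians) on the Vm time base.
#' @param whisking Logical per-sample whisking mask on the Vm time base.
#' @param config A [whiskephys_config()] (`n_phase_bins_vm`,
#'   `min_whisk_cycles`).
#' @return Object of class `phase_locked_vm`: `phase_centers`, `mean_vm`,
#'   `depth_mv`, `preferred_phase`, `n_cycles`.
#' @export
phase_locked_vm <- function(rec, phase, whisking, config = whiskephys_config()) {
  stopifnot(inherits(rec, "vm_recording"))
  if (is.null(rec$cleaned_vm)) rec <- detect_and_clean_spikes(rec, config)
  ok <- whisking & is.finite(phase)
  nb <- config$n_phase_bins_vm
  edges <- seq(-pi, pi, length.out = nb + 1L)
  b <- pmin(pmax(findInterval(phase[ok], edges, rightmost.closed = TRUE), 1L), nb)
  v <- rec$cleaned_vm[ok]
  # cycle count: wraps of the phase within the whisking mask
  n_cycles <- sum(diff(phase[ok]) < -pi)
  if (n_cycles < config$min_whisk_cycles) {
    warning(sprintf("only %d whisk cycles (< %d); phase-locked average unreliable",
                    n_cycles, config$min_whisk_cycles))
  }
  sums <- numeric(nb); cnts <- tabulate(b, nbins = nb)
  rs <- rowsum(v, b, reorder = TRUE)
  sums[as.integer(rownames(rs))] <- rs[, 1L]
  mv <- ifelse(cnts > 0, sums / cnts, NA_real_)
  centers <- (edges[-1L] + edges[-(nb + 1L)]) / 2
  depth <- diff(range(mv, na.rm = TRUE))
  structure(list(phase_centers = centers, mean_vm = mv, depth_mv = depth,
                 preferred_phase = centers[which.max(mv)], n_cycles = n_cycles),
            class = "phase_locked_vm")
}

#' @export
print.phase_locked_vm <- function(x, ...) {
  cat(sprintf("phase_locked_vm: depth %.2f mV, most depolarized at %.2f rad (%d cycles)\n",
              x$depth_mv, x$preferred_phase, x$n_cycles))
  invisible(x)
}

#' Circular-shuffle significance test for phase-locked Vm
#'
#' Each shuffle circularly rotates the Vm trace of every whisking epoch by
#' an independent uniform offset, breaking the phase-Vm alignment while
#' preserving the autocorrelation, and recomputes the phase-averaged
#' modulation depth. The p-value is the fraction of shuffled depths at or
#' above the observed depth.
#'
#' @inheritParams phase_locked_vm
#' @param epochs An [segment_epochs()] result (defines the per-epoch
#'   rotation blocks); when `NULL` the whole whisking mask is one block.
#' @param n_shuffles Number of rotations (default from config; below 100 a
#'   resolution warning is issued).
#' @param seed Integer seed.
#' @return List with `p_shuffle`, `observed_depth`, `shuffled_depths`.
#' @export
test_phase_lock <- function(rec, phase, whisking, epochs = NULL,
                            config = whiskephys_config(),
                            n_shuffles = config$n_shuffles, seed = config$seed) {
  stopifnot(inherits(rec, "vm_recording"))
  if (is.null(rec$cleaned_vm)) rec <- detect_and_clean_spikes(rec, config)
  if (n_shuffles < 100L) warning("fewer than 100 shuffles: p-value resolution is coarse")
  fs <- rec$sample_rate
  n <- length(rec$vm)
  blocks <- if (is.null(epochs)) {
    r <- rle(whisking)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    Map(function(a, b) a:b, starts[r$values], ends[r$values])
  } else {
    ep <- epochs$epochs[epochs$epochs$label == "whisking", , drop = FALSE]
    lapply(seq_len(nrow(ep)), function(i) {
      max(1L, as.integer(floor(ep$start_s[i] * fs)) + 1L):
        min(n, as.integer(ceiling(ep$end_s[i] * fs)))
    })
  }
  blocks <- blocks[vapply(blocks, length, integer(1)) > 1L]
  obs <- phase_locked_vm(rec, phase, whisking, config)$depth_mv

  nb <- config$n_phase_bins_vm
  edges <- seq(-pi, pi, length.out = nb + 1L)
  idx_all <- unlist(blocks, use.names = FALSE)
  bin_all <- pmin(pmax(findInterval(phase[idx_all], edges,
                                    rightmost.closed = TRUE), 1L), nb)
  keep <- is.finite(phase[idx_all]) & whisking[idx_all]
  block_id <- rep(seq_along(blocks), vapply(blocks, length, integer(1)))
  block_len <- vapply(blocks, length, integer(1))
  block_off <- c(0L, cumsum(block_len))[seq_along(blocks)]
  pos_in_block <- sequence(block_len) - 1L

  set.seed(derive_seed(seed, "vm-circshift"))
  depths <- numeric(n_shuffles)
  v <- rec$cleaned_vm
  for (s in seq_len(n_shuffles)) {
    rot <- floor(stats::runif(length(blocks)) * block_len)
    new_pos <- (pos_in_block + rot[block_id]) %% block_len[block_id]
    vi <- v[idx_all[block_off[block_id] + new_pos + 1L]]
    sums <- numeric(nb); cnts <- numeric(nb)
    rs <- rowsum(cbind(vi[keep], 1), bin_all[keep], reorder = TRUE)
    sums[as.integer(rownames(rs))] <- rs[, 1L]
    cnts[as.integer(rownames(rs))] <- rs[, 2L]
    mv <- sums[cnts > 0] / cnts[cnts > 0]
    depths[s] <- diff(range(mv))
  }
  list(p_shuffle = mean(depths >= obs), observed_depth = obs,
       shuffled_depths = depths)
}
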