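# Laminar LFP: preprocessing, state-dependent power spectra with
# light-off-peak normalization, current source density, and layer-4
# localization from touch-evoked responses.

#' Construct a laminar LFP session
#'
#' @param lfp Channels x samples matrix (mV).
#' @param channel_depths Depth below pia (um) per channel; must be strictly
#'   increasing within each of the two interleaved probe columns (odd and
#'   even channel numbers).
#' @param sample_rate Sampling rate (Hz).
#' @param touch_times Active-touch event times (s).
#' @param light_condition `"OFF"` or `"ON"`.
#' @return Object of class `laminar_session`.
#' @export
laminar_session <- function(lfp, channel_depths, sample_rate,
                            touch_times = numeric(0), light_condition = "OFF") {
  stopifnot(is.matrix(lfp), nrow(lfp) == length(channel_depths), sample_rate > 0)
  for (par in c(1L, 0L)) {
    col <- which(seq_len(nrow(lfp)) %% 2L == par)
    if (length(col) > 1L && is.unsorted(channel_depths[col], strictly = TRUE)) {
      stop("channel depths must be strictly increasing within each odd/even column")
    }
  }
  dur <- ncol(lfp) / sample_rate
  if (length(touch_times) && (min(touch_times) < 0 || max(touch_times) > dur)) {
    stop("touch times must lie within the recording")
  }
  structure(list(lfp = lfp, channel_depths = channel_depths,
                 sample_rate = sample_rate, touch_times = touch_times,
                 light_condition = light_condition),
            class = "laminar_session")
}

#' @export
print.laminar_session <- function(x, ...) {
  cat(sprintf("laminar_session: %d channels x %.1f s at %g Hz, %d touches (%s)\n",
              nrow(x$lfp), ncol(x$lfp) / x$sample_rate, x$sample_rate,
              length(x$touch_times), x$light_condition))
  invisible(x)
}

#' Down-sample and low-pass filter a laminar session
#'
#' Anti-aliased decimation to the target rate followed by a zero-phase
#' low-pass at the stated cutoff (1 kHz / 100 Hz for spectra, 3 kHz /
#' 100 Hz for CSD).
#'
#' @param session A [laminar_session()].
#' @param target_rate Target sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz).
#' @return A `laminar_session` at the new rate.
#' @export
preprocess_lfp <- function(session, target_rate = 1000, cutoff = 100) {
  stopifnot(inherits(session, "laminar_session"))
  fs <- session$sample_rate
  if (target_rate > fs) stop("target rate exceeds the recorded rate")
  dec <- fs / target_rate
  if (abs(dec - round(dec)) > 1e-9) stop("target rate must divide the recorded rate")
  dec <- as.integer(round(dec))
  out <- session$lfp
  if (dec > 1L) {
    # anti-alias below the new Nyquist before decimating
    aa <- min(0.45 * target_rate, 0.45 * fs)
    out <- t(apply(out, 1L, zero_phase_filter, sample_rate = fs, w = aa,
                   type = "low"))
    out <- out[, seq(1L, ncol(out), by = dec), drop = FALSE]
  }
  if (cutoff < 0.5 * target_rate) {
    out <- t(apply(out, 1L, zero_phase_filter, sample_rate = target_rate,
                   w = cutoff, type = "low"))
  }
  session$lfp <- out
  session$sample_rate <- target_rate
  session
}

# Hann-tapered periodogram of one segment, one-sided power units.
hann_periodogram <- function(x) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  xw <- (x - mean(x)) * w
  p <- Mod(stats::fft(xw))^2 / sum(w^2)
  p[seq_len(n %/% 2L)]
}

#' State-dependent LFP power spectra with light-off-peak normalization
#'
#' Epochs of each state (quiet / whisking) lasting at least 2 s are cut
#' into non-overlapping 2 s segments; Hann-tapered periodograms are
#' averaged per state and condition (Welch estimate). All spectra are
#' divided by the peak of the averaged light-off spectrum, so the
#' normalized light-off peak is exactly 1. The 1-5 Hz band power is
#' reported per state and condition.
#'
#' @param sessions A [laminar_session()] or list of them (mixed light
#'   conditions); spectra use a single channel, `channel`.
#' @param epochs Matching [segment_epochs()] result(s).
#' @param channel Channel index used for the spectra.
#' @param config A [whiskephys_config()].
#' @return List with `freq`, `spectra` (named `state.condition`, normalized),
#'   `band_power`, `norm_peak` (the light-off divisor, raw units).
#' @export
lfp_power_spectra <- function(sessions, epochs, channel = 1L,
                              config = whiskephys_config()) {
  if (inherits(sessions, "laminar_session")) sessions <- list(sessions)
  if (inherits(epochs, "epoch_set")) epochs <- list(epochs)
  stopifnot(length(sessions) == length(epochs))
  seg_s <- config$min_spectrum_epoch
  acc <- list()
  freq <- NULL
  for (j in seq_along(sessions)) {
    ses <- sessions[[j]]
    fs <- ses$sample_rate
    seg_n <- as.integer(round(seg_s * fs))
    if (is.null(freq)) freq <- (seq_len(seg_n %/% 2L) - 1L) * fs / seg_n
    ep <- epochs[[j]]$epochs
    ep <- ep[ep$end_s - ep$start_s >= seg_s, , drop = FALSE]
    for (i in seq_len(nrow(ep))) {
      a <- max(1L, as.integer(floor(ep$start_s[i] * fs)) + 1L)
      b <- min(ncol(ses$lfp), as.integer(ceiling(ep$end_s[i] * fs)))
      nseg <- (b - a + 1L) %/% seg_n
      for (s in seq_len(nseg)) {
        x <- ses$lfp[channel, (a + (s - 1L) * seg_n):(a + s * seg_n - 1L)]
        key <- paste(ep$label[i], ses$light_condition, sep = ".")
        acc[[key]] <- c(acc[[key]], list(hann_periodogram(x)))
      }
    }
  }
  if (!length(acc)) stop("no epoch of sufficient length for spectra")
  spectra <- lapply(acc, function(lst) Reduce(`+`, lst) / length(lst))
  off_keys <- grep("\\.OFF$", names(spectra), value = TRUE)
  if (!length(off_keys)) stop("no light-off segments to normalize against")
  off_all <- unlist(acc[off_keys], recursive = FALSE)
  off_avg <- Reduce(`+`, off_all) / length(off_all)
  peak <- max(off_avg)
  spectra <- lapply(spectra, function(p) p / peak)
  inband <- freq >= config$vm_band[1] & freq <= config$vm_band[2]
  band <- vapply(spectra, function(p) trapz_integral(freq[inband], p[inband]),
                 numeric(1))
  list(freq = freq, spectra = spectra, band_power = band, norm_peak = peak)
}

# Touch-triggered average LFP over a window, channels x window samples.
touch_average <- function(session, window) {
  fs <- session$sample_rate
  a_off <- as.integer(round(window[1] * fs))
  b_off <- as.integer(round(window[2] * fs))
  nt <- 0L
  acc <- matrix(0, nrow(session$lfp), b_off - a_off + 1L)
  for (tt in session$touch_times) {
    i <- as.integer(round(tt * fs)) + 1L
    if (i + a_off < 1L || i + b_off > ncol(session$lfp)) next
    acc <- acc + session$lfp[, (i + a_off):(i + b_off), drop = FALSE]
    nt <- nt + 1L
  }
  if (nt == 0L) return(NULL)
  list(avg = acc / nt, time_s = (a_off:b_off) / fs, n_touches = nt)
}

#' Current source density of a touch-averaged LFP
#'
#' CSD along depth within one probe column (odd or even channel numbers) as
#' the negated discrete second spatial derivative,
#' `-(V[i-1] - 2 V[i] + V[i+1]) / dz^2`, so that current sinks (negative
#' LFP deflections) are negative and sources positive. Boundary channels
#' are padded by duplication.
#'
#' @param avg_lfp Channels x time matrix (the touch-triggered average, full
#'   array).
#' @param channel_depths Depths (um) of all channels.
#' @param channel_subset `"odd"` or `"even"` probe column.
#' @return Object of class `csd_profile`: `csd` (mV/mm^2, subset channels x
#'   time), `channels` (indices into the full array), `depths_um`.
#' @export
compute_csd <- function(avg_lfp, channel_depths, channel_subset = c("odd", "even")) {
  channel_subset <- match.arg(channel_subset)
  par <- if (channel_subset == "odd") 1L else 0L
  ch <- which(seq_len(nrow(avg_lfp)) %% 2L == par)
  if (length(ch) < 3L) stop("need at least 3 channels in the subset")
  v <- avg_lfp[ch, , drop = FALSE]
  dz <- diff(channel_depths[ch])
  if (any(abs(dz - dz[1L]) > 1e-6)) stop("channel spacing within a column must be uniform")
  dz_mm <- dz[1L] / 1000
  vp <- rbind(v[1L, ], v, v[nrow(v), ])          # duplicate-padded
  m <- nrow(v)
  csd <- -(vp[seq_len(m), , drop = FALSE] - 2 * v +
             vp[seq_len(m) + 2L, , drop = FALSE]) / dz_mm^2
  structure(list(csd = csd, channels = ch, depths_um = channel_depths[ch],
                 dz_um = dz[1L], subset = channel_subset),
            class = "csd_profile")
}

#' @export
print.csd_profile <- function(x, ...) {
  cat(sprintf("csd_profile (%s channels, dz = %g um): %d x %d, sink min %.2f mV/mm^2\n",
              x$subset, x$dz_um, nrow(x$csd), ncol(x$csd), min(x$csd)))
  invisible(x)
}

#' @export
plot.csd_profile <- function(x, time_s = NULL, ...) {
  t <- if (is.null(time_s)) seq_len(ncol(x$csd)) else time_s
  graphics::image(t, x$depths_um, t(x$csd[nrow(x$csd):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "RdBu"),
                  xlab = "time", ylab = "depth (um)", ...)
  invisible(x)
}

#' Locate the layer-4 center of a laminar session
#'
#' Three per-channel criteria are computed on the touch-triggered average
#' within one probe column: (1) shortest peak latency of the LFP response,
#' (2) largest negative peak amplitude, (3) earliest CSD sink onset (first
#' crossing of 20% of the channel's peak negative CSD after touch). The
#' channel winning all three is the layer-4 center; on disagreement a
#' majority vote decides, with ties broken toward the amplitude criterion
#' and the disagreement flagged. Channel depths are then re-anchored so the
#' winner sits at the conventional 500 um subpial depth, and layer
#' boundaries read from the configured depth table.
#'
#' @param session A [laminar_session()] (preprocessed for CSD).
#' @param channel_subset `"odd"` or `"even"` probe column.
#' @param config A [whiskephys_config()].
#' @return Object of class `l4_localization`: `l4_channel` (full-array
#'   index), `criteria` (per-channel table), `disagreement`, `failed`,
#'   `anchored_depths_um`, `layer_of_channel`, plus the `csd_profile`.
#' @export
locate_layer4 <- function(session, channel_subset = c("odd", "even"),
                          config = whiskephys_config()) {
  channel_subset <- match.arg(channel_subset)
  if (length(session$touch_times) < 1L) {
    return(structure(list(failed = TRUE, reason = "no touch events",
                          l4_channel = NA_integer_), class = "l4_localization"))
  }
  ta <- touch_average(session, config$touch_window)
  if (is.null(ta)) {
    return(structure(list(failed = TRUE, reason = "no touch with full window",
                          l4_channel = NA_integer_), class = "l4_localization"))
  }
  csd <- compute_csd(ta$avg, session$channel_depths, channel_subset)
  ch <- csd$channels
  v <- ta$avg[ch, , drop = FALSE]
  post <- ta$time_s >= 0
  tpost <- ta$time_s[post]
  # responses are negative deflections; a channel without one gets NA
  peak_amp <- apply(v[, post, drop = FALSE], 1L, function(x) -min(x))
  peak_lat <- apply(v[, post, drop = FALSE], 1L, function(x) tpost[which.min(x)])
  resp <- peak_amp > 0.2 * max(peak_amp)
  sink_onset <- vapply(seq_along(ch), function(i) {
    x <- csd$csd[i, post]
    pk <- min(x)
    if (pk >= -abs(0.2 * min(csd$csd))) return(NA_real_)
    hit <- which(x <= config$sink_onset_fraction * pk)
    if (!length(hit)) NA_real_ else tpost[hit[1L]]
  }, numeric(1))
  crit <- data.frame(channel = ch, peak_amp_mv = peak_amp,
                     peak_latency_s = peak_lat, sink_onset_s = sink_onset)
  win_amp <- ch[which.max(peak_amp)]
  win_lat <- ch[resp][which.min(peak_lat[resp])]
  win_sink <- if (all(is.na(sink_onset))) NA_integer_
              else ch[which.min(sink_onset)]
  votes <- c(latency = win_lat, amplitude = win_amp, sink = win_sink)
  votes_ok <- votes[!is.na(votes)]
  tab <- sort(table(votes_ok), decreasing = TRUE)
  disagreement <- length(tab) > 1L
  winner <- if (length(tab) >= 2L && tab[1L] == tab[2L]) {
    win_amp                             # tie broken toward amplitude
  } else as.integer(names(tab)[1L])
  anchored <- session$channel_depths -
    session$channel_depths[winner] + config$l4_anchor_depth
  lb <- config$layer_boundaries
  layer_of <- names(lb)[pmax(1L, findInterval(anchored, lb))]
  structure(list(failed = FALSE, l4_channel = winner,
                 l4_depth_um = config$l4_anchor_depth,
                 criteria = crit, votes = votes, disagreement = disagreement,
                 anchored_depths_um = anchored, layer_of_channel = layer_of,
                 csd = csd, touch_average = ta), class = "l4_localization")
}

#' @export
print.l4_localization <- function(x, ...) {
  if (x$failed) {
    cat("l4_localization: FAILED (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("l4_localization: channel %d anchored at %g um%s\n",
                x$l4_channel, x$l4_depth_um,
                if (x$disagreement) " (criteria disagreed; majority vote)" else ""))
  }
  invisible(x)
}
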