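# Whisker kinematic decomposition: phase / amplitude / midpoint / setpoint,
# and quiet-vs-whisking epoch segmentation.

#' Construct a whisker angle trace
#'
#' @param angle Numeric vector of whisker angles in degrees (one sample per
#'   video frame); increasing angle is protraction by default.
#' @param sample_rate Sampling rate in Hz (500 for standard high-speed film).
#' @param sweep_id Optional sweep identifier.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `whisker_trace`.
#' @export
whisker_trace <- function(angle, sample_rate = 500, sweep_id = 1L, t0 = 0) {
  stopifnot(is.numeric(angle), all(is.finite(angle)), sample_rate > 0)
  structure(list(angle = as.numeric(angle), sample_rate = sample_rate,
                 sweep_id = sweep_id, t0 = t0),
            class = "whisker_trace")
}

#' @export
print.whisker_trace <- function(x, ...) {
  cat(sprintf("whisker_trace: %.1f s at %g Hz (sweep %s), angle range [%.1f, %.1f] deg\n",
              length(x$angle) / x$sample_rate, x$sample_rate,
              format(x$sweep_id), min(x$angle), max(x$angle)))
  invisible(x)
}

trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$angle) - 1L) / trace$sample_rate
}

#' Band-pass filter a whisker trace into the whisking band
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass over the
#' whisking frequency band (default 4-25 Hz). Zero-phase filtering is
#' essential so that phase landmarks extracted downstream are not delayed.
#'
#' @param trace A [whisker_trace()].
#' @param config A [whiskephys_config()].
#' @return A `whisker_trace` holding the band-passed angle.
#' @export
bandpass_whisker <- function(trace, config = whiskephys_config()) {
  stopifnot(inherits(trace, "whisker_trace"))
  if (length(trace$angle) < trace$sample_rate) {
    stop("trace shorter than 1 s cannot be band-pass filtered reliably")
  }
  y <- zero_phase_filter(trace$angle, trace$sample_rate, config$whisk_band,
                         type = "pass", order = config$filter_order)
  out <- trace
  out$angle <- y
  out
}

#' Instantaneous whisking phase from the Hilbert transform
#'
#' Phase 0 marks the most protracted position of the whisk cycle and phase
#' +/- pi the end of retraction. If the trace has essentially no oscillatory
#' energy the phase is meaningless; a `degenerate` flag is set.
#'
#' @param filtered A band-passed `whisker_trace` (see [bandpass_whisker()]).
#' @param degenerate_tol Envelope (deg) below which the trace is flagged
#'   degenerate.
#' @return List with `phase` (radians in (-pi, pi]), `envelope` (deg) and
#'   `degenerate` flag.
#' @export
hilbert_phase <- function(filtered, degenerate_tol = 1e-6) {
  stopifnot(inherits(filtered, "whisker_trace"))
  a <- analytic_signal(filtered$angle - mean(filtered$angle))
  env <- Mod(a)
  degenerate <- stats::median(env) < degenerate_tol
  list(phase = Arg(a), envelope = env, degenerate = degenerate)
}

# Locate protraction (phase = 0) and retraction (phase = +/- pi) events as
# crossings of the unwrapped phase through even / odd multiples of pi.
phase_events <- function(phase) {
  u <- unwrap_phase(phase)
  k <- floor(u / pi)            # integer level; changes at each pi crossing
  idx <- which(diff(k) > 0)     # crossing between idx and idx+1
  if (length(idx) == 0L) {
    return(list(protraction = integer(0), retraction = integer(0)))
  }
  lev <- k[idx + 1L]            # level entered: even -> crossed even*pi (phase 0)
  # choose the sample nearer the crossing
  cross <- vapply(seq_along(idx), function(j) {
    i <- idx[j]
    target <- lev[j] * pi
    if (abs(u[i] - target) <= abs(u[i + 1L] - target)) i else i + 1L
  }, integer(1))
  list(protraction = cross[lev %% 2L == 0L],
       retraction  = cross[lev %% 2L != 0L])
}

#' Decompose a whisker trace into phase, amplitude, midpoint and setpoint
#'
#' The raw angle is band-pass filtered (4-25 Hz) and the Hilbert phase
#' extracted so that phase 0 is the most protracted position. At each
#' adjacent protraction/retraction event pair the amplitude is half the
#' protraction-retraction excursion of the *raw* angle and the midpoint its
#' center:
#' amplitude = (theta_phase0 - theta_phasePi) / 2,
#' midpoint  = theta_phasePi + (theta_phase0 - theta_phasePi) / 2.
#' Between events both are linearly interpolated. The setpoint is the slow
#' (<6 Hz) envelope of the raw angle.
#'
#' @param trace A [whisker_trace()] of the raw angle.
#' @param config A [whiskephys_config()]; `protraction_positive` flips the
#'   sign convention when whisker angle decreases during protraction.
#' @return Object of class `kinematic_decomposition` with per-sample `phase`,
#'   `amplitude`, `midpoint`, `setpoint`, event indices, and flags.
#' @export
decompose_whisking <- function(trace, config = whiskephys_config()) {
  stopifnot(inherits(trace, "whisker_trace"))
  raw <- trace$angle
  work <- trace
  if (!config$protraction_positive) work$angle <- -work$angle
  bp <- bandpass_whisker(work, config)
  hp <- hilbert_phase(bp)
  ev <- phase_events(hp$phase)
  n <- length(raw)
  undefined <- hp$degenerate ||
    (length(ev$protraction) + length(ev$retraction)) < 2L

  sgn <- if (config$protraction_positive) 1 else -1
  if (!undefined) {
    all_ev <- sort(c(ev$protraction, ev$retraction))
    is_prot <- all_ev %in% ev$protraction
    th <- sgn * raw[all_ev]     # sign-adjusted raw angle at events
    m <- length(all_ev)
    amp_ev <- rep(NA_real_, m)
    mid_ev <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      # pair each event with its nearest opposite-type neighbour
      prev_ok <- j > 1L && is_prot[j - 1L] != is_prot[j]
      next_ok <- j < m && is_prot[j + 1L] != is_prot[j]
      other <- if (prev_ok && next_ok) {
        if (all_ev[j] - all_ev[j - 1L] <= all_ev[j + 1L] - all_ev[j]) j - 1L else j + 1L
      } else if (prev_ok) j - 1L else if (next_ok) j + 1L else NA_integer_
      if (is.na(other)) next
      th0 <- if (is_prot[j]) th[j] else th[other]
      thp <- if (is_prot[j]) th[other] else th[j]
      amp_ev[j] <- (th0 - thp) / 2
      mid_ev[j] <- thp + (th0 - thp) / 2
    }
    keep <- !is.na(amp_ev)
    if (sum(keep) >= 2L) {
      amplitude <- stats::approx(all_ev[keep], amp_ev[keep], xout = seq_len(n),
                                 rule = 2)$y
      midpoint <- sgn * stats::approx(all_ev[keep], mid_ev[keep],
                                      xout = seq_len(n), rule = 2)$y
      amplitude[amplitude < 0] <- 0
    } else {
      undefined <- TRUE
    }
  }
  if (undefined) {
    amplitude <- rep(NA_real_, n)
    midpoint <- rep(NA_real_, n)
  }

  structure(list(
    phase = hp$phase,
    amplitude = amplitude,
    midpoint = midpoint,
    setpoint = compute_setpoint(trace, config),
    envelope = hp$envelope,
    protraction_events = ev$protraction,
    retraction_events = ev$retraction,
    sample_rate = trace$sample_rate,
    t0 = trace$t0,
    degenerate = hp$degenerate,
    undefined_amplitude = undefined,
    protraction_positive = config$protraction_positive
  ), class = "kinematic_decomposition")
}

#' @export
print.kinematic_decomposition <- function(x, ...) {
  cat(sprintf(paste0("kinematic_decomposition: %d samples at %g Hz, ",
                     "%d protraction / %d retraction events\n"),
              length(x$phase), x$sample_rate,
              length(x$protraction_events), length(x$retraction_events)))
  if (x$undefined_amplitude) cat("  amplitude/midpoint undefined (too few events)\n")
  invisible(x)
}

#' @export
plot.kinematic_decomposition <- function(x, trace = NULL, ...) {
  t <- x$t0 + (seq_along(x$phase) - 1L) / x$sample_rate
  graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  if (!is.null(trace)) {
    graphics::plot(t, trace$angle, type = "l", ylab = "angle (deg)", xlab = "")
    graphics::lines(t, reconstruct_whisker(x)$angle, col = 2)
  } else {
    graphics::plot(t, x$midpoint, type = "l", ylab = "midpoint (deg)", xlab = "")
  }
  graphics::plot(t, x$amplitude, type = "l", ylab = "amplitude (deg)", xlab = "")
  graphics::plot(t, x$phase, type = "l", ylab = "phase (rad)", xlab = "time (s)")
  invisible(x)
}

#' Whisking setpoint: slow envelope of the whisker angle
#'
#' Zero-phase low-pass of the raw angle at the setpoint cutoff (default 6 Hz).
#'
#' @inheritParams decompose_whisking
#' @return Numeric vector of setpoint samples (degrees).
#' @export
compute_setpoint <- function(trace, config = whiskephys_config()) {
  stopifnot(inherits(trace, "whisker_trace"))
  # a steeper rolloff than the band-pass: the 8-12 Hz whisking fundamental
  # sits close above the 6 Hz cutoff and must not ripple through
  zero_phase_filter(trace$angle, trace$sample_rate, config$setpoint_cutoff,
                    type = "low", order = 2L * config$filter_order)
}

#' Segment a sweep into quiet and whisking epochs
#'
#' Tiles the sweep greedily with the longest qualifying window (3, then 2,
#' then 1 s). A window is whisking when the band-passed oscillation envelope
#' stays above `whisk_envelope_min` throughout, quiet when it stays below
#' `quiet_envelope_max`; intermediate windows are left unlabelled. The onset
#' of each whisking epoch is the first sample at which the raw angle exceeds
#' the baseline (median raw angle over the preceding quiet window) by the
#' onset threshold (1 degree).
#'
#' @inheritParams decompose_whisking
#' @param decomp Optional precomputed [decompose_whisking()] result.
#' @return Object of class `epoch_set`: data frame `epochs` (label, start_s,
#'   end_s, onset_s) plus the sweep id.
#' @export
segment_epochs <- function(trace, config = whiskephys_config(), decomp = NULL) {
  stopifnot(inherits(trace, "whisker_trace"))
  if (is.null(decomp)) decomp <- decompose_whisking(trace, config)
  env <- decomp$envelope
  fs <- trace$sample_rate
  n <- length(env)
  wins <- as.integer(round(sort(config$window_lengths, decreasing = TRUE) * fs))
  step <- max(1L, as.integer(round(0.5 * fs)))

  labels <- character(0); starts <- integer(0); ends <- integer(0)
  pos <- 1L
  while (pos <= n - min(wins) + 1L) {
    placed <- FALSE
    for (w in wins) {
      if (pos + w - 1L > n) next
      seg <- env[pos:(pos + w - 1L)]
      lab <- if (all(seg > config$whisk_envelope_min)) "whisking"
             else if (all(seg < config$quiet_envelope_max)) "quiet"
             else NA_character_
      if (!is.na(lab)) {
        labels <- c(labels, lab); starts <- c(starts, pos)
        ends <- c(ends, pos + w - 1L)
        pos <- pos + w
        placed <- TRUE
        break
      }
    }
    if (!placed) pos <- pos + step
  }

  if (length(labels) == 0L) {
    warning("no qualifying quiet or whisking windows found")
    ep <- data.frame(label = character(0), start_s = numeric(0),
                     end_s = numeric(0), onset_s = numeric(0))
    return(structure(list(epochs = ep, sweep_id = trace$sweep_id),
                     class = "epoch_set"))
  }

  onset <- rep(NA_real_, length(labels))
  sgn <- if (config$protraction_positive) 1 else -1
  for (i in which(labels == "whisking")) {
    prev_q <- which(labels == "quiet" & ends < starts[i])
    if (length(prev_q) == 0L) next
    q <- prev_q[which.max(ends[prev_q])]
    baseline <- stats::median(sgn * trace$angle[starts[q]:ends[q]])
    # the 1-degree crossing belonging to this movement: walk back from the
    # epoch start to the last sub-threshold sample (slow pre-bout movement can
    # begin inside the preceding low-envelope window), then forward to the
    # first sample above threshold
    scan <- starts[q]:ends[i]
    above <- sgn * trace$angle[scan] > baseline + config$onset_threshold
    pre <- which(!above & scan <= starts[i])
    from <- if (length(pre)) pre[length(pre)] + 1L else 1L
    hit <- which(above & seq_along(scan) >= from)
    if (length(hit)) onset[i] <- trace$t0 + (scan[hit[1L]] - 1L) / fs
  }

  ep <- data.frame(label = labels,
                   start_s = trace$t0 + (starts - 1L) / fs,
                   end_s = trace$t0 + ends / fs,
                   onset_s = onset)
  structure(list(epochs = ep, sweep_id = trace$sweep_id), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  tab <- table(x$epochs$label)
  cat(sprintf("epoch_set (sweep %s): %s\n", format(x$sweep_id),
              paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", ")))
  invisible(x)
}

# Logical per-sample mask for epochs of a given label.
epoch_mask <- function(epochs, label, n, sample_rate, t0 = 0) {
  mask <- logical(n)
  ep <- epochs$epochs[epochs$epochs$label == label, , drop = FALSE]
  for (i in seq_len(nrow(ep))) {
    a <- max(1L, as.integer(floor((ep$start_s[i] - t0) * sample_rate)) + 1L)
    b <- min(n, as.integer(ceiling((ep$end_s[i] - t0) * sample_rate)))
    if (b >= a) mask[a:b] <- TRUE
  }
  mask
}

#' Per-epoch kinematic summaries
#'
#' For each whisking epoch: mean whisking amplitude, midpoint and setpoint
#' excursions (max minus min), mean peak protraction and retraction speeds
#' (deg/s, per half-cycle), and mean whisk-cycle duration
#' (inter-protraction-event interval).
#'
#' @param decomp A [decompose_whisking()] result.
#' @param epochs A [segment_epochs()] result.
#' @param trace The raw [whisker_trace()] (for angular velocity).
#' @return Data frame, one row per whisking epoch.
#' @export
kinematic_summaries <- function(decomp, epochs, trace) {
  stopifnot(inherits(decomp, "kinematic_decomposition"),
            inherits(epochs, "epoch_set"))
  fs <- decomp$sample_rate
  ep <- epochs$epochs[epochs$epochs$label == "whisking", , drop = FALSE]
  vel <- c(NA, diff(trace$angle)) * fs   # deg/s
  pe <- decomp$protraction_events
  re <- decomp$retraction_events
  all_ev <- sort(c(pe, re))
  out <- lapply(seq_len(nrow(ep)), function(i) {
    a <- as.integer(floor((ep$start_s[i] - decomp$t0) * fs)) + 1L
    b <- min(length(decomp$phase), as.integer(ceiling((ep$end_s[i] - decomp$t0) * fs)))
    rng <- a:b
    pe_in <- pe[pe >= a & pe <= b]
    ev_in <- all_ev[all_ev >= a & all_ev <= b]
    prot_speed <- retr_speed <- NA_real_
    if (length(ev_in) >= 2L) {
      ps <- rs <- numeric(0)
      for (j in seq_len(length(ev_in) - 1L)) {
        seg <- vel[ev_in[j]:ev_in[j + 1L]]
        if (ev_in[j + 1L] %in% pe) {          # half-cycle ends at protraction
          ps <- c(ps, max(seg, na.rm = TRUE))
        } else {
          rs <- c(rs, -min(seg, na.rm = TRUE))
        }
      }
      if (length(ps)) prot_speed <- mean(ps)
      if (length(rs)) retr_speed <- mean(rs)
    }
    data.frame(
      epoch_start_s = ep$start_s[i],
      epoch_end_s = ep$end_s[i],
      mean_amplitude = mean(decomp$amplitude[rng]),
      midpoint_excursion = diff(range(decomp$midpoint[rng])),
      setpoint_excursion = diff(range(decomp$setpoint[rng])),
      protraction_speed = prot_speed,
      retraction_speed = retr_speed,
      cycle_duration = if (length(pe_in) >= 2L) mean(diff(pe_in)) / fs else NA_real_
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Reconstruct the whisker angle from its decomposition
#'
#' The reconstruction is midpoint + amplitude * cos(phase): with phase 0 at
#' peak protraction the cosine carries the rhythmic component and the
#' midpoint the slow one.
#'
#' @param decomp A [decompose_whisking()] result.
#' @param trace Optional raw trace; when supplied the RMS reconstruction
#'   error is returned alongside.
#' @return List with `angle` (reconstructed trace) and, when `trace` is
#'   given, `rms_error`.
#' @export
reconstruct_whisker <- function(decomp, trace = NULL) {
  stopifnot(inherits(decomp, "kinematic_decomposition"))
  amp <- decomp$amplitude
  amp[is.na(amp)] <- 0
  mid <- decomp$midpoint
  if (all(is.na(mid))) mid <- decomp$setpoint
  sgn <- if (isFALSE(decomp$protraction_positive)) -1 else 1
  rec <- mid + sgn * amp * cos(decomp$phase)
  out <- list(angle = rec)
  if (!is.null(trace)) {
    out$rms_error <- sqrt(mean((rec - trace$angle)^2))
  }
  out
}
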