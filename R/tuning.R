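# Tuning of firing rate to whisking variables (phase, amplitude, midpoint):
# equal-probability binning, occupancy-normalized rate histograms, spline
# smoothing, a two-step ANOVA + shuffle significance test, and modulation
# depth / index statistics.

#' Equal-probability bin edges
#'
#' Splits the sorted samples into `n_bins` groups of (as near as possible)
#' equal size and places edges halfway between adjacent group-boundary
#' samples, so every bin carries probability 1/n_bins up to one sample.
#' Heavy ties that collapse edges are merged and flagged.
#'
#' @param x Numeric samples of the variable during whisking.
#' @param n_bins Number of bins (default 50).
#' @param range Optional known support, e.g. `c(-pi, pi)` for phase; used
#'   for the outer edges.
#' @return List with `edges` (length `n_bins + 1` or fewer after merging),
#'   `n_bins`, `merged` flag.
#' @export
equal_probability_bins <- function(x, n_bins = 50L, range = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < n_bins) stop("need at least n_bins distinct samples")
  xs <- sort(x)
  cut_idx <- floor(seq_len(n_bins - 1L) * n / n_bins)
  inner <- (xs[cut_idx] + xs[cut_idx + 1L]) / 2
  lo <- if (!is.null(range)) range[1] else xs[1L] - 1e-9 * max(1, abs(xs[1L]))
  hi <- if (!is.null(range)) range[2] else xs[n] + 1e-9 * max(1, abs(xs[n]))
  edges <- c(lo, inner, hi)
  merged <- anyDuplicated(edges) > 0L
  if (merged) edges <- unique(edges)
  list(edges = edges, n_bins = length(edges) - 1L, merged = merged)
}

#' Precompute the binning design linking kinematics to spike tuning
#'
#' Restricts to whisking-epoch samples (phase and amplitude are meaningless
#' when the whisker is still), bins the chosen variable into
#' equal-probability bins, and identifies "bin visits" -- maximal runs of
#' consecutive samples falling in the same bin -- which are the response
#' samples of the significance test. Several units recorded over the same
#' sweep share one design.
#'
#' @param decomp A [decompose_whisking()] result (or generator truth wrapped
#'   in the same fields).
#' @param epochs An [segment_epochs()] result.
#' @param variable One of `"phase"`, `"amplitude"`, `"midpoint"`.
#' @param config A [whiskephys_config()].
#' @return Object of class `tuning_design`.
#' @export
tuning_design <- function(decomp, epochs, variable = c("phase", "amplitude", "midpoint"),
                          config = whiskephys_config()) {
  variable <- match.arg(variable)
  v <- decomp[[variable]]
  n <- length(v)
  fs <- decomp$sample_rate
  mask <- epoch_mask(epochs, "whisking", n, fs, decomp$t0) & is.finite(v)
  if (sum(mask) < config$n_tuning_bins) {
    stop("not enough whisking samples to form equal-probability bins")
  }
  rng <- if (variable == "phase") c(-pi, pi) else NULL
  bins <- equal_probability_bins(v[mask], config$n_tuning_bins, range = rng)
  b <- rep(NA_integer_, n)
  b[mask] <- pmin(pmax(findInterval(v[mask], bins$edges,
                                    rightmost.closed = TRUE), 1L), bins$n_bins)
  # visits: runs of consecutive masked samples in one bin
  idx <- which(mask)
  new_visit <- c(TRUE, diff(idx) != 1L | diff(b[idx]) != 0L)
  visit_id <- cumsum(new_visit)
  visit_of_sample <- rep(NA_integer_, n)
  visit_of_sample[idx] <- visit_id
  visit_bin <- b[idx][new_visit]
  visit_len <- tabulate(visit_id)
  occupancy <- tabulate(b[idx], nbins = bins$n_bins) / fs
  centers <- (bins$edges[-1L] + bins$edges[-length(bins$edges)]) / 2
  structure(list(variable = variable, edges = bins$edges,
                 n_bins = bins$n_bins, merged = bins$merged,
                 bin_centers = centers, occupancy_s = occupancy,
                 sample_bin = b, visit_of_sample = visit_of_sample,
                 visit_bin = visit_bin, visit_dur_s = visit_len / fs,
                 n_visits = length(visit_bin), sample_rate = fs, t0 = decomp$t0),
            class = "tuning_design")
}

# Spike -> sample index on the design grid; spikes outside whisking get NA.
spikes_to_samples <- function(spike_times, design) {
  i <- as.integer(floor((spike_times - design$t0) * design$sample_rate)) + 1L
  i[i < 1L | i > length(design$sample_bin)] <- NA_integer_
  i
}

#' Occupancy-normalized tuning histogram
#'
#' Rate in each bin is the number of spikes whose concurrent variable value
#' falls in the bin divided by the time spent there.
#'
#' @param spike_times Spike times (s) of one unit.
#' @param design A [tuning_design()].
#' @return List with `raw_rates` (Hz per bin), `occupancy_s`, `spike_counts`.
#' @export
tuning_histogram <- function(spike_times, design) {
  i <- spikes_to_samples(spike_times, design)
  sb <- design$sample_bin[i[!is.na(i)]]
  sb <- sb[!is.na(sb)]
  counts <- tabulate(sb, nbins = design$n_bins)
  list(raw_rates = counts / design$occupancy_s, occupancy_s = design$occupancy_s,
       spike_counts = counts)
}

#' Smooth a binned tuning curve
#'
#' Penalized regression-spline smoothing (cyclic for phase, cubic
#' otherwise) with smoothness chosen by generalized cross-validation,
#' weighted by bin occupancy; the smoothed curve is floored at zero.
#'
#' @param raw_rates Hz per bin.
#' @param design A [tuning_design()] (supplies centers, occupancy,
#'   periodicity).
#' @param n_grid Evaluation grid size.
#' @return List with `x` (grid), `y` (Hz), `max`, `min`, `preferred`
#'   (argmax), `flat` flag.
#' @export
smooth_tuning_curve <- function(raw_rates, design, n_grid = 256L) {
  ok <- is.finite(raw_rates)
  if (sum(ok) < 10L) stop("need at least 10 bins with defined rates")
  x <- design$bin_centers[ok]
  y <- raw_rates[ok]
  w <- design$occupancy_s[ok]
  periodic <- design$variable == "phase"
  if (all(y == 0)) {
    grid <- seq(min(x), max(x), length.out = n_grid)
    return(list(x = grid, y = rep(0, n_grid), max = 0, min = 0,
                preferred = NA_real_, flat = TRUE))
  }
  if (periodic) {
    k <- min(12L, sum(ok) - 1L)
    fit <- mgcv::gam(y ~ s(x, bs = "cc", k = k), weights = w,
                     knots = list(x = seq(-pi, pi, length.out = k)))
    grid <- seq(-pi, pi, length.out = n_grid + 1L)[-1L]
  } else {
    k <- min(12L, sum(ok) - 1L)
    fit <- mgcv::gam(y ~ s(x, bs = "cr", k = k), weights = w)
    grid <- seq(min(x), max(x), length.out = n_grid)
  }
  yy <- pmax(as.numeric(mgcv::predict.gam(fit, newdata = data.frame(x = grid))), 0)
  flat <- (max(yy) - min(yy)) < 1e-12
  list(x = grid, y = yy, max = max(yy), min = min(yy),
       preferred = if (flat) NA_real_ else grid[which.max(yy)], flat = flat)
}

# One-way ANOVA F from group sums (used identically for the observed and
# every shuffled labelling; agreement with stats::oneway.test is covered by
# a unit test).
anova_f_stat <- function(y, group_sums, n_per_group, sst, n, k) {
  ssb <- sum(group_sums^2 / n_per_group) - n * mean(y)^2
  ssw <- sst - ssb
  if (ssw <= 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Two-step tuning significance test
#'
#' Step 1: one-way ANOVA of per-bin-visit firing rates across bins at level
#' `alpha`. Step 2 (only for units passing step 1): the visit responses are
#' shuffled across bin labels `n_shuffles` times, the ANOVA F recomputed
#' each time, and the unit declared tuned when the observed F exceeds the
#' 95th percentile of the shuffled F distribution. `p_shuffle` is the
#' fraction of shuffled F values at or above the observed one.
#'
#' @param spike_times Spike times (s) of one unit.
#' @param design A [tuning_design()].
#' @param config A [whiskephys_config()] (`n_shuffles`, `alpha`,
#'   `shuffle_percentile`).
#' @param seed Integer seed for the shuffles.
#' @return List with `tuned`, `p_anova`, `p_shuffle`, `f_observed`,
#'   `untestable`.
#' @export
test_tuning <- function(spike_times, design, config = whiskephys_config(),
                        seed = config$seed) {
  n <- design$n_visits
  k <- design$n_bins
  if (n / k < 2) {
    return(list(tuned = FALSE, p_anova = NA_real_, p_shuffle = NA_real_,
                f_observed = NA_real_, untestable = TRUE))
  }
  i <- spikes_to_samples(spike_times, design)
  vi <- design$visit_of_sample[i[!is.na(i)]]
  vi <- vi[!is.na(vi)]
  y <- tabulate(vi, nbins = n) / design$visit_dur_s
  g <- design$visit_bin
  # bins with no visits (possible after heavy tie merging) drop out of the test
  present <- sort(unique(g))
  k <- length(present)
  g <- match(g, present)
  n_per <- tabulate(g, nbins = k)
  s_obs <- numeric(k)
  rs <- rowsum(y, g, reorder = TRUE)
  s_obs[as.integer(rownames(rs))] <- rs[, 1L]
  sst <- sum(y^2) - n * mean(y)^2
  if (sst <= 0) {
    return(list(tuned = FALSE, p_anova = 1, p_shuffle = NA_real_,
                f_observed = 0, untestable = FALSE))
  }
  f_obs <- anova_f_stat(y, s_obs, n_per, sst, n, k)
  p_anova <- stats::pf(f_obs, k - 1, n - k, lower.tail = FALSE)
  if (p_anova >= config$alpha) {
    return(list(tuned = FALSE, p_anova = p_anova, p_shuffle = NA_real_,
                f_observed = f_obs, untestable = FALSE))
  }
  set.seed(derive_seed(seed, "tuning-shuffle"))
  ends <- cumsum(n_per)
  # permuting y across visits only moves its nonzero entries (visits holding
  # spikes); group sums of a random permutation are obtained by dropping the
  # nonzero responses uniformly without replacement into the index blocks
  nz <- which(y != 0)
  yz <- y[nz]
  m <- length(nz)
  f_sh <- numeric(config$n_shuffles)
  for (s in seq_len(config$n_shuffles)) {
    pos <- sample.int(n, m)
    gpos <- findInterval(pos - 0.5, c(0, ends))
    gs <- numeric(k)
    rs <- rowsum(yz, gpos, reorder = TRUE)
    gs[as.integer(rownames(rs))] <- rs[, 1L]
    f_sh[s] <- anova_f_stat(y, gs, n_per, sst, n, k)
  }
  crit <- stats::quantile(f_sh, config$shuffle_percentile, names = FALSE)
  list(tuned = f_obs > crit,
       p_shuffle = mean(f_sh >= f_obs),
       p_anova = p_anova, f_observed = f_obs, untestable = FALSE)
}

#' Modulation depth, index and preferred value of a tuning curve
#'
#' Depth is `(max - min) / baseline` (baseline: the unit's mean rate over
#' quiet epochs); index is `(max - min) / (max + min)`, in `[0, 1]`.
#'
#' @param curve A [smooth_tuning_curve()] result.
#' @param baseline_rate Baseline firing rate (Hz); `NA` or 0 flags depth
#'   undefined.
#' @return List with `modulation_depth`, `modulation_index`,
#'   `preferred_value`.
#' @export
curve_statistics <- function(curve, baseline_rate) {
  depth <- if (is.na(baseline_rate) || baseline_rate <= 0) NA_real_
           else (curve$max - curve$min) / baseline_rate
  index <- if (curve$max + curve$min <= 0) NA_real_
           else (curve$max - curve$min) / (curve$max + curve$min)
  list(modulation_depth = depth, modulation_index = index,
       preferred_value = curve$preferred)
}

#' Full tuning analysis of one unit for one whisking variable
#'
#' Convenience wrapper chaining [tuning_histogram()],
#' [smooth_tuning_curve()], [test_tuning()] and [curve_statistics()].
#'
#' @param unit A [spike_unit()].
#' @param design A [tuning_design()].
#' @param baseline_rate Baseline (quiet-epoch) rate in Hz for the depth.
#' @param config A [whiskephys_config()].
#' @param seed Shuffle seed.
#' @return Object of class `tuning_result`.
#' @export
tuning_curve <- function(unit, design, baseline_rate = NA_real_,
                         config = whiskephys_config(), seed = config$seed) {
  hist <- tuning_histogram(unit$spike_times, design)
  curve <- smooth_tuning_curve(hist$raw_rates, design)
  test <- test_tuning(unit$spike_times, design, config, seed)
  stats <- curve_statistics(curve, baseline_rate)
  structure(c(list(unit_id = unit$unit_id, variable = design$variable,
                   bin_centers = design$bin_centers,
                   raw_rates = hist$raw_rates, occupancy_s = hist$occupancy_s,
                   curve_x = curve$x, curve_y = curve$y,
                   max_rate = curve$max, min_rate = curve$min,
                   baseline_rate = baseline_rate),
              test, stats),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("tuning_result: unit %s, variable %s\n", format(x$unit_id), x$variable))
  cat(sprintf("  tuned: %s (ANOVA p = %.3g, shuffle p = %s, F = %.2f)\n",
              x$tuned, x$p_anova,
              if (is.na(x$p_shuffle)) "-" else format(x$p_shuffle, digits = 3),
              x$f_observed))
  cat(sprintf("  rate range [%.2f, %.2f] Hz, depth %.2f, index %.2f, preferred %.3g\n",
              x$min_rate, x$max_rate,
              ifelse(is.na(x$modulation_depth), NaN, x$modulation_depth),
              ifelse(is.na(x$modulation_index), NaN, x$modulation_index),
              ifelse(is.na(x$preferred_value), NaN, x$preferred_value)))
  invisible(x)
}

#' @export
plot.tuning_result <- function(x, ...) {
  graphics::plot(x$bin_centers, x$raw_rates, pch = 16, col = "grey50",
                 xlab = x$variable, ylab = "rate (Hz)", ...)
  graphics::lines(x$curve_x, x$curve_y, col = 2, lwd = 2)
  if (!is.na(x$preferred_value)) graphics::abline(v = x$preferred_value, lty = 2)
  invisible(x)
}

#' Preferred-phase shift between conditions
#'
#' Circular difference (on minus off) of preferred phases per unit, wrapped
#' to (-pi, pi], with a cohort summary (circular mean, SE) and a Wilcoxon
#' signed-rank test of the wrapped shifts against zero.
#'
#' @param preferred_off,preferred_on Preferred phases (radians) per unit.
#' @return List with `shift` (per unit), `mean_shift`, `se_shift`, `p`.
#' @export
phase_shift_report <- function(preferred_off, preferred_on) {
  stopifnot(length(preferred_off) == length(preferred_on))
  shift <- circ_diff(preferred_on, preferred_off)
  ok <- is.finite(shift)
  p <- if (sum(ok) >= 2L && any(shift[ok] != 0)) {
    suppressWarnings(stats::wilcox.test(shift[ok])$p.value)
  } else if (sum(ok) >= 1L && all(shift[ok] == 0)) 1 else NA_real_
  list(shift = shift, mean_shift = circ_mean(shift[ok]),
       se_shift = if (sum(ok) > 1L) stats::sd(shift[ok]) / sqrt(sum(ok)) else NA_real_,
       p = p)
}
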