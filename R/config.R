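#' Analysis configuration with field-standard defaults
#'
#' Collects every tunable threshold and parameter of the pipeline in one
#' list. Defaults follow the conventions of awake-rodent whisking
#' electrophysiology: a 4-25 Hz whisking band, 6 Hz setpoint cutoff,
#' quiet/whisking classification windows of 1, 2 or 3 s, a 1 degree
#' above-baseline whisking-onset rule, 0.4/0.5 ms waveform cuts separating
#' fast-spiking from regular-spiking units, 50 equal-probability tuning bins
#' with a 1,000-iteration shuffle test at the 95th percentile, 2 s bins for
#' rate Z-scoring, 200 ms peri-event bins with a -1.0 to -0.2 s baseline,
#' a 1-5 Hz slow-wave band integrated over 2 s FFT segments, a 100 Hz LFP
#' low-pass, and a 500 um subpial anchor depth for the layer-4 center.
#'
#' @param ... Named overrides for any default listed below.
#' @return A list of class `whiskephys_config`.
#' @examples
#' cfg <- whiskephys_config(n_shuffles = 200)
#' cfg$whisk_band
#' @export
whiskephys_config <- function(...) {
  cfg <- list(
    # whisker kinematics
    whisk_band          = c(4, 25),    # Hz, band-pass for phase extraction
    setpoint_cutoff     = 6,           # Hz, low-pass for setpoint
    filter_order        = 2L,          # per pass; filtfilt doubles the order
    window_lengths      = c(3, 2, 1),  # s, preferred epoch windows, longest first
    onset_threshold     = 1,           # deg above baseline defines whisking onset
    whisk_envelope_min  = 2.5,         # deg, envelope floor for a whisking window
    quiet_envelope_max  = 1,           # deg, envelope ceiling for a quiet window
    protraction_positive = TRUE,       # increasing angle = protraction
    # spike analysis
    fs_max_trough_to_peak = 0.4,       # ms, below: fast-spiking
    rs_min_trough_to_peak = 0.5,       # ms, above: regular-spiking
    zscore_bin          = 2,           # s, bin for rate Z-scoring
    peth_bin            = 0.2,         # s, peri-event histogram bin
    peth_baseline       = c(-1.0, -0.2), # s relative to onset
    peth_smooth_sd      = 1,           # bins, Gaussian smoothing SD
    min_epochs_per_label = 5L,         # to test whisking modulation
    alpha               = 0.05,
    # tuning analysis
    n_tuning_bins       = 50L,
    n_shuffles          = 1000L,
    shuffle_percentile  = 0.95,
    # membrane potential
    vm_band             = c(1, 5),     # Hz, slow-wave band
    fft_segment         = 2,           # s, FFT segment length
    dvdt_threshold      = 10,          # V/s, spike detection on Vm
    spike_refractory    = 0.002,       # s
    spike_excision      = c(-0.001, 0.004), # s around AP peak
    n_phase_bins_vm     = 64L,
    min_whisk_cycles    = 20L,
    # LFP / CSD
    lfp_cutoff          = 100,         # Hz low-pass
    lfp_rate_spectra    = 1000,        # Hz target rate for spectra
    lfp_rate_csd        = 3000,        # Hz target rate for CSD
    min_spectrum_epoch  = 2,           # s
    sink_onset_fraction = 0.2,         # of peak negative CSD
    l4_anchor_depth     = 500,         # um subpial depth of the L4 center
    touch_window        = c(-0.01, 0.05), # s around touch for averaging
    # editable laminar boundary table (um below pia); values are
    # configuration, drawn from standard mouse barrel-cortex anatomy
    layer_boundaries    = c(L1 = 0, `L2/3` = 128, L4 = 418, L5 = 588,
                            L6 = 890, WM = 1154),
    seed                = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  class(cfg) <- "whiskephys_config"
  cfg
}

#' Read or write a configuration file
#'
#' Configurations round-trip losslessly through YAML (or JSON, by file
#' extension).
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param cfg A `whiskephys_config` object (for writing).
#' @return `read_config` returns a `whiskephys_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "whiskephys_config"))
  x <- unclass(cfg)
  x$layer_boundaries <- as.list(x$layer_boundaries)  # keep the layer names
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # restore types that YAML flattens
  ints <- c("filter_order", "min_epochs_per_label", "n_tuning_bins",
            "n_shuffles", "n_phase_bins_vm", "min_whisk_cycles", "seed")
  for (f in intersect(ints, names(x))) x[[f]] <- as.integer(x[[f]])
  lb <- x$layer_boundaries
  if (!is.null(lb) && is.list(lb)) x$layer_boundaries <- unlist(lb)
  if (!is.null(x$layer_boundaries)) {
    x$layer_boundaries <- stats::setNames(as.numeric(x$layer_boundaries),
                                          names(x$layer_boundaries))
  }
  do.call(whiskephys_config, x)
}

#' @export
print.whiskephys_config <- function(x, ...) {
  cat("whiskephys analysis configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]], digits = 4), collapse = " ")))
  }
  invisible(x)
}
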