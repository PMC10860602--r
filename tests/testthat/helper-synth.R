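# Shared fixture builders. Everything is generated in code at test time.

# Continuous whisking over `dur` seconds: contiguous bouts of varying
# frequency/amplitude, decomposed by the pipeline, with one whisking epoch.
make_whisking_session <- function(dur = 300, seed = 1L,
                                  freqs = c(8, 10, 12, 9, 11, 10),
                                  amps = c(10, 8, 12, 9, 11, 10),
                                  mids = c(15, 12, 18, 14, 16, 15)) {
  nb <- length(freqs)
  edges <- seq(0, dur, length.out = nb + 1L)
  bs <- data.frame(start_s = edges[-(nb + 1L)], end_s = edges[-1L],
                   freq_hz = freqs, amplitude_deg = amps, midpoint_deg = mids)
  p <- whisk_gen_params(dur, bout_schedule = bs, seed = seed)
  sim <- simulate_whisker_trace(p)
  decomp <- decompose_whisking(sim$trace)
  epochs <- structure(list(
    epochs = data.frame(label = "whisking", start_s = 0, end_s = dur,
                        onset_s = 0),
    sweep_id = 1L), class = "epoch_set")
  list(sim = sim, trace = sim$trace, decomp = decomp, epochs = epochs)
}

# Quiet / whisking alternation with enough epochs per label for modulation
# classification tests.
make_alternating_session <- function(n_blocks = 35, block_s = 3, seed = 1L) {
  starts <- (seq_len(n_blocks) - 1L) * 2 * block_s + block_s
  bs <- data.frame(start_s = starts, end_s = starts + block_s,
                   freq_hz = 10, amplitude_deg = 10, midpoint_deg = 15)
  dur <- n_blocks * 2 * block_s
  p <- whisk_gen_params(dur, bout_schedule = bs, quiet_noise_sd = 0.15,
                        seed = seed)
  sim <- simulate_whisker_trace(p)
  decomp <- decompose_whisking(sim$trace)
  epochs <- segment_epochs(sim$trace, decomp = decomp)
  list(sim = sim, trace = sim$trace, decomp = decomp, epochs = epochs,
       duration = dur)
}

# Map a 500 Hz per-sample vector onto an n-sample grid by index resampling.
resample_to <- function(x, n) {
  x[pmin(length(x), pmax(1L, ceiling(seq_len(n) * (length(x) / n))))]
}

# Independent frequency-domain masking oracle: keep only DFT components
# within [lo, hi] Hz.
dft_mask_oracle <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  keep <- f >= lo & f <= hi
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE) / n)
}
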