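# Shared signal-processing and circular-statistics primitives.

#' Analytic signal via the frequency domain
#'
#' Computes the discrete analytic signal (the signal plus i times its Hilbert
#' transform) by zeroing negative frequencies of the DFT and doubling positive
#' ones. The complex argument of the result is the instantaneous phase; the
#' modulus is the instantaneous amplitude envelope.
#'
#' @param x Numeric vector (real-valued signal).
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for analytic-signal construction")
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Zero-phase Butterworth filtering with reflection padding to suppress edge
# transients. `type` is "pass" (length-2 w in Hz) or "low"/"high" (scalar).
zero_phase_filter <- function(x, sample_rate, w, type = c("pass", "low", "high"),
                              order = 2L) {
  type <- match.arg(type)
  n <- length(x)
  nyq <- sample_rate / 2
  if (any(w <= 0) || any(w >= nyq)) {
    stop("filter corner frequencies must lie strictly inside (0, Nyquist)")
  }
  bf <- signal::butter(order, w / nyq, type = type)
  pad <- min(n - 1L, as.integer(3 * sample_rate))
  xp <- c(2 * x[1L] - rev(x[2L:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1L):(pad + n)]
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Smallest signed circular difference a - b, in (-pi, pi].
circ_diff <- function(a, b) wrap_angle(a - b)

# Circular mean of angles (radians); NA when no input.
circ_mean <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  Arg(sum(complex(modulus = 1, argument = x)))
}

# Unwrap a wrapped phase sequence (cumulative, jump threshold pi).
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- c(0, cumsum(ifelse(d > pi, -2 * pi, ifelse(d < -pi, 2 * pi, 0))))
  p + jumps
}

# Trapezoid-rule integral of y over x.
trapz_integral <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

# Per-stream reproducible seeding: derive a 31-bit child seed from a master
# seed and a stream label, so independent generators never share streams.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}
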