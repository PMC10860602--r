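# Plain-text and binary-matrix I/O for traces, epochs, spikes and arrays.

#' Read and write whisker angle traces as CSV
#'
#' Columns `time_s`, `angle_deg`.
#'
#' @param trace A [whisker_trace()].
#' @param path File path.
#' @return `read_whisker_csv` returns a `whisker_trace`.
#' @export
write_whisker_csv <- function(trace, path) {
  stopifnot(inherits(trace, "whisker_trace"))
  utils::write.csv(data.frame(time_s = trace_times(trace),
                              angle_deg = trace$angle),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_whisker_csv
#' @export
read_whisker_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "angle_deg") %in% names(d)))
  fs <- 1 / stats::median(diff(d$time_s))
  whisker_trace(d$angle_deg, sample_rate = round(fs), t0 = d$time_s[1L])
}

#' Write a kinematic decomposition as CSV
#'
#' Columns `time_s`, `phase_rad`, `amp_deg`, `mid_deg`, `set_deg`.
#'
#' @param decomp A [decompose_whisking()] result.
#' @param path File path.
#' @export
write_decomposition_csv <- function(decomp, path) {
  t <- decomp$t0 + (seq_along(decomp$phase) - 1L) / decomp$sample_rate
  utils::write.csv(data.frame(time_s = t, phase_rad = decomp$phase,
                              amp_deg = decomp$amplitude,
                              mid_deg = decomp$midpoint,
                              set_deg = decomp$setpoint),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write epoch tables as CSV
#'
#' Columns `label`, `start_s`, `end_s`, `onset_s`.
#'
#' @param epochs An [segment_epochs()] result.
#' @param path File path.
#' @return `read_epochs_csv` returns an `epoch_set`.
#' @export
write_epochs_csv <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  utils::write.csv(epochs$epochs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs_csv
#' @export
read_epochs_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(d)))
  if (is.null(d$onset_s)) d$onset_s <- NA_real_
  structure(list(epochs = d, sweep_id = NA), class = "epoch_set")
}

#' Write spike tables as CSV
#'
#' Columns `unit_id`, `sweep_id`, `spike_time_s`.
#'
#' @param units List of [spike_unit()]s.
#' @param path File path.
#' @param sweep_id Sweep identifier recorded in the table.
#' @export
write_spikes_csv <- function(units, path, sweep_id = 1L) {
  if (inherits(units, "spike_unit")) units <- list(units)
  rows <- lapply(units, function(u) {
    if (!length(u$spike_times)) return(NULL)
    data.frame(unit_id = format(u$unit_id), sweep_id = sweep_id,
               spike_time_s = u$spike_times)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Binary float matrix with JSON sidecar
#'
#' The matrix is stored row-major as little-endian doubles in `<path>`,
#' with dimensions, units and any extra metadata (sample rate, channel
#' depths, light condition, touch times) in `<path>.json`.
#'
#' @param m Numeric matrix (rows = channels).
#' @param path Binary file path.
#' @param meta Named list of metadata stored in the sidecar.
#' @return `read_matrix_bin` returns a list with `m` and `meta`.
#' @export
write_matrix_bin <- function(m, path, meta = list()) {
  stopifnot(is.matrix(m))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(m)), con, size = 8L, endian = "little")
  side <- c(list(n_rows = nrow(m), n_cols = ncol(m), dtype = "float64",
                 order = "row-major", schema_version = 1L), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_matrix_bin
#' @export
read_matrix_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$n_rows * meta$n_cols, size = 8L,
               endian = "little")
  list(m = matrix(x, nrow = meta$n_rows, byrow = TRUE), meta = meta)
}
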