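#' Uniformly sampled signal trace
#'
#' Container for a voltage-clamp current trace (pA) or extracellular voltage
#' (uV): the sample vector, its sampling rate, units, a start time and free-
#' form metadata.
#'
#' @param samples numeric vector of samples; must be finite, length >= 2.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param units character, e.g. `"pA"` or `"uV"`.
#' @param t0_s start time in seconds (default 0).
#' @param meta optional named list of recording metadata.
#' @return object of class `trace`.
#' @export
trace <- function(samples, fs_hz, units = "pA", t0_s = 0, meta = list()) {
  samples <- as.numeric(samples)
  check_that(length(samples) >= 2, "trace needs at least 2 samples, got %d", length(samples))
  check_that(all(is.finite(samples)), "trace samples must be finite")
  check_that(is.numeric(fs_hz) && length(fs_hz) == 1 && fs_hz > 0, "fs_hz must be a positive scalar")
  structure(
    list(samples = samples, fs_hz = as.numeric(fs_hz), units = units,
         t0_s = as.numeric(t0_s), meta = meta),
    class = "trace"
  )
}

#' @export
length.trace <- function(x) length(x$samples)

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz (%.3f s), units %s\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz, x$units))
  invisible(x)
}

#' Time axis of a trace
#' @param tr a [trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(tr) {
  tr$t0_s + (seq_along(tr$samples) - 1) / tr$fs_hz
}

is_trace <- function(x) inherits(x, "trace")

#' Write / read a trace as CSV plus JSON sidecar
#'
#' The samples go to `<path>.csv` (one column, `value`), the sampling rate,
#' units and metadata to `<path>.json`.
#'
#' @param tr a [trace()].
#' @param path file stem (no extension).
#' @return `path`, invisibly (for `write_trace`); a [trace()] for `read_trace`.
#' @export
write_trace <- function(tr, path) {
  check_that(is_trace(tr), "not a trace")
  utils::write.csv(data.frame(value = tr$samples),
                   paste0(path, ".csv"), row.names = FALSE)
  side <- list(fs_hz = tr$fs_hz, units = tr$units, t0_s = tr$t0_s, meta = tr$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  v <- utils::read.csv(paste0(path, ".csv"))$value
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trace(v, fs_hz = side$fs_hz, units = side$units, t0_s = side$t0_s,
        meta = as.list(side$meta))
}

#' Recording-level inclusion filter for whole-cell recordings
#'
#' A recording is excluded when the holding current is more negative than
#' -200 pA (cell clamped at -70 mV) or the series resistance exceeds 25 MOhm.
#'
#' @param holding_current_pa holding current in pA.
#' @param series_resistance_mohm series resistance in MOhm.
#' @return list with `include` (logical) and `reason` (character, `""` when
#'   included).
#' @export
include_recording <- function(holding_current_pa, series_resistance_mohm) {
  reasons <- character(0)
  if (is.finite(holding_current_pa) && holding_current_pa < -200) {
    reasons <- c(reasons, "holding current")
  }
  if (is.finite(series_resistance_mohm) && series_resistance_mohm > 25) {
    reasons <- c(reasons, "series resistance")
  }
  list(include = length(reasons) == 0, reason = paste(reasons, collapse = "; "))
}
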