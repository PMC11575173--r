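#' @keywords internal
"_PACKAGE"

#' @importFrom stats mad median sd quantile rnorm rpois runif rlnorm rexp
#'   rgeom fft nextn kmeans nls coef predict approx t.test aov ks.test
#'   kruskal.test ecdf runmed complete.cases setNames
#' @importFrom utils head tail write.csv read.csv
#' @importFrom graphics hist
NULL

# Run code with a seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Robust standard deviation (scaled median absolute deviation)
#'
#' `1.4826 * MAD`, consistent with the SD of a Gaussian but insensitive to
#' the sparse large excursions that synaptic events add to a noise trace.
#'
#' @param x numeric vector.
#' @return scalar robust SD estimate.
#' @export
robust_sd <- function(x) {
  stats::mad(x, constant = 1.4826, na.rm = TRUE)
}

# Centered moving average, output same length; edges use truncated windows.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Zero-phase Butterworth filtering (forward-backward, 4th order by default).
butter_filtfilt <- function(x, fs, low = NULL, high = NULL, order = 4) {
  nyq <- fs / 2
  if (!is.null(low))  check_that(low > 0 && low < nyq, "low cutoff %g Hz outside (0, Nyquist %g)", low, nyq)
  if (!is.null(high)) check_that(high > 0 && high < nyq, "high cutoff %g Hz outside (0, Nyquist %g)", high, nyq)
  filt <- if (!is.null(low) && !is.null(high)) {
    signal::butter(order %/% 2, c(low, high) / nyq, type = "pass")
  } else if (!is.null(low)) {
    signal::butter(order, low / nyq, type = "high")
  } else {
    signal::butter(order, high / nyq, type = "low")
  }
  as.numeric(signal::filtfilt(filt, x))
}

# Analytic signal via FFT: zero negative frequencies, double positive ones.
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Start/end indices of maximal runs where `mask` is TRUE.
find_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
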