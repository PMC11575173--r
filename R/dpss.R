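#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth
#' product `nw` from the classical symmetric-tridiagonal formulation, whose
#' eigenvectors are the tapers ordered by eigenvalue. The top-k eigenpairs
#' are found by Sturm-sequence bisection plus inverse iteration (O(n) per
#' solve), so long segments are cheap. Tapers are unit-energy and follow
#' the usual polarity convention (positive mean for symmetric orders,
#' positive initial slope for antisymmetric ones).
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (e.g. 3).
#' @param k number of tapers (must satisfy `k <= 2*nw - 1` for good
#'   concentration).
#' @return `n x k` matrix, one taper per column, order 0 first.
#' @export
dpss_tapers <- function(n, nw, k) {
  check_that(n >= 8, "taper length too short")
  check_that(k >= 1 && k <= 2 * nw - 1, "need 1 <= k <= 2*nw - 1")
  w <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2  # off-diagonal

  # count of eigenvalues of the tridiagonal < x (Sturm sequence)
  count_below <- function(x) {
    cnt <- 0L
    q <- d[1] - x
    if (q < 0) cnt <- 1L
    for (j in 2:n) {
      if (q == 0) q <- .Machine$double.eps
      q <- d[j] - x - e[j - 1]^2 / q
      if (q < 0) cnt <- cnt + 1L
    }
    cnt
  }

  # bisection for the m-th largest eigenvalue (m = 1 is largest)
  gersh <- range(c(d[1] - abs(e[1]), d[n] - abs(e[n - 1]),
                   d[-c(1, n)] - abs(e[-1]) - abs(e[-(n - 1)]),
                   d[1] + abs(e[1]), d[n] + abs(e[n - 1]),
                   d[-c(1, n)] + abs(e[-1]) + abs(e[-(n - 1)])))
  kth_largest <- function(m) {
    lo <- gersh[1]; hi <- gersh[2]
    target <- n - m  # want count_below(x) == n - m just below the eigenvalue
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (count_below(mid) >= target + 1) hi <- mid else lo <- mid
      if (hi - lo < 1e-10 * max(1, abs(hi))) break
    }
    (lo + hi) / 2
  }

  # tridiagonal solve (Thomas algorithm with the shifted diagonal)
  tri_solve <- function(shift, b) {
    dd <- d - shift
    cp <- numeric(n - 1); dp <- numeric(n)
    denom <- dd[1]
    if (abs(denom) < 1e-300) denom <- 1e-300
    cp[1] <- e[1] / denom
    dp[1] <- b[1] / denom
    for (j in 2:n) {
      denom <- dd[j] - e[j - 1] * cp[j - 1]
      if (abs(denom) < 1e-300) denom <- 1e-300
      if (j < n) cp[j] <- e[j] / denom
      dp[j] <- (b[j] - e[j - 1] * dp[j - 1]) / denom
    }
    v <- numeric(n)
    v[n] <- dp[n]
    for (j in (n - 1):1) v[j] <- dp[j] - cp[j] * v[j + 1]
    v
  }

  tapers <- matrix(0, n, k)
  for (m in seq_len(k)) {
    lam <- kth_largest(m)
    v <- sin(pi * seq_len(n) * m / (n + 1))  # generic start, no symmetry bias
    for (it in 1:4) {
      v <- tri_solve(lam * (1 + 1e-9) + 1e-9, v)
      if (m > 1) {
        prev <- tapers[, seq_len(m - 1), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      v <- v / sqrt(sum(v^2))
    }
    # polarity convention
    if (m %% 2 == 1) {
      if (sum(v) < 0) v <- -v
    } else {
      if (v[2] - v[1] < 0) v <- -v
    }
    tapers[, m] <- v
  }
  tapers
}
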