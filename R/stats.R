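#' Group comparison with the study's standard tests
#'
#' Thin reporting layer around the classical tests used for group contrasts:
#' Welch's t, Kolmogorov-Smirnov, Kruskal-Wallis, or two-way ANOVA
#' (group x pulse) for evoked-train profiles.
#'
#' @param values_a,values_b numeric vectors (for `two_way_anova`, matrices
#'   with one row per cell and one column per pulse).
#' @param test one of `"welch_t"`, `"ks"`, `"kruskal_wallis"`,
#'   `"two_way_anova"`.
#' @return list of class `comparison_result`: `test`, `statistic`,
#'   `p_value`, `mean_a`, `mean_b`, `sem_a`, `sem_b`, `n_a`, `n_b`; for the
#'   ANOVA additionally `p_group`, `p_pulse`, `p_interaction` (with
#'   `p_value = p_group`).
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("welch_t", "ks", "kruskal_wallis",
                                    "two_way_anova")) {
  test <- match.arg(test)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  if (test == "two_way_anova") {
    check_that(is.matrix(values_a) && is.matrix(values_b) &&
                 ncol(values_a) == ncol(values_b),
               "two_way_anova needs cell x pulse matrices with equal pulse count")
    check_that(nrow(values_a) >= 2 && nrow(values_b) >= 2, "need >= 2 cells per group")
    n_p <- ncol(values_a)
    df <- data.frame(
      y = c(as.vector(t(values_a)), as.vector(t(values_b))),
      group = factor(rep(c("a", "b"), c(length(values_a), length(values_b)))),
      pulse = factor(rep(rep(seq_len(n_p), nrow(values_a) + nrow(values_b))))
    )
    fit <- stats::aov(y ~ group * pulse, data = df)
    tab <- summary(fit)[[1]]
    p <- tab[["Pr(>F)"]]
    res <- list(test = test, statistic = tab[["F value"]][1], p_value = p[1],
                p_group = p[1], p_pulse = p[2], p_interaction = p[3],
                mean_a = mean(values_a), mean_b = mean(values_b),
                sem_a = sem(as.vector(values_a)), sem_b = sem(as.vector(values_b)),
                n_a = nrow(values_a), n_b = nrow(values_b))
    return(structure(res, class = "comparison_result"))
  }
  check_that(length(values_a) >= 2 && length(values_b) >= 2,
             "need at least 2 observations per group")
  r <- switch(test,
    welch_t = stats::t.test(values_a, values_b, var.equal = FALSE),
    ks = suppressWarnings(stats::ks.test(values_a, values_b)),
    kruskal_wallis = stats::kruskal.test(list(values_a, values_b))
  )
  structure(list(test = test, statistic = unname(r$statistic),
                 p_value = r$p.value,
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 sem_a = sem(values_a), sem_b = sem(values_b),
                 n_a = length(values_a), n_b = length(values_b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> stat %.3g, p = %.3g (a: %.3g +/- %.3g, n=%d; b: %.3g +/- %.3g, n=%d)\n",
              x$test, x$statistic, x$p_value, x$mean_a, x$sem_a, x$n_a,
              x$mean_b, x$sem_b, x$n_b))
  invisible(x)
}

#' Empirical cumulative distribution
#'
#' @param values non-empty numeric vector.
#' @return data.frame: `value` (sorted) and `ecdf` in (0, 1].
#' @export
cumulative_distribution <- function(values) {
  check_that(length(values) > 0, "empty input")
  v <- sort(values)
  data.frame(value = v, ecdf = seq_along(v) / length(v))
}

#' Benjamini-Hochberg adjustment of a comparison table
#'
#' Optional multiple-testing correction (the per-window tests are reported
#' unadjusted by default).
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p_values) stats::p.adjust(p_values, method = "BH")
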