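#' Bootstrap configuration for group contrasts
#'
#' Each iteration resamples 75% of each group and computes the contrast of
#' subsample means. The default draws with replacement (classical
#' bootstrap at 75% subsample size); `replace = FALSE` gives the literal
#' without-replacement reading, whose confidence intervals understate the
#' sampling variability (finite-population shrinkage) and make the
#' significance rule anti-conservative -- see the methods vignette. The point estimate is the mean over
#' iterations, the confidence interval the percentile interval, and the
#' noise band the point estimate +/- 3 SD of the resampled contrasts.
#'
#' @param subsample_frac fraction drawn per group per iteration (default 0.75).
#' @param n_iter number of iterations (default 1000, minimum 100).
#' @param mode `"ratio"` (mean_b / mean_a) or `"difference"` (mean_b - mean_a).
#' @param ci_level confidence level (default 0.95).
#' @param replace logical; with-replacement resampling (default TRUE).
#'   `FALSE` selects literal 75% subsampling without replacement.
#' @param seed RNG seed.
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(subsample_frac = 0.75, n_iter = 1000,
                             mode = c("ratio", "difference"), ci_level = 0.95,
                             replace = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  check_that(subsample_frac > 0 && subsample_frac <= 1,
             "subsample_frac must be in (0, 1], got %g", subsample_frac)
  check_that(n_iter >= 100, "n_iter must be >= 100, got %d", n_iter)
  check_that(ci_level > 0 && ci_level < 1, "ci_level must be in (0, 1)")
  structure(as.list(environment()), class = "bootstrap_config")
}

#' Bootstrap a group contrast (ratio or difference of means)
#'
#' The contrast is group_b relative to group_a (e.g. lesion relative to
#' sham): `mean(b*) / mean(a*)` in ratio mode, `mean(b*) - mean(a*)` in
#' difference mode, where `a*`, `b*` are independent 75% subsamples. The
#' contrast is flagged significant when the null value (1 for ratio, 0 for
#' difference) falls outside the percentile confidence interval. Ratio
#' iterations with a zero denominator are redrawn; more than 10% redraws is
#' an error.
#'
#' @param group_a,group_b numeric vectors (reference and comparison group).
#' @param cfg a [bootstrap_config()].
#' @return list of class `bootstrap_result`: `point_estimate`, `sd`,
#'   `ci_low`, `ci_high`, `band_3sd_low`, `band_3sd_high`, `significant`,
#'   `n_rejected`, `mode`.
#' @export
bootstrap_contrast <- function(group_a, group_b, cfg = bootstrap_config()) {
  check_that(length(group_a) >= 1 && length(group_b) >= 1, "both groups must be non-empty")
  na <- max(1L, floor(length(group_a) * cfg$subsample_frac))
  nb <- max(1L, floor(length(group_b) * cfg$subsample_frac))
  with_seed(cfg$seed, {
    stat <- numeric(cfg$n_iter)
    n_rej <- 0L
    max_rej <- ceiling(0.1 * cfg$n_iter)
    i <- 1L
    while (i <= cfg$n_iter) {
      ma <- mean(group_a[sample.int(length(group_a), na, replace = cfg$replace)])
      mb <- mean(group_b[sample.int(length(group_b), nb, replace = cfg$replace)])
      if (cfg$mode == "ratio") {
        if (ma == 0) {
          n_rej <- n_rej + 1L
          if (n_rej > max_rej) {
            stopf("more than 10%% of ratio iterations had zero denominator")
          }
          next
        }
        stat[i] <- mb / ma
      } else {
        stat[i] <- mb - ma
      }
      i <- i + 1L
    }
    alpha <- (1 - cfg$ci_level) / 2
    ci <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE)
    pe <- mean(stat)
    s <- stats::sd(stat)
    null_value <- if (cfg$mode == "ratio") 1 else 0
    structure(list(
      point_estimate = pe, sd = s, ci_low = ci[1], ci_high = ci[2],
      band_3sd_low = pe - 3 * s, band_3sd_high = pe + 3 * s,
      significant = null_value < ci[1] || null_value > ci[2],
      n_rejected = n_rej, mode = cfg$mode
    ), class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap %s> %.4g [95%% CI %.4g, %.4g], SD %.3g%s\n",
              x$mode, x$point_estimate, x$ci_low, x$ci_high, x$sd,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Relative-change curve across time windows
#'
#' Ratio-mode bootstrap of lesion vs sham per time window, with a prepended
#' artificial reference point at 1 (the pre-lesion anchor of the curve).
#' Windows with an empty group yield a missing point.
#'
#' @param windowed named list; each element a list with `sham` and `lesion`
#'   numeric vectors, names are the time windows in order.
#' @param cfg a [bootstrap_config()] (mode forced to `"ratio"`).
#' @return data.frame: `window`, `estimate`, `sd`, `ci_low`, `ci_high`,
#'   `band_3sd_low`, `band_3sd_high`, `significant`; first row is the
#'   reference point.
#' @export
relative_change_curve <- function(windowed, cfg = bootstrap_config()) {
  cfg$mode <- "ratio"
  rows <- lapply(seq_along(windowed), function(i) {
    w <- windowed[[i]]
    wname <- names(windowed)[i]
    wcfg <- cfg
    if (!is.null(cfg$seed)) wcfg$seed <- cfg$seed + i
    if (length(w$sham) == 0 || length(w$lesion) == 0) {
      return(data.frame(window = wname, estimate = NA_real_, sd = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        band_3sd_low = NA_real_, band_3sd_high = NA_real_,
                        significant = NA))
    }
    r <- bootstrap_contrast(w$sham, w$lesion, wcfg)
    data.frame(window = wname, estimate = r$point_estimate, sd = r$sd,
               ci_low = r$ci_low, ci_high = r$ci_high,
               band_3sd_low = r$band_3sd_low, band_3sd_high = r$band_3sd_high,
               significant = r$significant)
  })
  ref <- data.frame(window = "reference", estimate = 1, sd = 0,
                    ci_low = 1, ci_high = 1, band_3sd_low = 1,
                    band_3sd_high = 1, significant = FALSE)
  out <- rbind(ref, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Excitation-inhibition trajectory across time windows
#'
#' Pairs per-window excitatory and inhibitory group contrasts (lesion vs
#' sham) into an ordered trajectory: one point per window with the E
#' contrast on the x axis and the I contrast on the y axis.
#'
#' @param e_results,i_results named lists of [bootstrap_contrast()] results,
#'   one per time window; names must match between the two.
#' @param cell_type optional label attached to every point.
#' @return data.frame: `window`, `delta_e`, `delta_i`, `e_significant`,
#'   `i_significant`, `cell_type`.
#' @export
ei_trajectory <- function(e_results, i_results, cell_type = NA_character_) {
  check_that(identical(names(e_results), names(i_results)),
             "E and I windows do not match")
  check_that(length(e_results) > 0, "no windows supplied")
  out <- do.call(rbind, lapply(names(e_results), function(w) {
    data.frame(window = w,
               delta_e = e_results[[w]]$point_estimate,
               delta_i = i_results[[w]]$point_estimate,
               e_significant = e_results[[w]]$significant,
               i_significant = i_results[[w]]$significant,
               cell_type = cell_type)
  }))
  rownames(out) <- NULL
  out
}
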