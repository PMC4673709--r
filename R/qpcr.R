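#' Amplification efficiency from a dilution series
#'
#' Fits the least-squares slope `b` of Ct on log10 relative concentration
#' and converts it to the per-cycle amplification efficiency
#' \eqn{E = 10^{-1/b} - 1}. Perfect doubling chemistry gives the textbook
#' slope of -3.3219 and E = 1.
#'
#' @param series tibble with columns log10_conc and ct (>= 3 points).
#' @return the efficiency E, a single number. Values above 1 (super-perfect
#'   chemistry, possible with noisy series) are clipped to 1.1 with a
#'   warning.
#' @examples
#' s <- tibble::tibble(log10_conc = c(0, -1, -2, -3),
#'                     ct = 20 + 3.3219 * c(0, 1, 2, 3))
#' efficiency_from_dilution(s) # 1
#' @export
efficiency_from_dilution <- function(series) {
  assert_columns(series, c("log10_conc", "ct"))
  if (nrow(series) < 3) abort("a dilution series needs at least 3 points")
  b <- unname(coef(lm(ct ~ log10_conc, data = series))[2])
  if (!is.finite(b) || b >= 0 || abs(b) < 0.1) {
    abort(sprintf(
      "dilution-series calibration failed: slope %.4f (expected a negative slope near -3.3)",
      b))
  }
  e <- 10^(-1 / b) - 1
  if (e > 1 + 1e-6) {
    warn(sprintf("efficiency %.3f > 1 from dilution slope %.3f; clipped to 1.1 max", e, b))
    e <- min(e, 1.1)
  }
  if (e <= 0) abort("dilution series implies non-positive efficiency")
  e
}

ct_group_means <- function(cts) {
  assert_columns(cts, c("group", "ct"), "cts")
  groups <- c("RR", "RT", "TR", "TT")
  cts <- cts |> mutate(group = sub("'", "", .data$group))
  if (!all(groups %in% cts$group)) {
    abort("Ct table must contain all four groups RR, RT, TR, TT")
  }
  if (any(!is.finite(cts$ct) | cts$ct <= 0)) {
    abort("Ct values must be finite and positive")
  }
  vapply(groups, function(g) mean(cts$ct[cts$group == g]), numeric(1))
}

#' Copy-number ratio from a qPCR run (efficiency-corrected delta-delta-Ct)
#'
#' Group means of the four Ct groups are substituted into
#' \eqn{\Delta\Delta Ct = (\overline{TT'} - \overline{TR'}) -
#' (\overline{RT'} - \overline{RR'})} and the mean copy-number ratio of the
#' test locus is \eqn{(1 + E)^{-\Delta\Delta Ct}}. The single efficiency
#' `E` is the plate's reference-dilution calibration.
#'
#' @param cts tibble with columns group (`RR`, `RT`, `TR`, `TT`; a
#'   trailing `'` is tolerated) and ct; at least one replicate per group.
#' @param efficiency amplification efficiency E in (0, 1].
#' @return the copy-number ratio, a single positive number.
#' @examples
#' run <- simulate_qpcr(1.41, 0.9, 0.9, 3, ct_sd = 0)
#' copy_ratio(run, efficiency = 0.9) # 1.41
#' @export
copy_ratio <- function(cts, efficiency) {
  assert_scalar_number(efficiency, "efficiency", lower = 1e-6, upper = 1.1)
  m <- ct_group_means(cts)
  ddct <- (m[["TT"]] - m[["TR"]]) - (m[["RT"]] - m[["RR"]])
  (1 + efficiency)^(-ddct)
}

#' Copy-number estimate with percentile bootstrap confidence interval
#'
#' Resamples, with replacement and preserving group size, the individual Ct
#' values within each of the four groups independently; the copy-number
#' ratio is recomputed for each of `iterations` bootstrap replicates and
#' the confidence bounds are the 2.5% and 97.5% quantiles of the sorted
#' bootstrap ratios (percentile method).
#'
#' @inheritParams copy_ratio
#' @param iterations bootstrap iterations (10,000 typical).
#' @param seed integer seed; fixed seed gives an identical interval.
#' @param conf_level confidence level for the percentile interval.
#' @return an object of class `copy_estimate` with fields estimate,
#'   conf_low, conf_high, efficiency, iterations, conf_level, seed and
#'   n_replicates. Use [tidy()] / [glance()] for tibble views.
#' @export
qpcr_estimate <- function(cts, efficiency, iterations = 10000, seed = NULL,
                          conf_level = 0.95) {
  assert_scalar_number(iterations, "iterations", lower = 1)
  if (iterations < 100) {
    warn("fewer than 100 bootstrap iterations give unstable quantiles")
  }
  m <- ct_group_means(cts)   # validates groups
  cts <- cts |> mutate(group = sub("'", "", .data$group))
  by_group <- split(cts$ct, cts$group)[c("RR", "RT", "TR", "TT")]
  sizes <- lengths(by_group)
  if (any(sizes < 2)) {
    abort("bootstrap needs at least 2 replicates in every Ct group")
  }

  point <- copy_ratio(cts, efficiency)
  boot_means <- with_seed_or_not(seed, {
    map(by_group, function(v) {
      n <- length(v)
      idx <- matrix(sample.int(n, n * iterations, replace = TRUE),
                    nrow = iterations)
      rowMeans(matrix(v[idx], nrow = iterations))
    })
  })
  ddct <- (boot_means$TT - boot_means$TR) - (boot_means$RT - boot_means$RR)
  ratios <- (1 + efficiency)^(-ddct)
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(ratios, c(alpha, 1 - alpha)))

  structure(
    list(estimate = point, conf_low = ci[1], conf_high = ci[2],
         efficiency = efficiency, iterations = as.integer(iterations),
         conf_level = conf_level, seed = seed,
         n_replicates = as.integer(sizes)),
    class = "copy_estimate"
  )
}

#' @export
print.copy_estimate <- function(x, ...) {
  cat(sprintf(
    "<copy_estimate> ratio %.3f  [%.3f, %.3f] %g%% percentile bootstrap (%d iterations, E = %.2f)\n",
    x$estimate, x$conf_low, x$conf_high, 100 * x$conf_level, x$iterations,
    x$efficiency))
  invisible(x)
}

#' Tidy a bootstrap copy-number estimate
#'
#' @param x a `copy_estimate` from [qpcr_estimate()].
#' @param ... unused.
#' @return a one-row tibble with estimate, conf.low, conf.high.
#' @export
tidy.copy_estimate <- function(x, ...) {
  tibble(estimate = x$estimate, conf.low = x$conf_low,
         conf.high = x$conf_high)
}

#' @rdname tidy.copy_estimate
#' @return `glance()`: a one-row tibble with the estimation settings.
#' @export
glance.copy_estimate <- function(x, ...) {
  tibble(efficiency = x$efficiency, iterations = x$iterations,
         conf.level = x$conf_level,
         min.replicates = min(x$n_replicates))
}
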