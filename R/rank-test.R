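#' Wilcoxon two-sample rank-sum test (normal approximation)
#'
#' The rank-sum statistic with midranks for ties, the tie-corrected normal
#' approximation, and an optional continuity correction — the form in which
#' CNV span distributions of adapting populations are compared against
#' spontaneous mutation-accumulation spans. The signed Z statistic refers
#' to the first sample: Z < 0 means the first sample tends to rank lower.
#'
#' With `W` the rank-sum of the first sample of size \eqn{n_a} in a pooled
#' sample of size \eqn{n}, \eqn{E[W] = n_a(n+1)/2} and
#' \eqn{Var[W] = \frac{n_a n_b}{12}\left(n + 1 - \frac{\sum (t^3 - t)}{n(n-1)}\right)}
#' with `t` the tie-group sizes.
#'
#' @param a,b numeric samples (non-empty).
#' @param continuity apply the 0.5 continuity correction.
#' @return an object of class `rank_test`; see [tidy.rank_test()].
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(a, b, continuity = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) abort("samples must not contain NA")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    abort("all values identical across both samples: rank variance is zero")
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(pooled)          # midranks
  w <- sum(r[seq_len(na)])
  ew <- na * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  vw <- na * nb / 12 * (n + 1 - tie_term)
  cc <- if (continuity) sign(w - ew) * 0.5 else 0
  z <- (w - ew - cc) / sqrt(vw)
  # one-sided p is the lower tail P(W <= w): small when the first sample
  # ranks low (continuity correction applied toward the tail)
  p_lower <- pnorm((w - ew + if (continuity) 0.5 else 0) / sqrt(vw))
  structure(
    list(statistic = z, p_two_sided = z_pvalue(z), p_one_sided = p_lower,
         rank_sum = w, expected_rank_sum = ew, variance = vw,
         n_a = na, n_b = nb, ties_corrected = tie_term > 0,
         continuity = continuity),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum (normal approximation%s)\nZ = %.4f, two-sided p = %.4g, one-sided p = %.4g (W = %g, n = %d + %d%s)\n",
    if (x$continuity) ", continuity-corrected" else "",
    x$statistic, x$p_two_sided, x$p_one_sided, x$rank_sum, x$n_a, x$n_b,
    if (x$ties_corrected) ", tie-corrected variance" else ""))
  invisible(x)
}

#' Tidy a rank-sum test result
#'
#' @param x a `rank_test` from [wilcoxon_rank_sum()].
#' @param ... unused.
#' @return one-row tibble: statistic (Z), p.value (two-sided),
#'   p.value.one.sided, rank.sum.
#' @export
tidy.rank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_two_sided,
         p.value.one.sided = x$p_one_sided, rank.sum = x$rank_sum)
}

#' @rdname tidy.rank_test
#' @return `glance()`: sample sizes and correction settings.
#' @export
glance.rank_test <- function(x, ...) {
  tibble(n.a = x$n_a, n.b = x$n_b, ties.corrected = x$ties_corrected,
         continuity = x$continuity)
}

#' Pearson product-moment correlation
#'
#' Standard correlation with the input validation the CNV method
#' comparisons need (paired copy-number estimates from different assays).
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance; pairs with missing values are dropped.
#' @return the correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(1:5, 2 * (1:5) + 3) # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in `x` or `y`")
  cor(x, y)
}
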