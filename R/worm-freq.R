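#' CNV frequency from single-worm PCR presence/absence counts
#'
#' Estimates the per-haploid rearrangement frequency from the fraction of
#' sampled adult males testing positive for a rearrangement-specific PCR
#' product. X-linked loci: males are hemizygous, so
#' \eqn{\hat{q} = k/n} directly. Autosomal loci under Hardy-Weinberg
#' equilibrium: non-carriers are homozygous for absence, so
#' \eqn{\hat{q} = 1 - \sqrt{1 - k/n}}. The average copy-number per haploid
#' genome follows as \eqn{\hat{c} = 1 + \hat{q}} for duplications and
#' \eqn{1 - \hat{q}} for deletions. An exact (Clopper-Pearson) binomial
#' confidence interval on the carrier fraction is mapped through the same
#' transform.
#'
#' @param counts tibble with columns n_sampled, n_positive,
#'   chromosome_class (`"autosome"`/`"X"`) and cnv_type
#'   (`"duplication"`/`"deletion"`); extra columns (population,
#'   generation, ...) pass through.
#' @param conf_level confidence level for the binomial interval; 0 gives a
#'   degenerate interval at the point estimate.
#' @param digits optional rounding of the estimates (the published tables
#'   print two decimals); `NULL` leaves full precision.
#' @return `counts` with added columns q_hat, copy_hat, q_low, q_high.
#' @examples
#' w <- tibble::tibble(n_sampled = 43, n_positive = 28,
#'                     chromosome_class = "autosome",
#'                     cnv_type = "duplication")
#' estimate_worm_frequency(w, digits = 2) # q_hat 0.41, copy_hat 1.41
#' @export
estimate_worm_frequency <- function(counts, conf_level = 0.95,
                                    digits = NULL) {
  assert_columns(counts, c("n_sampled", "n_positive", "chromosome_class",
                           "cnv_type"))
  if (any(counts$n_sampled <= 0)) abort("n_sampled must be positive")
  if (any(counts$n_positive < 0 | counts$n_positive > counts$n_sampled)) {
    abort("n_positive must lie in [0, n_sampled]")
  }
  if (!all(counts$chromosome_class %in% c("autosome", "X"))) {
    abort("chromosome_class must be 'autosome' or 'X'")
  }

  out <- counts |>
    mutate(
      .carrier = .data$n_positive / .data$n_sampled,
      q_hat = ifelse(.data$chromosome_class == "X", .data$.carrier,
                     1 - sqrt(1 - .data$.carrier)),
      copy_hat = ifelse(.data$cnv_type == "duplication", 1 + .data$q_hat,
                        1 - .data$q_hat)
    )
  ci <- pmap(list(out$n_positive, out$n_sampled, out$chromosome_class,
                  out$q_hat),
             function(k, n, cls, qh) {
               b <- carrier_ci(k, n, conf_level)
               if (cls == "autosome") b <- 1 - sqrt(1 - b)
               if (conf_level == 0) b <- c(qh, qh)
               b
             })
  out <- out |>
    mutate(q_low = map_dbl(ci, 1), q_high = map_dbl(ci, 2)) |>
    select(-".carrier")
  if (!is.null(digits)) {
    out <- out |> mutate(across(c("q_hat", "copy_hat"), ~ round(.x, digits)))
  }
  out
}

carrier_ci <- function(k, n, conf_level) {
  if (conf_level <= 0) return(c(k / n, k / n))
  as.numeric(binom.test(k, n, conf.level = conf_level)$conf.int)
}

#' Confidence interval for a single worm-count record
#'
#' Clopper-Pearson interval on the positive fraction, mapped through the
#' Hardy-Weinberg transform for autosomal loci (see
#' [estimate_worm_frequency()]).
#'
#' @param n_sampled,n_positive sample size and positives.
#' @param chromosome_class `"autosome"` or `"X"`.
#' @param level confidence level.
#' @return a length-2 numeric vector (low, high) on the frequency scale.
#' @export
frequency_ci <- function(n_sampled, n_positive,
                         chromosome_class = c("autosome", "X"),
                         level = 0.95) {
  chromosome_class <- match.arg(chromosome_class)
  assert_scalar_number(n_sampled, "n_sampled", lower = 1)
  assert_scalar_number(n_positive, "n_positive", lower = 0,
                       upper = n_sampled)
  b <- carrier_ci(n_positive, n_sampled, level)
  if (chromosome_class == "autosome") b <- 1 - sqrt(1 - b)
  if (level == 0) {
    q <- if (chromosome_class == "X") n_positive / n_sampled else
      1 - sqrt(1 - n_positive / n_sampled)
    b <- c(q, q)
  }
  b
}
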