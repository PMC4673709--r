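#' Simulate a pooled-DNA array-CGH probe profile
#'
#' Pooled hybridization observation model: a CNV segregating at per-haploid
#' frequency `q` shifts the population-average copy-number per haploid to
#' `1 + q * extra_copies` (duplication) or `1 - q` (deletion), and the
#' expected probe log2 ratio against a single-copy reference is `log2()` of
#' that average. Probes outside any CNV have expectation 0. Gaussian noise
#' of standard deviation `probe_sd` is added per probe. A fixed deletion
#' (`q = 1`) has zero expected intensity; its probes are assigned the finite
#' floor `del_floor`, mirroring the finite background intensities real
#' arrays report.
#'
#' @param genome a `genome_model` from [make_genome()].
#' @param cnvs tibble describing the population CNV configuration: columns
#'   chrom, start, end, type (`"duplication"`/`"deletion"`), frequency
#'   (in `[0,1]`, per haploid genome) and optionally extra_copies (extra
#'   copies per carrier haplotype, default 1). CNVs must not overlap.
#' @param probe_sd Gaussian probe noise standard deviation (log2 units).
#' @param del_floor log2 ratio assigned to probes of a fully deleted
#'   segment.
#' @param seed integer seed.
#' @return a probe-profile tibble: chrom, pos, log2ratio, plus the
#'   ground-truth expectation in column `expected`.
#' @examples
#' g <- make_genome(1, 50000, 500, 0)
#' cnv <- tibble::tibble(chrom = "I", start = 10000, end = 20000,
#'                       type = "duplication", frequency = 1)
#' prof <- simulate_acgh(g, cnv, probe_sd = 0)
#' @export
simulate_acgh <- function(genome, cnvs, probe_sd = 0.25, del_floor = -8,
                          seed = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  assert_scalar_number(probe_sd, "probe_sd", lower = 0)
  cnvs <- validate_cnv_config(cnvs)

  probes <- genome$probes
  expected <- rep(0, nrow(probes))
  for (i in seq_len(nrow(cnvs))) {
    inside <- probes$chrom == cnvs$chrom[i] &
      probes$pos >= cnvs$start[i] & probes$pos <= cnvs$end[i]
    q <- cnvs$frequency[i]
    if (cnvs$type[i] == "duplication") {
      expected[inside] <- log2(1 + q * cnvs$extra_copies[i])
    } else {
      expected[inside] <- if (q >= 1) del_floor else log2(1 - q)
    }
  }
  noise <- with_seed_or_not(seed, rnorm(nrow(probes), 0, probe_sd))
  probes |>
    mutate(log2ratio = expected + noise, expected = expected)
}

validate_cnv_config <- function(cnvs) {
  assert_columns(cnvs, c("chrom", "start", "end", "type", "frequency"),
                 "cnvs")
  if (!"extra_copies" %in% names(cnvs)) cnvs$extra_copies <- 1
  if (any(cnvs$start > cnvs$end)) abort("CNV intervals must have start <= end")
  if (any(cnvs$frequency < 0 | cnvs$frequency > 1)) {
    abort("CNV frequencies must lie in [0, 1]")
  }
  if (!all(cnvs$type %in% c("duplication", "deletion"))) {
    abort("CNV type must be 'duplication' or 'deletion'")
  }
  # CNVs within one population configuration must not overlap: the real
  # populations never carry two different CNVs over one interval.
  by_chrom <- split(cnvs, cnvs$chrom)
  for (cc in by_chrom) {
    if (nrow(cc) > 1) {
      cc <- cc[order(cc$start), ]
      if (any(cc$start[-1] <= cc$end[-nrow(cc)])) {
        abort("CNVs in one configuration must not overlap")
      }
    }
  }
  cnvs
}

#' Simulate a qPCR run under the delta-delta-Ct model
#'
#' Inverse of the quantification in [copy_ratio()]: generates the four
#' groups of unpaired technical replicates (RR' reference DNA/reference
#' primers, RT' reference DNA/test primers, TR' test DNA/reference primers,
#' TT' test DNA/test primers) such that the expected
#' \eqn{\Delta\Delta Ct = -\log_{1+E}(\mathrm{true\_ratio})}, then adds
#' Gaussian replicate noise of sd `ct_sd`.
#'
#' @param true_ratio true copy-number ratio of the test locus (> 0).
#' @param efficiency_ref,efficiency_test amplification efficiencies in
#'   (0, 1]; the test-primer efficiency shapes the generated TT' Cts.
#' @param n_replicates technical replicates per group (3 typical).
#' @param ct_sd Gaussian Ct noise standard deviation.
#' @param seed integer seed.
#' @param base_ct baseline cycle threshold for the reference groups.
#' @return tibble with columns group (`RR`, `RT`, `TR`, `TT`), replicate
#'   and ct.
#' @examples
#' run <- simulate_qpcr(2, 1, 1, 3, ct_sd = 0)
#' copy_ratio(run, efficiency = 1) # 2
#' @export
simulate_qpcr <- function(true_ratio, efficiency_ref = 1, efficiency_test = 1,
                          n_replicates = 3, ct_sd = 0.15, seed = NULL,
                          base_ct = 25) {
  if (!is.numeric(true_ratio) || length(true_ratio) != 1 || true_ratio <= 0) {
    abort("`true_ratio` must be a single positive number")
  }
  assert_scalar_number(efficiency_ref, "efficiency_ref", lower = 1e-6, upper = 1)
  assert_scalar_number(efficiency_test, "efficiency_test", lower = 1e-6, upper = 1)
  assert_scalar_number(n_replicates, "n_replicates", lower = 2)
  assert_scalar_number(ct_sd, "ct_sd", lower = 0)

  shift <- log(true_ratio, base = 1 + efficiency_test)
  means <- c(RR = base_ct, RT = base_ct + 2, TR = base_ct,
             TT = base_ct + 2 - shift)
  groups <- rep(names(means), each = n_replicates)
  cts <- with_seed_or_not(seed, {
    rep(unname(means), each = n_replicates) +
      rnorm(4 * n_replicates, 0, ct_sd)
  })
  tibble(group = groups,
         replicate = rep(seq_len(n_replicates), times = 4),
         ct = cts)
}

#' Simulate a single-worm PCR sample
#'
#' Draws the number of adult males testing positive for a rearrangement in
#' a population at per-haploid CNV frequency `q` under Hardy-Weinberg
#' equilibrium. Autosomal loci: a male carries the rearrangement with
#' probability \eqn{1 - (1-q)^2} (heterozygous or homozygous carrier).
#' X-linked loci: males are hemizygous, so the positive probability is `q`
#' directly.
#'
#' @param q per-haploid CNV frequency in `[0,1]`.
#' @param n number of males sampled.
#' @param chromosome_class `"autosome"` or `"X"`.
#' @param cnv_type `"duplication"` or `"deletion"` (carried through to the
#'   output record).
#' @param seed integer seed.
#' @param population,generation optional labels carried into the record.
#' @return one-row tibble: population, generation, n_sampled, n_positive,
#'   chromosome_class, cnv_type.
#' @export
simulate_worm_sample <- function(q, n, chromosome_class = c("autosome", "X"),
                                 cnv_type = c("duplication", "deletion"),
                                 seed = NULL, population = NA_character_,
                                 generation = NA_integer_) {
  assert_scalar_number(q, "q", lower = 0, upper = 1)
  assert_scalar_number(n, "n", lower = 1)
  chromosome_class <- match.arg(chromosome_class)
  cnv_type <- match.arg(cnv_type)
  p_pos <- if (chromosome_class == "X") q else 1 - (1 - q)^2
  k <- with_seed_or_not(seed, rbinom(1, as.integer(n), p_pos))
  tibble(population = population, generation = generation,
         n_sampled = as.integer(n), n_positive = k,
         chromosome_class = chromosome_class, cnv_type = cnv_type)
}
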