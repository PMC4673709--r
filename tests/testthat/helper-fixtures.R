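# Small builders used by several test files.

step_profile <- function(n_low = 20, n_high = 20, low = 0, high = 1,
                         chrom = "I") {
  tibble::tibble(chrom = chrom, pos = seq_len(n_low + n_high),
                 log2ratio = c(rep(low, n_low), rep(high, n_high)))
}

ct_run_from_means <- function(rr, rt, tr, tt, reps = 3) {
  tibble::tibble(group = rep(c("RR", "RT", "TR", "TT"), each = reps),
                 ct = rep(c(rr, rt, tr, tt), each = reps))
}

dup_genome <- function(chrom_length = 200000, spacing = 1000) {
  make_genome(1, chrom_length, spacing, 0)
}

dup_config <- function(q, start = 50001, end = 100000,
                       type = "duplication") {
  tibble::tibble(chrom = "I", start = start, end = end, type = type,
                 frequency = q)
}
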