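# Independent oracles used across the suite. These deliberately use naive
# enumeration / simulation, not the package's own code paths.

# Exact permutation distribution of the first-sample rank-sum.
perm_ranksum_pvalues <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  w_obs <- sum(r[seq_len(na)])
  lower <- mean(ws <= w_obs)
  upper <- mean(ws >= w_obs)
  list(w = w_obs, lower = lower, upper = upper,
       two_sided = min(1, 2 * min(lower, upper)))
}

# Brute-force maximal sets of intervals with non-empty common intersection:
# enumerate every subset, keep those whose max(start) <= min(end), then
# keep the maximal ones under set inclusion.
brute_interval_cliques <- function(start, end) {
  n <- length(start)
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  valid <- Filter(function(s) max(start[s]) <= min(end[s]), subsets)
  maximal <- Filter(function(s) {
    !any(vapply(valid, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, logical(1)))
  }, valid)
  unique(lapply(maximal, sort))
}

# Gene-dropping Monte-Carlo for the full-sib inbreeding coefficient.
# Generation-0 parents are themselves full sibs bred from unrelated,
# non-inbred grandparents (4 distinct allele labels), so that the first
# sib-mating offspring (generation 1) have F = 1/4; thereafter sibs mate
# every generation. F_t is the probability that an individual of
# generation t carries two identical-by-descent alleles.
gene_drop_fullsib <- function(t_max, n_reps) {
  ibd <- matrix(FALSE, nrow = n_reps, ncol = t_max)
  for (r in seq_len(n_reps)) {
    gm <- c(1L, 2L); gf <- c(3L, 4L)
    mother <- c(sample(gm, 1), sample(gf, 1))
    father <- c(sample(gm, 1), sample(gf, 1))
    for (t in seq_len(t_max)) {
      child1 <- c(sample(mother, 1), sample(father, 1))
      child2 <- c(sample(mother, 1), sample(father, 1))
      ibd[r, t] <- child1[1] == child1[2]
      mother <- child1; father <- child2
    }
  }
  colMeans(ibd)
}

# Shared synthetic breakpoint-repeat scenario: two aligned repeats
# differing at fixed informative sites, plus chimeras switching in chosen
# gaps.
make_repeat_pair <- function(len = 120, sites = c(10, 50, 90)) {
  up <- rep("A", len); down <- rep("A", len)
  up[sites] <- "G"; down[sites] <- "T"
  list(upstream = paste(up, collapse = ""),
       downstream = paste(down, collapse = ""),
       sites = sites)
}

make_chimera <- function(pair, n_downstream) {
  len <- nchar(pair$upstream)
  x <- strsplit(pair$upstream, "")[[1]]
  take <- pair$sites[seq_len(n_downstream)]
  x[take] <- strsplit(pair$downstream, "")[[1]][take]
  paste(x, collapse = "")
}
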