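test_that("quantile normalization matches hand-computed order statistics", {
  p <- tibble::tibble(profile = rep(c("a", "b"), each = 3), chrom = "I",
                      pos = rep(1:3, 2), log2ratio = c(1, 2, 3, 2, 4, 6))
  out <- quantile_normalize(p)
  expect_equal(out$log2ratio[out$profile == "a"], c(1.5, 3, 4.5))
  expect_equal(out$log2ratio[out$profile == "b"], c(1.5, 3, 4.5))

  # single profile is the identity
  one <- tibble::tibble(profile = "a", chrom = "I", pos = 1:5,
                        log2ratio = c(0.3, -1, 2, 0, 0.7))
  expect_equal(quantile_normalize(one)$log2ratio, one$log2ratio)

  # permuted profiles end up with identical value multisets
  set.seed(41)
  x <- rnorm(30)
  perm <- tibble::tibble(profile = rep(c("a", "b"), each = 30), chrom = "I",
                         pos = rep(1:30, 2),
                         log2ratio = c(x, sample(x)))
  res <- quantile_normalize(perm)
  expect_equal(sort(res$log2ratio[res$profile == "a"]),
               sort(res$log2ratio[res$profile == "b"]))

  bad <- tibble::tibble(profile = c("a", "a", "b"), chrom = "I",
                        pos = c(1, 2, 1), log2ratio = 0)
  expect_error(quantile_normalize(bad), "probe set")
})

test_that("constant profiles collapse to one segment", {
  for (n in c(2, 7, 40)) {
    prof <- tibble::tibble(chrom = "I", pos = seq_len(n), log2ratio = 0.3)
    segs <- segment_profile(prof)
    expect_equal(nrow(segs), 1)
    expect_equal(segs$n_probes, n)
  }
})

test_that("a noiseless step is segmented exactly at the breakpoint", {
  segs <- segment_profile(step_profile(20, 20), p_merge = 0.01)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end_index[1], 20)
  expect_equal(segs$start_index[2], 21)
  expect_equal(segs$mean, c(0, 1))
  # this split also maximizes the between-segment t statistic over all
  # 2-segment partitions of the step
  x <- c(rep(0, 20), rep(1, 20))
  tstats <- vapply(2:39, function(k) {
    abs(mean(x[1:(k - 1)]) - mean(x[k:40])) /
      sqrt(var(x[1:(k - 1)]) / (k - 1) + var(x[k:40]) / (40 - k + 1) + 1e-12)
  }, numeric(1))
  expect_equal(which.max(tstats) + 1L, 21L)
})

test_that("segments partition every chromosome in order", {
  set.seed(7)
  prof <- tibble::tibble(
    chrom = rep(c("I", "II"), each = 60),
    pos = rep(seq(1000, 60000, by = 1000), 2),
    log2ratio = rnorm(120, rep(c(0, 0.8, 0, 0), each = 30), 0.2))
  segs <- segment_profile(prof, p_merge = 1e-3)
  for (cc in c("I", "II")) {
    s <- segs[segs$chrom == cc, ]
    covered <- unlist(Map(seq, s$start_index, s$end_index))
    expect_equal(covered, 1:60)   # each probe exactly once, in order
  }
})

test_that("stopping condition verified against brute-force adjacent t-tests", {
  p_merge <- 0.05
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    x <- rnorm(n, mean = sample(c(0, 0, 1), n, replace = TRUE), sd = 0.3)
    prof <- tibble::tibble(chrom = "I", pos = seq_len(n), log2ratio = x)
    segs <- segment_profile(prof, p_merge = p_merge)
    if (nrow(segs) > 1) {
      for (i in seq_len(nrow(segs) - 1)) {
        a <- x[segs$start_index[i]:segs$end_index[i]]
        b <- x[segs$start_index[i + 1]:segs$end_index[i + 1]]
        # independent computation of the adjacent-pair similarity: Welch
        # for stably-sized segments, robust-sd z below 4 probes
        p <- if (length(a) >= 4 && length(b) >= 4 &&
                   (var(a) > 0 || var(b) > 0)) {
          stats::t.test(a, b)$p.value
        } else {
          sd0 <- 1.4826 * median(abs(diff(x))) / sqrt(2)
          z <- (mean(a) - mean(b)) /
            (sd0 * sqrt(1 / length(a) + 1 / length(b)))
          2 * pnorm(-abs(z))
        }
        expect_lt(p, p_merge)
      }
    }
  }
})

test_that("segment count is monotone in the merge threshold", {
  set.seed(23)
  prof <- tibble::tibble(chrom = "I", pos = 1:80,
                         log2ratio = rnorm(80, rep(c(0, 1), each = 40), 0.3))
  thresholds <- c(1e-8, 1e-5, 1e-3, 1e-2, 0.1, 0.5)
  counts <- vapply(thresholds,
                   function(p) nrow(segment_profile(prof, p_merge = p)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("classification applies mean, p-value and size filters", {
  segs <- tibble::tibble(chrom = "I", segment = 1:4,
                         start_index = 1L, end_index = 1L,
                         start_pos = 1L, end_pos = 1L,
                         n_probes = c(50L, 50L, 2L, 50L),
                         mean = c(0, 1.0, 1.0, -1.0),
                         variance = c(0.04, 0.04, 0.04, 0.04))
  out <- classify_segments(segs, m_min = 0.2, p_class = 1e-3, min_probes = 3)
  expect_equal(out$label, c("neutral", "amplified", "neutral", "deleted"))
  # 50 probes at mean 1, sd 0.2: t is ~35, far below the p threshold
  expect_lt(out$p_value[2], 1e-3)
})

test_that("calls carry inner/outer intervals and frequency from 2^mean", {
  g <- dup_genome()
  prof <- simulate_acgh(g, dup_config(1), probe_sd = 0)
  calls <- call_cnvs(prof, chrom_lengths = c(I = 200000))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 51000)       # first internal probe
  expect_equal(calls$end, 100000)        # last internal probe
  expect_equal(calls$outer_start, 50001) # just inside the flanking probe
  expect_equal(calls$outer_end, 100999)
  expect_equal(calls$copy_number, 2)
  expect_equal(calls$frequency, 1)

  # copy-number arithmetic: amplified mean 0.496 -> c ~ 1.41, q ~ 0.41
  segs <- tibble::tibble(chrom = "I", segment = 1L, start_index = 2L,
                         end_index = 4L, start_pos = 2000L, end_pos = 4000L,
                         n_probes = 3L, mean = log2(1.41), variance = 1e-4,
                         label = "amplified")
  fake_prof <- tibble::tibble(chrom = "I", pos = c(1000, 2000, 3000, 4000, 5000),
                              log2ratio = 0)
  cc <- cgh_calls(segs, fake_prof)
  expect_equal(cc$copy_number, 1.41, tolerance = 1e-12)
  expect_equal(cc$frequency, 0.41, tolerance = 1e-12)

  # deleted mean -4 -> c = 0.0625, q ~ 0.94
  segs$mean <- -4; segs$label <- "deleted"
  cc2 <- cgh_calls(segs, fake_prof)
  expect_equal(cc2$copy_number, 0.0625)
  expect_equal(cc2$frequency, 0.9375)
})

test_that("simulated duplications are recovered with accurate breakpoints", {
  g <- dup_genome()
  hits <- 0L
  for (i in 1:40) {
    prof <- simulate_acgh(g, dup_config(1), probe_sd = 0.2, seed = 100 + i)
    calls <- call_cnvs(prof)
    dup <- calls[calls$type == "duplication" & calls$start <= 75000 &
                   calls$end >= 75000, ]
    if (nrow(dup) == 1 && abs(dup$start - 51000) <= 1000 &&
          abs(dup$end - 100000) <= 1000) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 38L)   # >= 95% of seeded runs
})
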