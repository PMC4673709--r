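test_that("probe grid is arithmetic and deterministic", {
  g <- make_genome(1, 100000, 1000, 0, seed = 1)
  expect_equal(nrow(g$probes), 100)
  expect_equal(g$probes$pos, seq(1000, 100000, by = 1000))

  g3 <- make_genome(1, 10000, 3000, 0, seed = 5)
  expect_equal(g3$probes$pos, c(3000, 6000, 9000))

  a <- make_genome(2, 50000, 500, 20, seed = 7)
  b <- make_genome(2, 50000, 500, 20, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$features$start >= 1 & a$features$end <= 50000))
  expect_true(all(a$features$start <= a$features$end))

  expect_error(make_genome(1, -5, 100, 0), "chrom_length")
  expect_error(make_genome(1, 1000, 0, 0), "probe_spacing")
})

test_that("pooled-hybridization expectations follow log2(1 +/- q)", {
  g <- dup_genome()
  inside <- function(p) p$pos >= 50001 & p$pos <= 100000

  p1 <- simulate_acgh(g, dup_config(1), probe_sd = 0)
  expect_equal(unique(p1$log2ratio[inside(p1)]), 1.0)
  expect_equal(unique(p1$log2ratio[!inside(p1)]), 0)

  pdel <- simulate_acgh(g, dup_config(0.5, type = "deletion"), probe_sd = 0)
  expect_equal(unique(pdel$log2ratio[inside(pdel)]), -1.0)

  # average copy-number 1.41 scenario
  p41 <- simulate_acgh(g, dup_config(0.41), probe_sd = 0)
  expect_equal(unique(p41$log2ratio[inside(p41)]), log2(1.41),
               tolerance = 1e-12)

  # fixed deletion hits the configurable floor
  pfix <- simulate_acgh(g, dup_config(1, type = "deletion"), probe_sd = 0,
                        del_floor = -8)
  expect_equal(unique(pfix$log2ratio[inside(pfix)]), -8)

  # two extra copies per carrier haplotype
  cfg <- dup_config(0.5)
  cfg$extra_copies <- 2
  p2 <- simulate_acgh(g, cfg, probe_sd = 0)
  expect_equal(unique(p2$log2ratio[inside(p2)]), 1.0)
})

test_that("overlapping CNVs in one configuration are rejected", {
  g <- dup_genome()
  cfg <- dplyr::bind_rows(dup_config(0.5, 10000, 60000),
                          dup_config(0.5, 50000, 90000, type = "deletion"))
  expect_error(simulate_acgh(g, cfg), "overlap")
  expect_error(simulate_acgh(g, dup_config(1.5)), "frequenc")
})

test_that("acgh noise is seeded and mean-recovering", {
  g <- dup_genome()
  a <- simulate_acgh(g, dup_config(0.5), probe_sd = 0.25, seed = 11)
  b <- simulate_acgh(g, dup_config(0.5), probe_sd = 0.25, seed = 11)
  expect_identical(a, b)

  big <- make_genome(1, 2000000, 100, 0)
  p <- simulate_acgh(big, dup_config(0.5, 1, 2000000), probe_sd = 0.02,
                     seed = 3)
  expect_equal(mean(p$log2ratio), log2(1.5), tolerance = 1e-3)
})

test_that("simulated qPCR runs invert the delta-delta-Ct model", {
  r0 <- simulate_qpcr(1, 1, 1, 3, ct_sd = 0)
  expect_equal(copy_ratio(r0, 1), 1)

  r2 <- simulate_qpcr(2, 1, 1, 3, ct_sd = 0)
  m <- tapply(r2$ct, r2$group, mean)
  ddct <- (m[["TT"]] - m[["TR"]]) - (m[["RT"]] - m[["RR"]])
  expect_equal(unname(ddct), -1)

  # round trip at the catalog's 1.41 copy-number with E = 0.9
  r41 <- simulate_qpcr(1.41, 0.9, 0.9, 3, ct_sd = 0)
  expect_equal(copy_ratio(r41, 0.9), 1.41, tolerance = 1e-12)

  expect_error(simulate_qpcr(0, 1, 1, 3), "positive")
  expect_identical(simulate_qpcr(1.5, 0.9, 0.9, 3, ct_sd = 0.1, seed = 2),
                   simulate_qpcr(1.5, 0.9, 0.9, 3, ct_sd = 0.1, seed = 2))
})

test_that("worm sampling follows the hemizygous/Hardy-Weinberg carrier model", {
  expect_equal(simulate_worm_sample(0, 30, "autosome", seed = 1)$n_positive, 0L)
  expect_equal(simulate_worm_sample(1, 30, "autosome", seed = 1)$n_positive, 30L)

  big_auto <- simulate_worm_sample(0.41, 10000, "autosome", seed = 9)
  p_expect <- 1 - 0.59^2
  se <- sqrt(p_expect * (1 - p_expect) / 10000)
  expect_lt(abs(big_auto$n_positive / 10000 - p_expect), 4 * se)

  big_x <- simulate_worm_sample(0.41, 10000, "X", seed = 9)
  se_x <- sqrt(0.41 * 0.59 / 10000)
  expect_lt(abs(big_x$n_positive / 10000 - 0.41), 4 * se_x)
})

test_that("Wright-Fisher trajectories are seeded, absorbing and martingale", {
  t1 <- simulate_wright_fisher(50, 1, generations = 20, n_reps = 5, seed = 2)
  expect_true(all(t1$frequency == 1))

  a <- simulate_wright_fisher(30, 0.3, 15, 50, seed = 4)
  b <- simulate_wright_fisher(30, 0.3, 15, 50, seed = 4)
  expect_identical(a, b)

  # neutral martingale: mean frequency stays near p0 at every generation
  tr <- simulate_wright_fisher(50, 0.5, generations = 25, n_reps = 4000,
                               seed = 8)
  by_gen <- tapply(tr$frequency, tr$generation, mean)
  expect_true(all(abs(by_gen - 0.5) < 0.03))

  # neutral fixation probability equals p0
  fs <- wf_fixation_summary(20, 0.5, n_reps = 4000, seed = 10)
  expect_lt(abs(fs$fixation_fraction - 0.5), 4 * sqrt(0.25 / 4000))

  # recurrent gain keeps boundaries non-absorbing
  tm <- simulate_wright_fisher(50, 0, generations = 200, n_reps = 200,
                               s = 0, mu = 0.01, delta = 0, seed = 12)
  expect_gt(mean(tm$frequency[tm$generation == 200]), 0.5)
})
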