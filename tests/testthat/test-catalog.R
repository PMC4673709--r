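test_that("span arithmetic is 1-based inclusive", {
  expect_equal(cnv_span(tibble::tibble(start = 6837055, end = 6879497))$span,
               42443L)
  expect_equal(cnv_span(tibble::tibble(start = 14037517, end = 14039164))$span,
               1648L)
  expect_equal(cnv_span(tibble::tibble(start = 5, end = 5))$span, 1L)
  expect_error(cnv_span(tibble::tibble(start = 10, end = 9)), "start <= end")
})

test_that("every packaged catalog row satisfies span = end - start + 1", {
  fx <- load_cnv_fixtures()
  dup <- cnv_span(dplyr::rename(fx$duplications, span_printed = span))
  del <- cnv_span(dplyr::rename(fx$deletions, span_printed = span))
  expect_equal(dup$span, dup$span_printed)
  expect_equal(del$span, del$span_printed)
  expect_equal(nrow(dup) + nrow(del), 50)
})

test_that("feature annotation counts any >= 1 bp overlap by biotype", {
  feats <- tibble::tibble(
    chrom = c("I", "I", "I", "I", "II"),
    start = c(100, 300, 500, 900, 100),
    end = c(199, 399, 599, 1100, 199),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "tRNA", "protein_coding"),
    id = paste0("f", 1:5))

  none <- annotate_cnvs(tibble::tibble(chrom = "I", start = 700, end = 800),
                        feats)
  expect_true(all(none[c("protein_coding", "trna", "pirna", "ncrna",
                         "pseudogene", "transposon")] == 0))

  exact <- annotate_cnvs(tibble::tibble(chrom = "I", start = 100, end = 599),
                         feats)
  expect_equal(exact$protein_coding, 3L)

  # ending 1 bp inside a feature still counts it (partial overlap)
  partial <- annotate_cnvs(tibble::tibble(chrom = "I", start = 700, end = 900),
                           feats)
  expect_equal(partial$trna, 1L)

  g <- make_genome(1, 2000, 500, 0)
  g$features <- feats[feats$chrom == "I", ]
  expect_error(annotate_cnvs_genome(
    tibble::tibble(chrom = "III", start = 1, end = 10), g),
    "unknown chromosome")
})

test_that("frequency conversion clips to the paper's fixation convention", {
  calls <- tibble::tibble(type = c("duplication", "deletion", "duplication",
                                   "deletion"),
                          copy_number = c(2.19, 0.04, 1, 1))
  out <- frequency_from_copy(calls)
  expect_equal(out$frequency, c(1, 0.96, 0, 0))

  # identity on q through c = 1 +/- q
  q <- seq(0, 1, by = 0.05)
  dup <- frequency_from_copy(tibble::tibble(type = "duplication",
                                            copy_number = 1 + q))
  del <- frequency_from_copy(tibble::tibble(type = "deletion",
                                            copy_number = 1 - q))
  expect_equal(dup$frequency, q)
  expect_equal(del$frequency, q)
  expect_error(frequency_from_copy(tibble::tibble(type = "deletion",
                                                  copy_number = -0.1)),
               ">= 0")
})

test_that("catalog summaries agree with a sort-based oracle and permutation", {
  fx <- load_cnv_fixtures()
  dels <- fx$deletions
  s <- summarize_cnvs(dels)
  spans <- sort(dels$end - dels$start + 1)
  expect_equal(s$n_events, 25L)
  expect_equal(s$span_median, spans[13])      # odd n: middle order statistic
  expect_equal(s$span_min, spans[1])
  expect_equal(s$span_max, spans[25])

  shuffled <- dels[sample(nrow(dels)), ]
  expect_equal(summarize_cnvs(shuffled), s)

  single <- summarize_cnvs(dels[1, ])
  expect_equal(single$span_median, single$span_min)
  expect_equal(single$span_median, single$span_max)

  empty <- summarize_cnvs(dels[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("repeat identity and informative sites are column-wise", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  expect_equal(percent_identity("ACGT", "TGCA"), 0)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  expect_error(percent_identity("ACG", "ACGT"), "equal length")

  # a 1031 bp alignment with 41 mismatches is 96.0% identical
  up <- paste(rep("A", 1031), collapse = "")
  down_vec <- rep("A", 1031); down_vec[seq_len(41)] <- "C"
  down <- paste(down_vec, collapse = "")
  expect_equal(round(percent_identity(up, down), 1), 96.0)
  expect_equal(informative_sites(up, down), 1:41)
})

test_that("crossover localization brackets the switch between repeats", {
  pair <- make_repeat_pair(len = 120, sites = c(10, 50, 90))

  # chimera matching downstream at 10 and 50, upstream at 90
  ch <- make_chimera(pair, 2)
  iv <- infer_crossover_interval(pair$upstream, pair$downstream, ch)
  expect_equal(iv$left, 50L)
  expect_equal(iv$right, 90L)

  # chimera identical to the downstream repeat: interval past the last site
  all_down <- infer_crossover_interval(pair$upstream, pair$downstream,
                                       pair$downstream)
  expect_equal(all_down$left, 90L)
  expect_equal(all_down$right, 121L)

  # chimeras switching in different gaps are distinct (independent) events
  intervals <- purrr::map(0:3, function(k) {
    infer_crossover_interval(pair$upstream, pair$downstream,
                             make_chimera(make_repeat_pair(120, c(10, 50, 90, 110)), k))
  }) |> purrr::list_rbind()
  expect_equal(nrow(dplyr::distinct(intervals[, c("left", "right")])), 4)

  # a base matching neither repeat at an informative site is an error
  bad <- strsplit(pair$upstream, "")[[1]]; bad[50] <- "C"
  expect_error(
    infer_crossover_interval(pair$upstream, pair$downstream,
                             paste(bad, collapse = "")),
    "neither repeat.*50")
})
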