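#' Inclusive span of CNV calls
#'
#' All catalog coordinates are 1-based inclusive (WormBase style), so a
#' call covering positions start..end spans `end - start + 1` bp. The
#' inclusive convention uniquely reproduces the published span columns of
#' the packaged duplication and deletion catalogs.
#'
#' @param calls tibble with columns start and end.
#' @return `calls` with a (re)computed integer `span` column.
#' @examples
#' cnv_span(tibble::tibble(start = 6837055, end = 6879497))$span # 42443
#' @export
cnv_span <- function(calls) {
  assert_columns(calls, c("start", "end"))
  if (any(calls$start > calls$end)) abort("calls must have start <= end")
  calls |> mutate(span = as.integer(.data$end - .data$start + 1))
}

#' Count annotation features encompassed by CNV calls
#'
#' A feature is counted when its interval overlaps the call interval by at
#' least 1 bp — partial overlap counts, matching how a partially deleted
#' gene is tallied in published CNV catalogs. Counts are reported per
#' biotype in the columns the catalogs use.
#'
#' @param calls tibble with columns chrom, start, end.
#' @param features feature tibble (chrom, start, end, biotype), e.g. the
#'   `features` element of a [make_genome()] model.
#' @return `calls` with one count column per biotype
#'   (protein_coding, trna, pirna, ncrna, pseudogene, transposon).
#' @export
annotate_cnvs <- function(calls, features) {
  assert_columns(calls, c("chrom", "start", "end"))
  assert_columns(features, c("chrom", "start", "end", "biotype"),
                 "features")
  biotypes <- c(protein_coding = "protein_coding", trna = "tRNA",
                pirna = "piRNA", ncrna = "ncRNA", pseudogene = "pseudogene",
                transposon = "transposon")
  counts <- pmap(list(calls$chrom, calls$start, calls$end),
                 function(cc, s, e) {
                   hit <- features$chrom == cc & features$start <= e &
                     features$end >= s
                   tab <- table(features$biotype[hit])
                   map_int(biotypes, function(b) {
                     if (b %in% names(tab)) as.integer(tab[[b]]) else 0L
                   })
                 })
  cmat <- do.call(rbind, counts)
  colnames(cmat) <- names(biotypes)
  bind_cols(calls, as_tibble(cmat))
}

#' @rdname annotate_cnvs
#' @param genome a `genome_model`; errors if a call names a chromosome the
#'   genome does not have.
#' @export
annotate_cnvs_genome <- function(calls, genome) {
  stopifnot(inherits(genome, "genome_model"))
  unknown <- setdiff(unique(calls$chrom), genome$chromosomes$name)
  if (length(unknown) > 0) {
    abort(paste("unknown chromosome(s) in calls:",
                paste(unknown, collapse = ", ")))
  }
  annotate_cnvs(calls, genome$features)
}

#' Per-haploid CNV frequency from the average copy-number
#'
#' Under a one-extra-copy model (each duplication carrier haplotype holds
#' exactly one additional copy), a population-average copy-number `c` per
#' haploid genome translates to a duplication frequency `c - 1` and a
#' deletion frequency `1 - c`, clipped to `[0, 1]`. Clipping mirrors the
#' published treatment of copy-numbers slightly above 2 (reported as
#' frequency 1, i.e. fixation).
#'
#' @param calls tibble with columns type and copy_number.
#' @return `calls` with an added `frequency` column.
#' @examples
#' frequency_from_copy(tibble::tibble(type = "duplication",
#'                                    copy_number = 2.19))$frequency # 1
#' @export
frequency_from_copy <- function(calls) {
  assert_columns(calls, c("type", "copy_number"))
  if (any(calls$copy_number < 0)) abort("copy_number must be >= 0")
  calls |>
    mutate(frequency = ifelse(.data$type == "duplication",
                              clip01(.data$copy_number - 1),
                              clip01(1 - .data$copy_number)))
}

#' Summarize a CNV catalog
#'
#' Event counts, number of populations carrying at least one event, and
#' median/min/max of the span and of each feature-count column present.
#' Medians follow the usual midpoint rule (average of the two central order
#' statistics for even n); feature columns with missing values are
#' summarized over their non-missing entries.
#'
#' @param calls a CNV-call tibble with columns population, start, end and
#'   optionally feature-count columns.
#' @param ... optional grouping expressions passed to [dplyr::group_by()]
#'   (e.g. `type` or `cohort`).
#' @return a summary tibble, one row per group (or a single row); empty
#'   input yields a zero-row tibble.
#' @export
summarize_cnvs <- function(calls, ...) {
  assert_columns(calls, c("population", "start", "end"))
  if (nrow(calls) == 0) {
    return(tibble(n_events = integer(), n_populations = integer()))
  }
  calls <- cnv_span(calls)
  feature_cols <- intersect(
    c("protein_coding", "trna", "pirna", "ncrna", "pseudogene", "transposon"),
    names(calls))
  calls |>
    group_by(...) |>
    summarize(
      n_events = n(),
      n_populations = n_distinct(.data$population),
      span_median = median(.data$span),
      span_min = min(.data$span),
      span_max = max(.data$span),
      across(all_of(feature_cols),
             list(median = ~ median(.x, na.rm = TRUE),
                  min = ~ suppressWarnings(min(.x, na.rm = TRUE)),
                  max = ~ suppressWarnings(max(.x, na.rm = TRUE)))),
      .groups = "drop"
    )
}

#' Load the packaged CNV catalogs and single-worm PCR table
#'
#' Returns the package's plain-text transcriptions of the published CNV
#' catalogs: 25 duplication calls, 25 deletion calls, and the single-worm
#' PCR frequency table. Rows of the single-worm table that are internally
#' inconsistent as printed carry `parseable = FALSE` (and a `note`), and
#' rows whose printed frequency disagrees with the Hardy-Weinberg estimator
#' applied to their own counts carry `freq_discrepant = TRUE`. Feature
#' counts unavailable without guessing digit grouping are `NA` in the
#' duplication catalog.
#'
#' @return a list with tibbles `duplications`, `deletions`, `single_worm`.
#' @export
load_cnv_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "wormcnv",
                                  mustWork = TRUE)
  dup <- readr::read_tsv(path("table1_duplications.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  del <- readr::read_tsv(path("table2_deletions.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  sw <- readr::read_tsv(path("table3_single_worm.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  if (nrow(dup) != 25 || nrow(del) != 25 || nrow(sw) != 16) {
    abort("packaged catalog fixtures are corrupted (unexpected row counts)")
  }
  dup$type <- "duplication"; del$type <- "deletion"
  list(duplications = dup, deletions = del, single_worm = sw)
}
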