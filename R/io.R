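#' Read and write the pipeline's tabular file formats
#'
#' Plain-text interchange formats, all round-tripping through these
#' readers:
#' * probe profiles — tab-delimited `chrom`, `pos` (1-based bp),
#'   `log2ratio`;
#' * Ct tables — CSV `run_id`, `group` (RR/RT/TR/TT, trailing `'`
#'   tolerated), `ct`;
#' * dilution series — CSV `log10_conc`, `ct`;
#' * worm counts — tab-delimited mirror of the single-worm PCR table;
#' * CNV catalogs — tab-delimited with 1-based inclusive `start`/`end`.
#'
#' @param x tibble to write.
#' @param path file path.
#' @return readers return tibbles; writers return `path` invisibly.
#' @name cnv_io
NULL

#' @rdname cnv_io
#' @export
write_probe_profile <- function(x, path) {
  assert_columns(x, c("chrom", "pos", "log2ratio"))
  readr::write_tsv(x[, c("chrom", "pos", "log2ratio")], path, progress = FALSE)
  invisible(path)
}

#' @rdname cnv_io
#' @export
read_probe_profile <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(x, c("chrom", "pos", "log2ratio"), "probe profile")
  x |> arrange(.data$chrom, .data$pos)
}

#' @rdname cnv_io
#' @export
write_ct_table <- function(x, path) {
  assert_columns(x, c("group", "ct"))
  if (!"run_id" %in% names(x)) x$run_id <- "run1"
  readr::write_csv(x[, c("run_id", "group", "ct")], path, progress = FALSE)
  invisible(path)
}

#' @rdname cnv_io
#' @export
read_ct_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(x, c("run_id", "group", "ct"), "Ct table")
  x
}

#' @rdname cnv_io
#' @export
read_dilution_series <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(x, c("log10_conc", "ct"), "dilution series")
  x
}

#' @rdname cnv_io
#' @export
write_worm_counts <- function(x, path) {
  assert_columns(x, c("n_sampled", "n_positive", "chromosome_class",
                      "cnv_type"))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname cnv_io
#' @export
read_worm_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(x, c("n_sampled", "n_positive", "chromosome_class",
                      "cnv_type"), "worm counts")
  x
}

#' @rdname cnv_io
#' @export
write_cnv_catalog <- function(x, path) {
  assert_columns(x, c("chrom", "start", "end", "type"))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname cnv_io
#' @export
read_cnv_catalog <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(x, c("chrom", "start", "end", "type"), "CNV catalog")
  x
}

#' Export CNV calls as BED6
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention (`chromStart = start - 1`, `chromEnd = end`). The
#' name field is `population|type` when a population column is present,
#' otherwise `type`; the score field carries round(1000 * frequency) when
#' available.
#'
#' @param calls CNV-call tibble with chrom, start, end, type.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  assert_columns(calls, c("chrom", "start", "end", "type"))
  name <- if ("population" %in% names(calls)) {
    paste(calls$population, calls$type, sep = "|")
  } else calls$type
  score <- if ("frequency" %in% names(calls)) {
    as.integer(round(1000 * clip01(calls$frequency)))
  } else rep(0L, nrow(calls))
  bed <- tibble(chrom = calls$chrom,
                chromStart = as.integer(calls$start - 1L),
                chromEnd = as.integer(calls$end),
                name = name, score = score, strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
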