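#' Build a synthetic genome model with a regular probe grid
#'
#' Generates a compact stand-in for a worm genome annotation: chromosomes of
#' equal length, an evenly spaced oligo-probe grid on each, and a set of
#' random non-degenerate annotation features drawn from the biotypes that
#' CNV catalogs count (protein-coding genes, tRNAs, piRNAs, ncRNAs,
#' pseudogenes, transposons). All coordinates are 1-based inclusive.
#'
#' @param n_chromosomes number of chromosomes; named I, II, ... (roman).
#' @param chrom_length length of every chromosome in bp.
#' @param probe_spacing distance in bp between consecutive probes; probes sit
#'   at `probe_spacing, 2*probe_spacing, ...` up to the chromosome end.
#' @param n_features total number of annotation features to scatter across
#'   the genome (0 for none).
#' @param seed integer seed; identical seeds give identical genomes.
#' @param feature_length_range min/max feature length in bp.
#' @return an object of class `genome_model`: a list with tibbles
#'   `chromosomes` (name, length), `probes` (chrom, pos) and `features`
#'   (chrom, start, end, biotype, id).
#' @examples
#' g <- make_genome(1, 100000, 1000, 0, seed = 1)
#' nrow(g$probes) # 100
#' @export
make_genome <- function(n_chromosomes, chrom_length, probe_spacing,
                        n_features = 0, seed = NULL,
                        feature_length_range = c(200, 5000)) {
  assert_scalar_number(n_chromosomes, "n_chromosomes", lower = 1)
  assert_scalar_number(chrom_length, "chrom_length", lower = 1)
  assert_scalar_number(probe_spacing, "probe_spacing", lower = 1)
  assert_scalar_number(n_features, "n_features", lower = 0)
  if (probe_spacing > chrom_length) {
    abort("`probe_spacing` must not exceed `chrom_length`")
  }

  chroms <- as.character(utils::as.roman(seq_len(n_chromosomes)))
  chromosomes <- tibble(name = chroms, length = as.integer(chrom_length))
  grid <- seq(probe_spacing, chrom_length, by = probe_spacing)
  probes <- tibble(
    chrom = rep(chroms, each = length(grid)),
    pos   = as.integer(rep(grid, times = n_chromosomes))
  )

  biotypes <- c("protein_coding", "tRNA", "piRNA", "ncRNA", "pseudogene",
                "transposon")
  features <- with_seed_or_not(seed, {
    if (n_features == 0) {
      tibble(chrom = character(), start = integer(), end = integer(),
             biotype = character(), id = character())
    } else {
      len <- round(runif(n_features, feature_length_range[1],
                         min(feature_length_range[2], chrom_length - 1)))
      start <- floor(runif(n_features, 1, chrom_length - len))
      tibble(
        chrom   = sample(chroms, n_features, replace = TRUE),
        start   = as.integer(start),
        end     = as.integer(start + len - 1),
        biotype = sample(biotypes, n_features, replace = TRUE,
                         prob = c(0.6, 0.08, 0.08, 0.08, 0.08, 0.08)),
        id      = sprintf("feat%04d", seq_len(n_features))
      ) |>
        arrange(.data$chrom, .data$start)
    }
  })

  structure(list(chromosomes = chromosomes, probes = probes,
                 features = features),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$probes), "probes,", nrow(x$features), "features\n")
  invisible(x)
}

features_to_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges   = IRanges::IRanges(start = features$start, end = features$end),
    biotype  = features$biotype,
    ID       = features$id
  )
}

#' Write and read genome annotation as GFF3 or BED
#'
#' The feature table of a [make_genome()] model (or any tibble with columns
#' chrom, start, end, biotype, id) is exported through `rtracklayer`.
#' GFF3 carries the biotype in the attributes column; the BED variant is
#' 6-column BED (0-based half-open, biotype in the name field as
#' `id|biotype`). Both round-trip through the matching readers.
#'
#' @param features tibble with columns chrom, start, end, biotype, id.
#' @param path output file.
#' @return `path`, invisibly (writers); a feature tibble (readers).
#' @export
write_annotation_gff3 <- function(features, path) {
  assert_columns(features, c("chrom", "start", "end", "biotype", "id"))
  gr <- features_to_granges(features)
  gr$type <- features$biotype
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import.gff3(path)
  tibble(
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr),
    end     = GenomicRanges::end(gr),
    biotype = as.character(gr$biotype),
    id      = as.character(gr$ID)
  )
}

#' @rdname write_annotation_gff3
#' @export
write_annotation_bed <- function(features, path) {
  assert_columns(features, c("chrom", "start", "end", "biotype", "id"))
  gr <- features_to_granges(features)
  names(gr) <- paste(features$id, features$biotype, sep = "|")
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  nm <- strsplit(as.character(gr$name), "|", fixed = TRUE)
  tibble(
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr),
    end     = GenomicRanges::end(gr),
    biotype = map_chr(nm, 2),
    id      = map_chr(nm, 1)
  )
}
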