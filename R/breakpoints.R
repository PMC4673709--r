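#' Percent identity of two aligned repeat sequences
#'
#' Simple column-wise identity of two equal-length aligned sequences,
#' as quoted for the repeat pairs that mediate unequal crossing-over.
#'
#' @param a,b character strings (or `Biostrings` objects coercible with
#'   `as.character()`) of equal length.
#' @return percent identity in `[0, 100]`.
#' @examples
#' percent_identity("ACGT", "ACGA") # 75
#' @export
percent_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  if (nchar(a) != nchar(b)) {
    abort("aligned sequences must have equal length")
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  100 * mean(av == bv)
}

#' Informative sites between two aligned repeats
#'
#' Positions at which the upstream and downstream repeat differ; only these
#' sites can localize the point of unequal crossing-over within the repeat.
#'
#' @inheritParams percent_identity
#' @return integer vector of 1-based positions.
#' @export
informative_sites <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) abort("aligned sequences must have equal length")
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Localize an unequal crossing-over point from a chimeric repeat
#'
#' A tandem duplication formed by unequal crossing-over between two
#' flanking repeats carries a chimeric repeat at its center: its 5' part
#' matches the downstream repeat and its 3' part the upstream repeat. At
#' each informative site the chimera is scored against both repeats; the
#' crossover is localized to the open interval between the last informative
#' site matching the downstream repeat and the first subsequent site
#' matching the upstream repeat. Distinct chimeras whose intervals fall in
#' different inter-site gaps are independent crossover events.
#'
#' @param upstream,downstream the aligned flanking repeat sequences.
#' @param chimera the chimeric (breakpoint-spanning) repeat sequence,
#'   aligned end-to-end with the repeats (equal length).
#' @return a one-row tibble: left, right (open interval bounds; `left = 0`
#'   when the chimera matches the upstream repeat at every informative
#'   site, `right = nchar + 1` when it matches the downstream repeat
#'   throughout), n_informative, n_downstream_matched.
#' @export
infer_crossover_interval <- function(upstream, downstream, chimera) {
  upstream <- toupper(as.character(upstream))
  downstream <- toupper(as.character(downstream))
  chimera <- toupper(as.character(chimera))
  if (nchar(chimera) != nchar(upstream)) {
    abort("chimera must align end-to-end with the repeats (equal length)")
  }
  sites <- informative_sites(upstream, downstream)
  if (length(sites) == 0) {
    abort("repeats are identical: no informative sites to localize a crossover")
  }
  uv <- strsplit(upstream, "")[[1]]
  dv <- strsplit(downstream, "")[[1]]
  cv <- strsplit(chimera, "")[[1]]

  match_up <- cv[sites] == uv[sites]
  match_down <- cv[sites] == dv[sites]
  neither <- !match_up & !match_down
  if (any(neither)) {
    abort(paste0("chimera matches neither repeat at informative site(s): ",
                 paste(sites[neither], collapse = ", ")))
  }
  # expected pattern: a (possibly empty) run of downstream matches followed
  # by a run of upstream matches; anything else is a mosaic we refuse to
  # interpret as a single crossover
  k <- sum(cumprod(match_down))          # leading downstream-matching sites
  if (any(match_down[seq_along(sites) > k])) {
    abort("chimera is mosaic: downstream-matching site found after the switch to upstream")
  }
  left <- if (k == 0) 0L else sites[k]
  right <- if (k == length(sites)) nchar(chimera) + 1L else sites[k + 1]
  tibble(left = as.integer(left), right = as.integer(right),
         n_informative = length(sites), n_downstream_matched = as.integer(k))
}

#' Read an aligned repeat pair (and optional chimeras) from FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` returning plain
#' character sequences named as in the FASTA headers.
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return named character vector of sequences.
#' @export
read_repeat_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}
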