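#' Cluster CNV calls that overlap the same genomic region
#'
#' Finds convergent (parallel) CNVs: same-chromosome, same-type calls from
#' different populations that overlap a common region.
#'
#' Two modes:
#' * `"intersection"` — maximal sets of calls whose **common** intersection
#'   is non-empty. For intervals these are exactly the maximal cliques of
#'   the interval-overlap graph (a clique of intervals shares at least one
#'   covered point), found by a sweep over interval start points.
#' * `"connected"` — connected components of the pairwise-overlap graph
#'   (calls chained by transitive overlap).
#'
#' Clusters are returned sorted by decreasing member count.
#'
#' @param calls tibble with columns population, chrom, start, end, type.
#' @param type optional filter: `"duplication"` or `"deletion"`. Mixed-type
#'   clustering is never performed; when `type` is `NULL` each type is
#'   clustered separately.
#' @param mode `"intersection"` (default) or `"connected"`.
#' @param min_members drop clusters with fewer members (default 1 keeps
#'   singletons).
#' @return tibble of clusters: chrom, type, n_members, populations
#'   (comma-separated), shared_start, shared_end, shared_length (inclusive;
#'   NA in connected mode when the common intersection is empty), and a
#'   list-column `members` holding the member calls.
#' @examples
#' calls <- load_cnv_fixtures()$deletions
#' overlap_clusters(calls, type = "deletion")
#' @export
overlap_clusters <- function(calls, type = NULL,
                             mode = c("intersection", "connected"),
                             min_members = 1) {
  assert_columns(calls, c("population", "chrom", "start", "end", "type"))
  mode <- match.arg(mode)
  if (!is.null(type)) calls <- calls |> filter(.data$type == !!type)
  if (nrow(calls) == 0) {
    return(tibble(chrom = character(), type = character(),
                  n_members = integer(), populations = character(),
                  shared_start = integer(), shared_end = integer(),
                  shared_length = integer(), members = list()))
  }

  groups <- calls |> group_by(.data$chrom, .data$type) |> group_split()
  clusters <- map(groups, function(g) {
    member_sets <- if (mode == "intersection") {
      interval_cliques(g$start, g$end)
    } else {
      overlap_components(g$start, g$end)
    }
    map(member_sets, function(idx) {
      m <- g[idx, ]
      s <- max(m$start); e <- min(m$end)
      tibble(
        chrom = m$chrom[1], type = m$type[1], n_members = nrow(m),
        populations = paste(m$population, collapse = ","),
        shared_start = if (s <= e) as.integer(s) else NA_integer_,
        shared_end = if (s <= e) as.integer(e) else NA_integer_,
        shared_length = if (s <= e) as.integer(e - s + 1) else NA_integer_,
        members = list(m)
      )
    }) |> bind_rows()
  }) |> bind_rows()

  clusters |>
    filter(.data$n_members >= min_members) |>
    arrange(desc(.data$n_members), .data$chrom, .data$shared_start)
}

# Maximal sets of intervals with a non-empty common intersection. Every
# such maximal set is the set of intervals covering some point; sweeping
# the start points enumerates all candidate point-cover sets, and subset
# filtering keeps the maximal ones.
interval_cliques <- function(start, end) {
  n <- length(start)
  cand <- map(sort(unique(start)), function(p) {
    which(start <= p & end >= p)
  })
  cand <- unique(cand)
  keep <- map_lgl(seq_along(cand), function(i) {
    !any(map_lgl(seq_along(cand), function(j) {
      j != i && length(cand[[i]]) < length(cand[[j]]) &&
        all(cand[[i]] %in% cand[[j]])
    }))
  })
  cand[keep]
}

# Connected components of the pairwise interval-overlap graph (union-find).
overlap_components <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && start[j] <= end[i] && end[j] >= start[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

#' Shared region of a set of overlapping CNV calls
#'
#' The maximal region common to every member of a convergent-CNV cluster:
#' start = max of member starts, end = min of member ends, length inclusive
#' (`end - start + 1`). Errors if the common intersection is empty.
#'
#' @param calls tibble with columns chrom, start, end (one cluster's
#'   members; must share one chromosome).
#' @return one-row tibble: chrom, shared_start, shared_end, shared_length.
#' @examples
#' dels <- load_cnv_fixtures()$deletions
#' six <- dels[dels$chrom == "V" & dels$start > 7e6 & dels$start < 8e6, ]
#' shared_region(six) # 17,333 bp
#' @export
shared_region <- function(calls) {
  assert_columns(calls, c("chrom", "start", "end"))
  if (nrow(calls) == 0) abort("no calls supplied")
  if (length(unique(calls$chrom)) != 1) {
    abort("shared_region expects calls on a single chromosome")
  }
  s <- max(calls$start); e <- min(calls$end)
  if (s > e) abort("calls have an empty common intersection")
  tibble(chrom = calls$chrom[1], shared_start = as.integer(s),
         shared_end = as.integer(e),
         shared_length = as.integer(e - s + 1))
}
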