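#' Read a pipeline run configuration from YAML
#'
#' A run configuration fully determines a simulated experiment: a root
#' `seed` (every stage draws from a named substream of it, so re-running a
#' config reproduces all outputs bit for bit), a `genome` block
#' (n_chromosomes, chrom_length, probe_spacing, n_features), a `noise`
#' block (probe_sd, ct_sd), a `segmentation` block (p_merge, m_min,
#' p_class, min_probes), a `worms` block (n_sampled), a vector of
#' `generations`, and a `populations` list, each population carrying an
#' `id` and a list of `cnvs` (chrom, start, end, type, chromosome_class,
#' and a `frequency` map from generation to per-haploid frequency).
#'
#' @param path YAML file.
#' @return the configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a configuration list built in R.
#' @export
validate_run_config <- function(config) {
  defaults <- list(
    seed = 1L,
    genome = list(n_chromosomes = 1, chrom_length = 1e6,
                  probe_spacing = 2000, n_features = 0),
    noise = list(probe_sd = 0.25, ct_sd = 0.15),
    segmentation = list(p_merge = 1e-3, m_min = 0.2, p_class = 1e-3,
                        min_probes = 3),
    worms = list(n_sampled = 30),
    generations = c(80, 140, 208),
    populations = list()
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && nm != "populations") {
      miss <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  for (pop in config$populations) {
    if (is.null(pop$id)) abort("every population needs an `id`")
    for (cnv in pop$cnvs %||% list()) {
      need <- c("chrom", "start", "end", "type", "frequency")
      if (!all(need %in% names(cnv))) {
        abort(sprintf("population %s: each CNV needs %s", pop$id,
                      paste(need, collapse = ", ")))
      }
    }
  }
  structure(config, class = c("run_config", "list"))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)), parent = e)
  })
}

#' Run the full simulated CNV-evolution pipeline
#'
#' End-to-end composition of the package's modules on a simulated
#' experiment: build a genome, inject each population's CNVs at their
#' per-generation frequencies, hybridize pooled DNA to the probe grid
#' ([simulate_acgh()]), segment and call CNVs ([call_cnvs()]), estimate
#' frequencies from the calls and from simulated single-worm PCR, cluster
#' convergent calls across populations at the final generation
#' ([overlap_clusters()]), and — when the config carries a `popgen` block
#' (ne, p0, n_reps) — attach a neutral-drift p-value to every surviving
#' call ([neutral_trajectory_pvalue()]).
#'
#' @param config a `run_config` (see [read_run_config()]) or a plain list
#'   with the same fields.
#' @param out_dir optional directory; when given, writes `calls.tsv`,
#'   `trajectory.tsv`, `clusters.tsv` and `summary.json` there.
#' @return a list of class `cnv_pipeline`: genome, calls, trajectory,
#'   clusters, popgen (or NULL) and summary.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_run_config(unclass(config))
  seed <- as.integer(config$seed)
  gp <- config$genome; np <- config$noise; sp <- config$segmentation

  genome <- pipeline_stage("genome", make_genome(
    gp$n_chromosomes, gp$chrom_length, gp$probe_spacing, gp$n_features,
    seed = substream_seed(seed, "genome")))
  chrom_lengths <- setNames(genome$chromosomes$length,
                            genome$chromosomes$name)
  generations <- as.integer(config$generations)

  calls_all <- list(); traj_all <- list()
  for (pi in seq_along(config$populations)) {
    pop <- config$populations[[pi]]
    cnv_list <- pop$cnvs %||% list()
    for (gi in seq_along(generations)) {
      gen <- generations[gi]
      empty_truth <- tibble(chrom = character(), start = integer(),
                            end = integer(), type = character(),
                            chromosome_class = character(),
                            frequency = double())
      truth <- c(list(empty_truth), map(cnv_list, function(cnv) {
        q <- cnv$frequency[[as.character(gen)]] %||% 0
        tibble(chrom = cnv$chrom, start = as.integer(cnv$start),
               end = as.integer(cnv$end), type = cnv$type,
               chromosome_class = cnv$chromosome_class %||% "autosome",
               frequency = as.numeric(q))
      })) |> bind_rows()
      active <- if (nrow(truth)) truth[truth$frequency > 0, ] else truth

      profile <- pipeline_stage("simulate_acgh", simulate_acgh(
        genome, active, probe_sd = np$probe_sd,
        seed = substream_seed(seed, paste0("acgh_", pop$id), gi)))
      calls <- pipeline_stage("call_cnvs", call_cnvs(
        profile, p_merge = sp$p_merge, m_min = sp$m_min,
        p_class = sp$p_class, min_probes = sp$min_probes,
        chrom_lengths = chrom_lengths, population = pop$id))
      calls$generation <- gen
      calls_all[[length(calls_all) + 1]] <- calls

      if (nrow(truth)) {
        traj <- truth
        traj$population <- pop$id; traj$generation <- gen
        traj$acgh_frequency <- pmap_dbl(
          list(truth$chrom, truth$start, truth$end, truth$type),
          function(cc, s, e, ty) {
            mid <- (s + e) / 2
            hit <- calls$chrom == cc & calls$type == ty &
              calls$start <= mid & calls$end >= mid
            if (any(hit)) calls$frequency[which(hit)[1]] else 0
          })
        worms <- pipeline_stage("worm_pcr", {
          pmap(list(truth$frequency, truth$chromosome_class, truth$type,
                    seq_len(nrow(truth))),
               function(q, cls, ty, k) {
                 simulate_worm_sample(
                   q, config$worms$n_sampled, cls, ty,
                   seed = substream_seed(seed, paste0("worm_", pop$id, "_", k), gi),
                   population = pop$id, generation = gen)
               }) |>
            bind_rows() |>
            estimate_worm_frequency()
        })
        traj$worm_q_hat <- worms$q_hat
        traj_all[[length(traj_all) + 1]] <- traj
      }
    }
  }

  calls <- bind_rows(calls_all)
  trajectory <- bind_rows(traj_all) |>
    (\(x) if (nrow(x)) select(x, "population", "generation", "chrom",
                              "start", "end", "type",
                              true_frequency = "frequency",
                              "acgh_frequency", "worm_q_hat") else x)()

  final_calls <- calls |> filter(.data$generation == max(generations))
  clusters <- pipeline_stage("convergence", {
    if (nrow(final_calls)) overlap_clusters(final_calls)
    else overlap_clusters(tibble(population = character(),
                                 chrom = character(), start = integer(),
                                 end = integer(), type = character()))
  })

  popgen <- NULL
  if (!is.null(config$popgen) && nrow(final_calls) > 0) {
    pg <- config$popgen
    popgen <- pipeline_stage("popgen", {
      final_calls |>
        mutate(drift_p = pmap_dbl(
          list(.data$frequency, seq_len(n())),
          function(q, k) {
            neutral_trajectory_pvalue(
              pg$ne, pg$p0 %||% (1 / (2 * pg$ne)), max(generations), q,
              n_reps = pg$n_reps %||% 2000,
              seed = substream_seed(seed, "popgen", k))$p_value
          }))
    })
  }

  summary <- list(
    seed = seed,
    n_populations = length(config$populations),
    generations = generations,
    n_calls = nrow(calls),
    n_clusters = nrow(clusters),
    calls_by_type = as.list(table(calls$type)),
    max_shared_members = if (nrow(clusters)) max(clusters$n_members) else 0L
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cnv_catalog(calls, file.path(out_dir, "calls.tsv"))
    if (nrow(trajectory)) {
      readr::write_tsv(trajectory, file.path(out_dir, "trajectory.tsv"),
                       progress = FALSE)
    }
    readr::write_tsv(clusters |> select(-"members"),
                     file.path(out_dir, "clusters.tsv"), progress = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(genome = genome, calls = calls, trajectory = trajectory,
                 clusters = clusters, popgen = popgen, summary = summary),
            class = "cnv_pipeline")
}

#' @export
print.cnv_pipeline <- function(x, ...) {
  cat("<cnv_pipeline>", x$summary$n_populations, "population(s) x",
      length(x$summary$generations), "generation(s);",
      x$summary$n_calls, "CNV call(s),", x$summary$n_clusters,
      "overlap cluster(s)\n")
  invisible(x)
}
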