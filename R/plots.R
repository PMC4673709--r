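#' Plot a probe profile with optional segment means
#'
#' Probe log2 ratios along a chromosome, optionally overlaid with the
#' stepwise segment means from [segment_profile()] and colored by the
#' labels from [classify_segments()].
#'
#' @param profile probe-profile tibble (chrom, pos, log2ratio).
#' @param segments optional segment tibble; a `label` column, if present,
#'   colors the segment means.
#' @return a ggplot object.
#' @export
plot_probe_profile <- function(profile, segments = NULL) {
  assert_columns(profile, c("chrom", "pos", "log2ratio"))
  p <- ggplot(profile, aes(x = .data$pos / 1e6, y = .data$log2ratio)) +
    geom_point(size = 0.4, alpha = 0.5, colour = "grey40") +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = expression(log[2] ~ ratio)) +
    theme_bw()
  if (!is.null(segments)) {
    if (!"label" %in% names(segments)) segments$label <- "segment"
    p <- p +
      geom_segment(
        data = segments,
        aes(x = .data$start_pos / 1e6, xend = .data$end_pos / 1e6,
            y = .data$mean, yend = .data$mean, colour = .data$label),
        linewidth = 1.1, inherit.aes = FALSE) +
      scale_colour_manual(values = c(amplified = "#d95f02",
                                     deleted = "#7570b3",
                                     neutral = "grey25",
                                     segment = "grey25"),
                          name = NULL)
  }
  p
}

#' Plot CNV frequency trajectories over generations
#'
#' One line per population x CNV, analogous to tracking the rise of
#' parallel duplications or deletions across the recovery generations.
#'
#' @param trajectory tibble with columns population, generation and a
#'   frequency column.
#' @param frequency name of the frequency column to draw.
#' @return a ggplot object.
#' @export
plot_frequency_trajectories <- function(trajectory,
                                        frequency = "acgh_frequency") {
  assert_columns(trajectory, c("population", "generation", frequency))
  key <- if (all(c("chrom", "start") %in% names(trajectory))) {
    paste0(trajectory$population, " ", trajectory$chrom, ":",
           trajectory$start)
  } else trajectory$population
  trajectory$series <- key
  ggplot(trajectory,
         aes(x = .data$generation, y = .data[[frequency]],
             colour = .data$series, group = .data$series)) +
    geom_line() + geom_point() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "recovery generation", y = "CNV frequency", colour = NULL) +
    theme_bw()
}

#' Plot a convergent-CNV cluster
#'
#' Horizontal bars for each member call with the shared region delimited by
#' vertical lines, mirroring the standard convergence figure.
#'
#' @param cluster one row of the tibble returned by [overlap_clusters()].
#' @return a ggplot object.
#' @export
plot_convergent_region <- function(cluster) {
  assert_columns(cluster, c("members", "shared_start", "shared_end"))
  if (nrow(cluster) != 1) abort("pass exactly one cluster row")
  m <- cluster$members[[1]]
  m$population <- factor(m$population, levels = rev(unique(m$population)))
  ggplot(m) +
    geom_segment(aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                     y = .data$population, yend = .data$population),
                 linewidth = 3, colour = "steelblue") +
    geom_vline(xintercept = c(cluster$shared_start, cluster$shared_end) / 1e6,
               colour = "darkorange") +
    labs(x = sprintf("chromosome %s position (Mb)", m$chrom[1]), y = NULL,
         title = sprintf("shared region: %s bp",
                         format(cluster$shared_length, big.mark = ","))) +
    theme_bw()
}

#' @export
autoplot.cnv_pipeline <- function(object, ...) {
  if (nrow(object$trajectory) == 0) {
    abort("pipeline has no trajectory to plot (no CNVs configured)")
  }
  plot_frequency_trajectories(object$trajectory)
}

#' @export
autoplot.copy_estimate <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = "estimate", y = .data$estimate)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                  width = 0.1) +
    labs(x = NULL, y = "copy-number ratio") +
    theme_bw()
}
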