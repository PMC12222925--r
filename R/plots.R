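#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot shift paths against the 1:1 line
#'
#' One panel per elevation cutoff: each lineage's path of reconstructed
#' pollinator-shift probability (x) versus environment-shift probability (y),
#' with the dashed 1:1 line. Paths grouping above the line indicate
#' environment shifts preceding pollinator shifts.
#'
#' @param object A `scenario_report`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.scenario_report <- function(object, ...) {
  ln <- object$lineages
  if (nrow(ln) == 0) abort("no lineages to plot")
  ggplot2::ggplot(
    ln,
    ggplot2::aes(x = .data$x_a, y = .data$y_a, colour = factor(.data$lineage))
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~cutoff, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "P(pollinator shifted) at ancestral node",
      y = "P(environment shifted) at ancestral node",
      colour = "lineage"
    ) +
    ggplot2::theme_minimal()
}

#' Plot full shift-path trajectories for one cutoff
#'
#' @param report A `scenario_report`.
#' @param tree,asr_poll,asr_env The inputs used to build the report.
#' @param cutoff Which cutoff to draw.
#' @return A ggplot with one line per lineage.
#' @export
plot_shift_paths <- function(report, tree, asr_poll, asr_env, cutoff = 1000) {
  cl <- report$clades
  if (nrow(cl) == 0) abort("no shifted clades")
  paths <- purrr::map_dfr(seq_len(nrow(cl)), function(i) {
    p <- extract_shift_path(
      tree, cl[i, ], asr_poll, asr_env,
      cutoff = cutoff, tau_shift = report$params$tau_shift,
      ancestral = report$params$ancestral
    )
    dplyr::mutate(tibble::as_tibble(p), lineage = cl$clade_id[i])
  })
  ggplot2::ggplot(
    paths,
    ggplot2::aes(.data$x, .data$y, group = .data$lineage, colour = factor(.data$lineage))
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "P(pollinator shifted)", y = "P(environment shifted)",
      colour = "lineage",
      title = sprintf("Shift paths, montane cutoff %d m", cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Elevation distribution by pollination group
#'
#' @param summaries Species niche summaries (from [summarize_species()]).
#' @param groups Named vector species -> group label.
#' @return A ggplot boxplot of median elevation per group.
#' @export
plot_elevation_by_group <- function(summaries, groups) {
  d <- dplyr::mutate(summaries, group = groups[.data$species])
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$elevation_m, fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "Median elevation (m)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
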