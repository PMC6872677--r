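#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' NMDS ordination scatter
#'
#' @param object An `nmds_result` from [run_nmds()].
#' @param groups Optional group labels (one per sample) used for colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmds_result <- function(object, groups = NULL, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  if (!is.null(groups)) {
    pts$group <- as.factor(groups)
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2,
                                           colour = .data$group))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Stacked bars of assembly-process fractions per group
#'
#' @param object An `assembly_result` from [run_assembly()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_result <- function(object, ...) {
  summ <- object$summary[!is.na(object$summary$fraction), ]
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$fraction,
                                     fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of pairwise comparisons",
                  fill = "process") +
    ggplot2::theme_minimal()
}

#' Distance-decay scatter of similarity against geographic distance
#'
#' @param comm Community dissimilarity `dist`.
#' @param geo Geographic distance `dist` (km).
#' @return A ggplot of 1 - dissimilarity vs distance with a linear trend.
#' @export
plot_distance_decay <- function(comm, geo) {
  df <- tibble::tibble(distance_km = as.vector(stats::as.dist(geo)),
                       similarity = 1 - as.vector(stats::as.dist(comm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_km, y = .data$similarity)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "geographic distance (km)",
                  y = "community similarity (1 - Bray-Curtis)") +
    ggplot2::theme_minimal()
}

#' Boxplots of alpha-diversity metrics by group
#'
#' @param alpha Tibble from [alpha_table()].
#' @param groups Group labels aligned with `alpha$sample_id`.
#' @return A ggplot faceted by metric.
#' @export
plot_alpha <- function(alpha, groups) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(alpha, group = as.factor(groups)),
    cols = c("richness", "shannon", "faith_pd"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
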