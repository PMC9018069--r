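#' Plot learner features colored by cluster
#'
#' Scatter of day-1 versus day-2 early error with point shape by savings
#' sign and color by cluster assignment.
#'
#' @param object a `learner_clusters` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot learner_clusters
#' @export
autoplot.learner_clusters <- function(object, ...) {
  df <- as.data.frame(object$features)
  df$cluster <- factor(object$labels$cluster)
  xv <- names(df)[1]; yv <- names(df)[2]
  ggplot2::ggplot(df, ggplot2::aes(.data[[xv]], .data[[yv]],
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Early error day 1 (z)", y = "Early error day 2 (z)",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Plot excursion curves
#'
#' Standardized excursion against volume, one line per subject, facetted by
#' network and day when those columns are present.
#'
#' @param curves tibble with `volume`, `standardized`, and optionally
#'   `subject`, `group`, `network`, `day`.
#' @param rotation_onset optional volume index to mark.
#' @return a ggplot.
#' @export
plot_excursion <- function(curves, rotation_onset = NULL) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(.data$volume, .data$standardized))
  if ("subject" %in% names(curves)) {
    p <- p + ggplot2::aes(group = .data$subject)
  }
  if ("group" %in% names(curves)) {
    p <- p + ggplot2::aes(colour = .data$group)
  }
  p <- p + ggplot2::geom_line(alpha = 0.5)
  if (all(c("network", "day") %in% names(curves))) {
    p <- p + ggplot2::facet_grid(network ~ day,
                                 labeller = ggplot2::label_both)
  }
  if (!is.null(rotation_onset)) {
    p <- p + ggplot2::geom_vline(xintercept = rotation_onset,
                                 linetype = "dashed")
  }
  p + ggplot2::labs(x = "Volume", y = "Excursion (baseline SD units)") +
    ggplot2::theme_minimal()
}

#' Plot mfPCA component curves
#'
#' One panel per element (network x day), one line per component.
#'
#' @param object an `mfpca_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mfpca_result
#' @export
autoplot.mfpca_result <- function(object, ...) {
  ggplot2::ggplot(object$components,
                  ggplot2::aes(.data$grid, .data$value,
                               colour = factor(.data$component))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~element) +
    ggplot2::labs(x = "Volume", y = "Component loading",
                  colour = "Component") +
    ggplot2::theme_minimal()
}

#' Plot joint-embedding scores
#'
#' Scatter of the first two component scores, optionally decorated from a
#' design tibble (rows aligned with the embedded observations).
#'
#' @param object a `joint_embedding`.
#' @param design optional tibble with per-observation `group` and `epoch`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot joint_embedding
#' @export
autoplot.joint_embedding <- function(object, design = NULL, ...) {
  if (ncol(object$scores) < 2L) {
    abort("Need at least two components to plot.")
  }
  df <- tibble(score1 = object$scores[, 1], score2 = object$scores[, 2])
  if (!is.null(design)) df <- dplyr::bind_cols(df, design)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$score1, .data$score2))
  if ("group" %in% names(df)) p <- p + ggplot2::aes(colour = .data$group)
  if ("epoch" %in% names(df)) p <- p + ggplot2::aes(shape = .data$epoch)
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Component 1 score", y = "Component 2 score") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap cluster-validity curves
#'
#' Observed within/total sum-of-squares ratio per candidate k against the
#' null 5th-95th percentile band.
#'
#' @param validity tibble from [bootstrap_cluster_validity()].
#' @return a ggplot.
#' @export
plot_cluster_validity <- function(validity) {
  ggplot2::ggplot(validity, ggplot2::aes(.data$k)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_q05,
                                      ymax = .data$null_q95),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_q50),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ss_ratio_observed),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$ss_ratio_observed),
                        colour = "firebrick") +
    ggplot2::labs(x = "Number of clusters",
                  y = "Within / total sum of squares") +
    ggplot2::theme_minimal()
}
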