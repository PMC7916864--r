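#' Plot an LD decay curve
#'
#' Mean r2 per distance bin against the bin's median pair distance, one
#' line per group.
#'
#' @param bins An [ld_decay()] tibble (rows for several groups may be bound
#'   together).
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(bins) {
  usable <- bins[!is.na(bins$mean_r2), ]
  ggplot2::ggplot(
    usable,
    ggplot2::aes(
      x = .data$median_distance / 1e3, y = .data$mean_r2,
      colour = .data$group
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Distance (kb)", y = expression(mean ~ r^2),
      colour = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ld_decay
#' @param object An `ld_decay` tibble.
#' @param ... Unused.
#' @export
autoplot.ld_decay <- function(object, ...) plot_ld_decay(object)

#' Plot an Ne trajectory
#'
#' Estimated effective population size against generations ago.
#'
#' @param traj An [ne_trajectory()] tibble; a `group` column, if present,
#'   is mapped to colour.
#' @return A ggplot object.
#' @export
plot_ne_trajectory <- function(traj) {
  p <- if ("group" %in% names(traj)) {
    ggplot2::ggplot(traj, ggplot2::aes(
      x = .data$generations_ago, y = .data$ne, colour = .data$group
    ))
  } else {
    ggplot2::ggplot(traj, ggplot2::aes(
      x = .data$generations_ago, y = .data$ne
    ))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Generations ago", y = "Estimated Ne") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ne_trajectory
#' @param object An `ne_trajectory` tibble.
#' @param ... Unused.
#' @export
autoplot.ne_trajectory <- function(object, ...) plot_ne_trajectory(object)

#' Plot per-sample F_ROH by group
#'
#' @param froh A tibble from [f_roh()] joined with a `group` column.
#' @return A ggplot object (boxplots per group, one facet per length
#'   threshold).
#' @export
plot_froh <- function(froh) {
  ggplot2::ggplot(froh, ggplot2::aes(x = .data$group, y = .data$f_roh)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~threshold, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Group", y = expression(F[ROH])) +
    ggplot2::theme_minimal()
}
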