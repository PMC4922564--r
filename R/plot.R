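#' Plot per-position, per-cluster mutual information
#'
#' Bar panel of `MI_pi(c_j)` across alignment positions, one facet per
#' cluster; tall bars mark candidate specificity determining positions.
#'
#' @param object An [overall_mi()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_report <- function(object, ...) {
  df <- object$per_position
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mi)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cluster)) +
    ggplot2::labs(x = "active-site position", y = "MI (nats)",
                  title = sprintf("Per-position cluster MI (overall %.3f)",
                                  object$overall)) +
    ggplot2::theme_minimal()
}

#' Plot cluster active-site composition profiles
#'
#' Stacked per-position residue frequencies, one facet per cluster: a
#' text-based stand-in for a sequence logo (residue letters scaled by
#' frequency are the logo analogue; here frequency is bar height).
#'
#' @param object A [cluster_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$position), y = .data$freq,
                               fill = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cluster)) +
    ggplot2::labs(x = "active-site position", y = "residue frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot the evolutionary fitness trajectory
#'
#' Best and mean fitness per generation; the best trajectory is
#' non-decreasing under elitism.
#'
#' @param object An `isofam_gp` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isofam_gp <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("best_fitness", "mean_fitness"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "MI fitness",
                  title = object$equation) +
    ggplot2::theme_minimal()
}
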