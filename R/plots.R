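#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the convergence trace of an ACO selection
#'
#' @param object A `panel_selection` from an ACO-based scheme.
#' @param ... Unused.
#' @return A ggplot of the global-best accuracy loss per epoch.
#' @method autoplot panel_selection
#' @export
autoplot.panel_selection <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("no per-epoch trace: only ACO-based selections can be plotted",
         call. = FALSE)
  }
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$epoch, .data$best_loss)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "epoch", y = "best accuracy loss (%)",
                  title = sprintf("%s: %d of %d loci, loss %.3g%%",
                                  object$scheme, object$n, object$k,
                                  object$loss)) +
    ggplot2::theme_minimal()
}

#' Boxplots of scheme accuracies by panel size
#'
#' @param object A `scheme_comparison` from [compare_schemes()].
#' @param ... Unused.
#' @method autoplot scheme_comparison
#' @export
autoplot.scheme_comparison <- function(object, ...) {
  ggplot2::ggplot(object$accuracies,
                  ggplot2::aes(factor(.data$n), .data$accuracy,
                               fill = .data$scheme)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8),
                          outlier.size = 0.6) +
    ggplot2::labs(x = "panel size (N)", y = "estimation accuracy (%)",
                  fill = "scheme") +
    ggplot2::theme_minimal()
}

#' Plot a marker-reduction curve
#'
#' @param object A `reduction_curve` tibble from [reduction_curve()].
#' @param ... Unused.
#' @method autoplot reduction_curve
#' @export
autoplot.reduction_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "panel size (N)", y = "AGD accuracy loss (%)",
                  title = paste("progressive reduction:",
                                attr(object, "scheme"))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a Nei distance matrix
#'
#' @param object A `nei_dist` from [genetic_dist()].
#' @param ... Unused.
#' @method autoplot nei_dist
#' @export
autoplot.nei_dist <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$group_a, .data$group_b,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Nei D") +
    ggplot2::theme_minimal()
}
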