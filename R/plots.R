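#' Plot methods
#'
#' `autoplot()` methods for the package's result objects:
#' a `coda_fit` shows the CODA score histogram with the fitted mixture
#' densities; `coda_scores` shows the per-position pairing-score contact
#' map; a `coda_fold` shows pair frequencies over the annealing ensemble
#' (upper triangle) against an optional reference (lower triangle).
#' `plot_pr_curve()` draws a precision-recall curve from [pr_curve()].
#'
#' @param object The object to plot.
#' @param reference Optional reference pair tibble.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @name codarna-plots
NULL

#' @rdname codarna-plots
#' @export
autoplot.coda_fit <- function(object, bins = 80, ...) {
  mx <- object$mixture
  d <- object$scores$per_mutation
  grid <- seq(min(d$coda), max(d$coda), length.out = 400)
  dens <- dplyr::bind_rows(
    tibble(coda = grid, component = "unpaired",
           density = (1 - mx$p_paired) * dnorm(grid, mx$a1, mx$sd1)),
    tibble(coda = grid, component = "paired",
           density = mx$p_paired * dnorm(grid, mx$a2, mx$sd2))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coda)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80",
                            colour = "grey50") +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(y = .data$density, colour = .data$component)) +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "CODA score", y = "density (sqrt scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname codarna-plots
#' @export
autoplot.coda_scores <- function(object, reference = NULL, ...) {
  pp <- object$per_position
  p <- ggplot2::ggplot(pp, ggplot2::aes(x = .data$j, y = .data$i)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$ps)) +
    ggplot2::scale_fill_viridis_c(name = "Ps") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position j", y = "position i") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_point(
      data = reference, ggplot2::aes(x = .data$i, y = .data$j),
      shape = 4, size = 1.5, colour = "red")
  }
  p
}

#' @rdname codarna-plots
#' @export
autoplot.coda_fold <- function(object, reference = NULL, ...) {
  p <- ggplot2::ggplot(object$pair_freq,
                       ggplot2::aes(x = .data$j, y = .data$i)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$freq,
                                     colour = .data$freq)) +
    ggplot2::scale_colour_viridis_c(name = "frequency") +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position j", y = "position i") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_point(
      data = reference, ggplot2::aes(x = .data$i, y = .data$j),
      shape = 4, size = 1.5, colour = "red")
  }
  p
}

#' @rdname codarna-plots
#' @param pr Result of [pr_curve()].
#' @export
plot_pr_curve <- function(pr, ...) {
  ggplot2::ggplot(pr$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("AUC-PR = %.3f", pr$auc_pr),
      x = "recall (sensitivity)", y = "precision") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
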