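#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster grid
#'
#' @param object a [raster_grid()].
#' @param ... unused.
#' @return A ggplot raster map of the unmasked cells.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- as_tibble.raster_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}

#' Plot a tuning grid
#'
#' @param object a `maxent_tuning`.
#' @param ... unused.
#' @return A ggplot of AICc difference against the regularization
#'   multiplier, one line per feature-class set, selected model marked.
#' @export
autoplot.maxent_tuning <- function(object, ...) {
  cand <- object$candidates
  ggplot2::ggplot(cand, ggplot2::aes(x = .data$rm, y = .data$dAICc,
                                     colour = .data$fc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = cand[cand$selected, ], size = 3,
                        shape = 21, fill = "white") +
    ggplot2::labs(x = "Regularization multiplier",
                  y = expression(Delta * "AICc"),
                  colour = "Feature classes")
}

#' Plot simulated loss distributions
#'
#' @param object a `risk_result`.
#' @param quantities which outputs to show.
#' @param ... unused.
#' @return A ggplot of the simulated distributions in billions USD,
#'   facetted by quantity.
#' @export
autoplot.risk_result <- function(object,
                                 quantities = c("F1", "F2", "F3", "F4", "F5"),
                                 ...) {
  long <- tidyr::pivot_longer(object$samples[quantities],
                              dplyr::everything(),
                              names_to = "quantity", values_to = "usd")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$usd / 1e9)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = "Billion USD", y = "Iterations")
}

#' Tornado plot of rank sensitivities
#'
#' @param result a `risk_result`.
#' @param output which simulated quantity's sensitivities to show.
#' @return A ggplot bar chart of Spearman rho sorted by magnitude.
#' @export
plot_sensitivity <- function(result, output = "F1") {
  stopifnot(inherits(result, "risk_result"),
            output %in% names(result$sensitivity))
  s <- result$sensitivity[[output]]
  s$variable <- factor(s$variable, levels = rev(s$variable))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$rho, y = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("Spearman rank correlation with %s", output),
                  y = NULL)
}

#' Plot a niche comparison matrix
#'
#' @param object a `niche_comparison`.
#' @param ... unused.
#' @return A ggplot tile chart: Sorensen overlap above the diagonal,
#'   centroid distance below.
#' @export
autoplot.niche_comparison <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::drop_na(
    tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(m), row = rownames(m)),
      -dplyr::all_of("row"), names_to = "col", values_to = "value"),
    "value")
  df$what <- ifelse(match(df$row, rownames(m)) < match(df$col, colnames(m)),
                    "Sorensen", "Centroid distance")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$value))) +
    ggplot2::facet_wrap(~what) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}

#' Plot a response curve
#'
#' @param model a `maxent_model` from [fit_sdm()].
#' @param variable variable to sweep.
#' @param n_points sweep resolution.
#' @return A ggplot of cloglog suitability against the variable.
#' @export
plot_response <- function(model, variable, n_points = 100) {
  rc <- response_curve(model, variable, n_points)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$value, y = .data$cloglog)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = variable, y = "Cloglog suitability") +
    ggplot2::ylim(0, 1)
}
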