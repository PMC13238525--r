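#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cross-map skill curve
#'
#' @param object A `ccm_result`.
#' @param ... Unused.
#' @return A ggplot: mean skill against library size with +/- 1 SD ribbon.
#' @export
autoplot.ccm_result <- function(object, ...) {
  d <- object$skill_curve
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lib_size, y = .data$rho)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rho - .data$rho_sd,
                                      ymax = .data$rho + .data$rho_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "library size", y = "cross-map skill (rho)",
                  title = object$direction_label,
                  subtitle = paste0("E = ", object$E, ", convergent: ",
                                    object$convergent)) +
    ggplot2::theme_minimal()
}

#' Plot calibration observed-vs-predicted values
#'
#' @param object An `edna_calibration`.
#' @param ... Unused.
#' @return A ggplot on log1p scales with the 1:1 line.
#' @export
autoplot.edna_calibration <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$observed + object$pseudocount,
                               y = .data$predicted + object$pseudocount)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "observed (+ pseudocount)",
                  y = "predicted (+ pseudocount)",
                  title = sprintf("eDNA transport calibration (tau = %.3g s)",
                                  object$tau)) +
    ggplot2::theme_minimal()
}

#' Plot a per-reach metric against flow distance to the outlet
#'
#' @param field A `reach_metrics_field` (or any data frame with
#'   `distance_km`).
#' @param metric Metric column name.
#' @return A ggplot with a linear trend line.
#' @export
plot_gradient <- function(field, metric = "link_density") {
  d <- field[stats::complete.cases(field[, c("distance_km", metric)]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_km,
                                  y = .data[[metric]])) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "steelblue") +
    ggplot2::labs(x = "distance to outlet (km)", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a food web by trophic level
#'
#' Nodes are placed on their prey-averaged trophic level (vertical axis)
#' with consumers above their resources.
#'
#' @param object A `food_web`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.food_web <- function(object, ...) {
  tl <- trophic_levels(object)
  set.seed(1)  # jitter layout only
  tl$x <- stats::ave(seq_len(nrow(tl)), round(tl$trophic_level),
                     FUN = function(i) seq_along(i) + stats::runif(length(i), -0.3, 0.3))
  seg <- dplyr::inner_join(
    dplyr::inner_join(object$links, tl, by = c(consumer = "taxon_id")),
    tl, by = c(resource = "taxon_id"), suffix = c("_c", "_r"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x_c, y = .data$trophic_level_c,
                   xend = .data$x_r, yend = .data$trophic_level_r),
      alpha = 0.25, colour = "grey40") +
    ggplot2::geom_point(data = tl,
                        ggplot2::aes(x = .data$x, y = .data$trophic_level),
                        size = 2, colour = "steelblue") +
    ggplot2::labs(x = NULL, y = "trophic level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
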