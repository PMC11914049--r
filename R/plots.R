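#' Plot posterior effect sizes of a hierarchical Bayesian fit
#'
#' Medians with 80% (thick) and 95% (thin) highest density intervals per
#' coefficient; credible trends (80% HDI excluding zero) are coloured.
#'
#' @param object An `hbm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hbm_fit
#' @export
autoplot.hbm_fit <- function(object, ...) {
  df <- object$summary |>
    filter(.data$term %in% object$spec$terms, .data$term != "intercept") |>
    mutate(term = factor(.data$term, levels = rev(object$spec$terms)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$hdi95_lower, xend = .data$hdi95_upper,
                                       yend = .data$term), linewidth = 0.4) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$hdi80_lower, xend = .data$hdi80_upper,
                                       yend = .data$term, colour = .data$credible),
                          linewidth = 1.6) +
    ggplot2::geom_point(ggplot2::aes(x = .data$median), size = 2) +
    ggplot2::scale_colour_manual(values = c(credible_negative = "#2166ac",
                                            credible_positive = "#b2182b",
                                            not_credible = "grey40")) +
    ggplot2::labs(x = "standardized effect size (alr scale)", y = NULL,
                  colour = "80% HDI") +
    ggplot2::theme_minimal()
}

#' Plot an nMDS ordination
#'
#' @param object A `reef_nmds`.
#' @param colour Optional vector (aligned to samples) mapped to point
#'   colour.
#' @param vectors Optional tibble from [fit_env_vectors()] overlaid as
#'   arrows scaled by correlation.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reef_nmds
#' @export
autoplot.reef_nmds <- function(object, colour = NULL, vectors = NULL, ...) {
  df <- object$points
  if (!is.null(colour)) df$group <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
  if (!is.null(vectors)) {
    sc <- 0.9 * max(abs(c(df$NMDS1, df$NMDS2)))
    arr <- vectors |> mutate(x = .data$NMDS1 * sqrt(.data$r2) * sc,
                             y = .data$NMDS2 * sqrt(.data$r2) * sc)
    p <- p +
      ggplot2::geom_segment(data = arr,
                            ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
                            arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                            colour = "grey30", inherit.aes = FALSE) +
      ggplot2::geom_text(data = arr,
                         ggplot2::aes(x = 1.08 * .data$x, y = 1.08 * .data$y,
                                      label = .data$variable),
                         size = 3, colour = "grey30", inherit.aes = FALSE)
  }
  p
}

#' Plot a fitted smooth with its confidence band
#'
#' @param object A `smooth_fit`.
#' @param n_grid Grid resolution.
#' @param ... Unused.
#' @return A ggplot of the data, fitted curve and 95% band (alr scale).
#' @method autoplot smooth_fit
#' @export
autoplot.smooth_fit <- function(object, n_grid = 100, ...) {
  mf <- object$gam$model
  grid <- seq(object$x_range[1], object$x_range[2], length.out = n_grid)
  pc <- predict_curve(object, grid)
  ggplot2::ggplot(pc, ggplot2::aes(.data$x, .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = mf, ggplot2::aes(.data$x, .data$y),
                        alpha = 0.4, inherit.aes = FALSE) +
    ggplot2::labs(x = "covariate", y = "alr cover",
                  caption = sprintf("EDF = %.2f (k = %d)", object$edf, object$k)) +
    ggplot2::theme_minimal()
}

#' Plot a light-response fit over its data
#'
#' @param object A `light_response`.
#' @param ... Unused.
#' @return A ggplot of window NEC against light with the fitted curve.
#' @method autoplot light_response
#' @export
autoplot.light_response <- function(object, ...) {
  df <- object$data
  grid <- tibble(light = seq(0, max(df$light), length.out = 100))
  grid$nec <- predict(object, grid$light)
  ggplot2::ggplot(df, ggplot2::aes(.data$light, .data$nec)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(x = "photon flux", y = expression(NEC~(mmol~m^-2~h^-1)),
                  caption = sprintf("form: %s", object$form)) +
    ggplot2::theme_minimal()
}
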