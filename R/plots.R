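#' Plot flux estimates with confidence intervals
#'
#' Bar chart of fitted net fluxes; if profile CIs have been computed
#' ([profile_ci]) they are drawn as error bars.
#'
#' @param object A `flux_fit`.
#' @param reactions Optional subset of reaction ids.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_fit <- function(object, reactions = NULL, ...) {
  d <- tidy(object)
  if (!is.null(reactions)) d <- d[d$reaction %in% reactions, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$reaction, .data$net_flux),
                                       y = .data$net_flux)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "net flux (nmol/10^6 cells/h)") +
    ggplot2::theme_minimal()
  if ("lo95" %in% names(d)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95), width = 0.3)
  }
  p
}

#' Compare simulated and measured MIDs
#'
#' Facetted bar/point plot of measured mass-isotopomer fractions against
#' the model prediction of a flux map.
#'
#' @param net A `flux_network`.
#' @param fmap A `flux_map` (e.g. from a `flux_fit`'s `$flux`).
#' @param mids Measured MID tibble.
#' @param tracer Tracer (spec or mixture) of the datasets shown.
#' @param fragments Fragment definitions, as in [simulate_mids].
#' @return A ggplot object.
#' @export
plot_mid_fit <- function(net, fmap, mids, tracer, fragments = mef_fragments()) {
  pred <- simulate_mids(net, fmap, tracer, fragments = fragments)
  meas <- mids %>%
    dplyr::group_by(.data$fragment, .data$mass_shift) %>%
    dplyr::summarise(measured = mean(.data$fraction), .groups = "drop")
  d <- dplyr::left_join(pred, meas, by = c("fragment", "mass_shift"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mass_shift)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$measured), fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$fraction), colour = "black", size = 1) +
    ggplot2::facet_wrap(~fragment, scales = "free_x") +
    ggplot2::labs(x = "mass shift (M+k)", y = "mole fraction",
                  caption = "bars: measured (mean over replicates); points: model") +
    ggplot2::theme_minimal()
}

#' Plot a growth curve with the fitted exponential
#'
#' @param cells Tibble with `time_h`, `cells_e6` (replicate rows allowed).
#' @return A ggplot object.
#' @export
plot_growth <- function(cells) {
  g <- fit_growth_rate(cells)
  curve <- tibble::tibble(
    time_h = seq(min(cells$time_h), max(cells$time_h), length.out = 50)
  )
  curve$cells_e6 <- g$x0 * exp(g$mu * curve$time_h)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$time_h, y = .data$cells_e6)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "grey40") +
    ggplot2::labs(x = "time (h)", y = "cells (10^6/well)",
                  subtitle = sprintf("mu = %.4f 1/h", g$mu)) +
    ggplot2::theme_minimal()
}
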