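#' @export
autoplot.stability_fit <- function(object, terms = object$predictors, ...) {
  td <- tidy(object) |>
    dplyr::filter(.data$term %in% terms)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_x") +
    ggplot2::labs(x = "effect on log-odds of choosing pair two (90% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.thurstone_fit <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$type, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q2.5,
                                          ymax = .data$q97.5)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free_y") +
    ggplot2::labs(x = "chord type",
                  y = paste0("finishedness relative to '", object$reference,
                             "' (latent SD units, 95% CI)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot predicted choice-probability curves
#'
#' @param curves Tibble from [predict_choice_curve()] (draw 0 is the
#'   posterior-mean curve; other draws are individual posterior curves).
#' @return A ggplot.
#' @export
plot_choice_curve <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$prob,
                                       group = .data$draw)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$draw != 0),
                       alpha = 0.15, colour = "steelblue") +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$draw == 0),
                       linewidth = 1) +
    ggplot2::facet_grid(ggplot2::vars(.data$group),
                        ggplot2::vars(.data$feature)) +
    ggplot2::labs(x = "feature change (third to fourth chord)",
                  y = "P(choose second pair as finished)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a smoothed log-frequency spectrum
#'
#' @param smoothed A `smoothed_spectrum`.
#' @return A ggplot of weight against cents position.
#' @export
plot_smoothed_spectrum <- function(smoothed) {
  df <- tibble::tibble(
    cents = smoothed$origin +
      (seq_along(smoothed$weights) - 1) * smoothed$resolution,
    weight = smoothed$weights
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$cents, .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cents above first partial", y = "weight") +
    ggplot2::theme_minimal()
}
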