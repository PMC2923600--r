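#' Plot training samples in PC space
#'
#' Scatter of the top two PC scores, optionally colored by population.
#'
#' @param object A `pca_fit`.
#' @param geo Optional [geo_table()] used to color points by population.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_fit <- function(object, geo = NULL, ...) {
  tb <- tidy(object)
  if (!is.null(geo)) {
    geo <- geo_table(geo)
    tb$population <- geo$population[match(tb$sample_id, geo$sample_id)]
  }
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if ("population" %in% names(tb)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$population),
                            alpha = 0.7)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::labs(x = "PC1", y = "PC2",
                    title = "Training samples in PC space")
}

#' Plot PCAIM leverage scores by rank
#'
#' @param scores A score table from [pcaim_scores()].
#' @param pool_size Optional pool cut-off to mark.
#' @return A ggplot of score against rank (log-log).
#' @export
plot_score_decay <- function(scores, pool_size = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "leverage score",
                  title = "PCAIM score decay")
  if (!is.null(pool_size)) {
    p <- p + ggplot2::geom_vline(xintercept = pool_size, linetype = 2)
  }
  p
}

#' Plot predicted against true coordinates
#'
#' One panel per axis: predicted versus true degrees with the identity line.
#'
#' @param object A `loocv_result`.
#' @param geo The [geo_table()] with true coordinates.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loocv_result <- function(object, geo, ...) {
  geo <- geo_table(geo)
  tb <- object$predictions
  gi <- match(tb$sample_id, geo$sample_id)
  long <- dplyr::bind_rows(
    tibble(axis = "latitude", true = geo$latitude[gi],
           predicted = tb$pred_latitude, population = geo$population[gi],
           panel_size = tb$panel_size),
    tibble(axis = "longitude", true = geo$longitude[gi],
           predicted = tb$pred_longitude, population = geo$population[gi],
           panel_size = tb$panel_size))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$predicted,
                                     colour = .data$population)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_grid(ggplot2::vars(.data$axis),
                        ggplot2::vars(.data$panel_size), scales = "free") +
    ggplot2::labs(x = "true (degrees)", y = "predicted (degrees)",
                  title = "Leave-one-out predicted vs true coordinates")
}
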