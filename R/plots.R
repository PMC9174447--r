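# ggplot2 methods for the result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.kde_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$density,
                                       colour = .data$set)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(
      x = "property value", y = "density",
      colour = NULL,
      subtitle = sprintf("Gaussian KDE, train-tuned bandwidth %.3g",
                         attr(object, "bandwidth"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hist2d <- function(object, ...) {
  xc <- (object$x_edges[-1] + object$x_edges[-length(object$x_edges)]) / 2
  yc <- (object$y_edges[-1] + object$y_edges[-length(object$y_edges)]) / 2
  df <- expand.grid(x = xc, y = yc)
  df$count <- as.vector(object$counts)
  ggplot2::ggplot(df[df$count > 0, ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = object$prop_x, y = object$prop_y, fill = "count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.distribution_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$distances, c("w_model", "w_oracle"),
                           names_to = "which", values_to = "distance")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$property, y = .data$distance,
                                  fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(w_model = "#377eb8", w_oracle = "#999999"),
      labels = c(w_model = "model", w_oracle = "train oracle")) +
    ggplot2::labs(x = NULL, y = "Wasserstein distance", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trained_lm <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d, c("train_nll", "heldout_nll"),
                           names_to = "set", values_to = "nll")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$nll,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "epoch", y = "mean NLL per token", colour = NULL) +
    ggplot2::theme_minimal()
}
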