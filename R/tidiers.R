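## broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Weibull fit
#'
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`alpha`, `a0`).
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "a0"), estimate = c(x$alpha, x$a0))
}

#' @rdname tidy.weibull_fit
#' @return `glance`: one-row tibble with `alpha`, `a0`, `r_squared`, `n`,
#'   `plotting_position`.
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, a0 = x$a0, r_squared = x$r_squared,
                 n = x$n, plotting_position = x$plotting_position)
}

#' Weibull probability plot
#'
#' Linearized probability plot (`ln a` vs `ln(-ln(1-P))`) with the fitted
#' line; straightness indicates how well the two-parameter model describes
#' the measured lengths.
#'
#' @param object A `weibull_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.weibull_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$alpha,
                         intercept = -object$alpha * log(object$a0),
                         colour = "firebrick") +
    ggplot2::labs(x = "ln(length)", y = "ln(-ln(1 - P))",
                  title = sprintf("Weibull probability plot (alpha = %.2f, a0 = %.2f)",
                                  object$alpha, object$a0)) +
    ggplot2::theme_minimal()
}

#' Tidy the classifier training log
#'
#' @param x A `microfract_cnn`.
#' @param ... Unused.
#' @return `tidy`: the per-epoch log tibble. `glance`: a one-row summary.
#' @export
tidy.microfract_cnn <- function(x, ...) x$log

#' @rdname tidy.microfract_cnn
#' @export
glance.microfract_cnn <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log), final_loss = last$loss,
                 train_accuracy = last$train_accuracy,
                 val_accuracy = last$val_accuracy)
}

#' Training-history plot for the classifier
#'
#' @param object A `microfract_cnn`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy per epoch.
#' @export
autoplot.microfract_cnn <- function(object, ...) {
  lg <- object$log
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = lg$epoch, value = lg$loss, what = "loss"),
    tibble::tibble(epoch = lg$epoch, value = lg$train_accuracy,
                   what = "train accuracy"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Classifier training history") +
    ggplot2::theme_minimal()
}

#' Plot a slice with detected regions overlaid
#'
#' @param image Intensity matrix.
#' @param records Metrics tibble for that slice (used for centroid labels);
#'   optional.
#' @param mask Optional fracture mask drawn over the image.
#' @return A ggplot raster with detected microfractures highlighted.
#' @export
plot_slice_detections <- function(image, records = NULL, mask = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    intensity = as.vector(image))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(mask) && any(mask)) {
    md <- df[as.vector(mask), ]
    p <- p + ggplot2::geom_raster(data = md, fill = "red", alpha = 0.6)
  }
  p
}

#' @importFrom rlang .data
NULL
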