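# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.seg_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = epoch, y = loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = "Segmentation training loss") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.experiment_report <- function(object, ...) {
  ggplot2::ggplot(object$per_case,
                  ggplot2::aes(x = case, y = dice, fill = size_class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Dice",
                  title = sprintf("%s / %s (mean Dice %.3f)",
                                  object$strategy, object$scheme,
                                  object$mean_dice)) +
    ggplot2::theme_minimal()
}

#' Plot the Dice size-bias curve
#'
#' @param sizes Square sides passed to [dice_offset_study()].
#' @param offset Fixed shift in pixels.
#' @return A ggplot object.
#' @export
plot_dice_offset <- function(sizes = 3:20, offset = 1L) {
  df <- dice_offset_study(sizes, offset)
  ggplot2::ggplot(df, ggplot2::aes(x = size, y = dice)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "square side (pixels)", y = "Dice",
                  title = sprintf("Dice under a fixed %d-pixel offset",
                                  offset)) +
    ggplot2::theme_minimal()
}
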