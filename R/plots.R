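# ggplot2 display of matching functions and model comparisons, in the usual
# layout of the matching literature: log-spaced abscissa for the test "A"
# contrast, matching contrast on the ordinate, a horizontal dashed line at the
# B pedestal and a unit-slope oblique (pse = A) as the two max-regimen
# reference lines.

# A = 0 cannot sit on a log axis; display it half an octave below the
# smallest positive level
.plot_abscissa <- function(A) {
  pos <- A[A > 0]
  ifelse(A > 0, A, if (length(pos)) min(pos) / sqrt(2) else 1)
}

#' Plot a matching curve table
#'
#' @param object A `matching_curve` tibble from [matching_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot matching_curve
#' @export
autoplot.matching_curve <- function(object, ...) {
  df <- as_tibble(object)
  df$A_plot <- .plot_abscissa(df$A)
  df$pipeline <- paste0(df$model, " (", df$granularity,
                        ifelse(df$filtered, ", filtered", ""), ")")
  B0 <- df$B[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$A_plot, y = .data$pse,
                                   colour = .data$pipeline)) +
    ggplot2::geom_hline(yintercept = B0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$A_plot), linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(ggplot2::vars(.data$j), ggplot2::vars(.data$match_mode),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "test 'A' contrast (%)", y = "matching contrast (%)",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Overlays each model's predicted matching function on the reference PSEs.
#'
#' @param object A `model_comparison` from [compare_models()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  tb <- object$table
  tb$A_plot <- .plot_abscissa(tb$A)
  ref <- object$reference
  ref$A_plot <- .plot_abscissa(ref$A)
  B0 <- ref$B[1]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$A_plot)) +
    ggplot2::geom_hline(yintercept = B0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$A_plot), linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pse_pred, colour = .data$model)) +
    ggplot2::geom_point(data = ref, ggplot2::aes(y = .data$pse),
                        shape = 21, fill = "white", size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(ggplot2::vars(.data$j), ggplot2::vars(.data$match_mode),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "test 'A' contrast (%)", y = "matching contrast (%)",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Display a stimulus image
#'
#' @param object A `luminance_image`.
#' @param ... Ignored.
#' @return A ggplot raster of the stimulus (mean luminance at mid-grey).
#' @method autoplot luminance_image
#' @export
autoplot.luminance_image <- function(object, ...) {
  px <- object$pixels / object$mean_luminance / 2   # 0..1
  df <- tidyr::expand_grid(y = seq_len(nrow(px)), x = seq_len(ncol(px)))
  df$value <- as.vector(t(px))   # row-major to match (y, x) order
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
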