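#' Plot a mask with measured diameters
#'
#' Raster view of a binary mask; when morphometry records are supplied the
#' maximum-Feret-diameter segments are overlaid.
#'
#' @param mask A logical mask matrix.
#' @param records Optional records from [measure_mask()] for this mask.
#' @return A ggplot object.
#' @export
plot_mask <- function(mask, records = NULL) {
  mask <- as_mask(mask)
  df <- tidyr::expand_grid(row = seq_len(nrow(mask)), col = seq_len(ncol(mask)))
  df$fg <- as.vector(t(mask))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fg), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey15", `TRUE` = "grey85")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (!is.null(records) && nrow(records)) {
    p <- p + ggplot2::geom_segment(
      data = records,
      ggplot2::aes(x = .data$end1_col, y = .data$end1_row,
                   xend = .data$end2_col, yend = .data$end2_row),
      colour = "red", linewidth = 0.6
    )
  }
  p
}

#' @rdname fit_linear
#' @param object A `calibration_model`.
#' @export
autoplot.calibration_model <- function(object, ...) {
  if (is.null(object$data)) abort("model carries no fitting data to plot")
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = object$x_units, y = object$y_units,
      title = sprintf("y = %.4g x %s %.4g   (R² = %.4f, n = %d)",
                      object$slope, ifelse(object$intercept < 0, "-", "+"),
                      abs(object$intercept), object$r_squared, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname fit_time_constant
#' @param object A `time_constant_fit`.
#' @export
autoplot.time_constant_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df[df$used, ],
                  ggplot2::aes(x = .data$neg_log_theta, y = .data$time_s)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$tau_s, intercept = 0,
                         colour = "firebrick") +
    ggplot2::labs(x = expression(-ln~theta), y = "cooling time (s)",
                  title = sprintf("tau = %.4g s  (R² = %.4f)",
                                  object$tau_s, object$r2)) +
    ggplot2::theme_minimal()
}

#' @rdname fit_exponential_decay
#' @param object A `decay_fit`.
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble(time = seq(min(df$time), max(df$time), length.out = 200))
  grid$value <- object$baseline +
    (df$value[which.min(df$time)] - object$baseline) *
    exp(-(grid$time - min(df$time)) / object$tau)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "time", y = "signal",
                  title = sprintf("half-life = %.3g  (R² = %.4f)",
                                  object$half_life, object$r2)) +
    ggplot2::theme_minimal()
}
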