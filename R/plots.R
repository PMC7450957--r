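#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, difference = object$differences)
  ylab <- if (object$mode == "percent") {
    "difference / pair mean"
  } else {
    expression(difference ~ (mm^2))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = expression(pair ~ mean ~ (mm^2)), y = ylab,
      title = sprintf("Bland-Altman: bias %.3g, LoA [%.3g, %.3g], n = %d",
                      object$bias, object$loa_low, object$loa_high,
                      object$n_pairs)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lin_ccc <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  fit <- stats::lm(y ~ x, data = df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(
      slope = stats::coef(fit)[2], intercept = stats::coef(fit)[1],
      colour = "steelblue"
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = expression(method ~ A ~ (mm^2)), y = expression(method ~ B ~ (mm^2)),
      title = sprintf("Concordance: CCC %.3f (r = %.3f), n = %d",
                      object$ccc, object$pearson, object$n_pairs)
    ) +
    ggplot2::theme_minimal()
}

#' Display a scan, class map or mask
#'
#' Quick ggplot2 rasters for visual inspection of synthetic scans and
#' segmentation output.
#'
#' @param image A [scan_image()].
#' @param map An integer class map or logical mask.
#' @return A ggplot.
#' @export
plot_scan <- function(image) {
  stopifnot(inherits(image, "scan_image"))
  d <- dim(image)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(
    as.vector(image$pixels[, , 1]) / 255,
    as.vector(image$pixels[, , 2]) / 255,
    as.vector(image$pixels[, , 3]) / 255
  )[(df$col - 1L) * d[1] + df$row]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @rdname plot_scan
#' @export
plot_class_map <- function(map) {
  if (is.logical(map)) map <- map * CLASS_DAMAGED
  d <- dim(map)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$class <- factor(
    CLASS_LEVELS[as.vector(map)[(df$col - 1L) * d[1] + df$row] + 1L],
    levels = CLASS_LEVELS
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(background = "grey90", healthy = "forestgreen",
                 damaged = "red3", confounder = "orange"),
      drop = FALSE
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
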