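#' Plot a spine annotation
#'
#' Draws the 17 vertebral quadrilaterals, their centres and (optionally)
#' the interpolated vertebral lines in image coordinates (y axis reversed
#' so superior is up).
#'
#' @param object A [spine_annotation()].
#' @param lines Optional `vertebral_lines` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spine_annotation <- function(object, lines = NULL, ...) {
  quads <- object |>
    dplyr::mutate(ord = c(1L, 2L, 4L, 3L)[.data$corner]) |>
    dplyr::arrange(.data$vertebra, .data$ord)
  ctr <- spine_centers(object)
  p <- ggplot2::ggplot(quads, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$vertebra),
                          fill = "grey85", colour = "grey30",
                          linewidth = 0.3) +
    ggplot2::geom_point(data = ctr, size = 0.8, colour = "firebrick") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(lines)) {
    ldf <- dplyr::bind_rows(lapply(names(lines), function(s) {
      dplyr::mutate(lines[[s]], side = s)
    }))
    p <- p + ggplot2::geom_path(
      data = ldf, ggplot2::aes(colour = .data$side), linewidth = 0.4)
  }
  p
}

#' Plot a simulated case
#'
#' Pseudo-radiograph as a raster with the annotation overlaid.
#'
#' @param object A `simulated_case` from [generate_case()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simulated_case <- function(object, ...) {
  ann <- object$annotation
  p <- autoplot.spine_annotation(ann)
  if (!is.null(object$image)) {
    img <- object$image
    df <- tibble::tibble(
      x = rep(0:(ncol(img) - 1L), each = nrow(img)),
      y = rep(0:(nrow(img) - 1L), times = ncol(img)),
      value = as.vector(img)
    )
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none") +
      ggplot2::geom_polygon(
        data = ann |>
          dplyr::mutate(ord = c(1L, 2L, 4L, 3L)[.data$corner]) |>
          dplyr::arrange(.data$vertebra, .data$ord),
        ggplot2::aes(group = .data$vertebra),
        fill = NA, colour = "yellow", linewidth = 0.25) +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = "x (px)", y = "y (px)") +
      ggplot2::theme_minimal()
  }
  p
}

#' Plot a training loss trace
#'
#' @param object A `vldet_fit` from [train_toy()].
#' @param ... Unused.
#' @return A ggplot object (log-scale total loss by step).
#' @export
autoplot.vldet_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$step, y = .data$total)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step", y = "total loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
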