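#' Display a candled image or ROI with ggplot2
#'
#' @param object A `candled_image` or `roi_pair`.
#' @param channel For images: `"rgb"` composite or a single channel name.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.candled_image <- function(object, channel = "rgb", ...) {
  h <- nrow(object$red); w <- ncol(object$red)
  df <- tibble::tibble(
    x = rep(seq_len(w), each = h), y = rep(seq_len(h), times = w),
    fill = if (channel == "rgb") {
      grDevices::rgb(object$red / 255, object$green / 255, object$blue / 255)
    } else {
      v <- object[[channel]] / 255
      grDevices::gray(as.numeric(v))
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$fill)) +
    ggplot2::geom_raster() + ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @rdname autoplot.candled_image
#' @export
autoplot.roi_pair <- function(object, ...) {
  h <- nrow(object$roi); w <- ncol(object$roi)
  df <- tibble::tibble(x = rep(seq_len(w), each = h),
                       y = rep(seq_len(h), times = w),
                       value = as.numeric(object$roi))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void() + ggplot2::labs(fill = "intensity")
}

#' Plot a boundary and its truncated reconstructions
#'
#' Overlays the original contour with reconstructions from increasing
#' numbers of low-frequency Fourier descriptors, showing how few
#' harmonics suffice to recover the yolk outline.
#'
#' @param contour An `egg_contour`.
#' @param n_values Numbers of retained coefficients to show.
#' @return A ggplot object, faceted by `n`.
#' @export
plot_reconstructions <- function(contour, n_values = c(4, 8, 16)) {
  xy <- as_contour(contour)
  ds <- fourier_descriptors(xy)
  orig <- tibble::tibble(x = xy[, 1], y = xy[, 2], which = "original")
  rec <- purrr::map_dfr(n_values, function(n) {
    r <- reconstruct_boundary(ds, n)
    tibble::tibble(x = r[, 1], y = r[, 2], which = "reconstruction",
                   n = n)
  })
  orig_rep <- tidyr::crossing(orig, n = n_values)
  ggplot2::ggplot(dplyr::bind_rows(orig_rep, rec),
                  ggplot2::aes(.data$x, .data$y, colour = .data$which)) +
    ggplot2::geom_path() + ggplot2::facet_wrap(~n, labeller = "label_both") +
    ggplot2::coord_fixed() + ggplot2::scale_y_reverse() +
    ggplot2::theme_minimal() + ggplot2::labs(colour = NULL)
}

#' Plot a reconstruction-error curve
#'
#' @param curve A tibble from [error_curve()] (columns `n`, `epsilon`),
#'   optionally with a grouping column `group`.
#' @return A ggplot object.
#' @export
plot_error_curve <- function(curve) {
  aes <- if ("group" %in% names(curve)) {
    ggplot2::aes(.data$n, .data$epsilon, group = .data$group,
                 colour = .data$group)
  } else {
    ggplot2::aes(.data$n, .data$epsilon)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of Fourier descriptors",
                  y = "reconstruction error (px)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.candled_image
#' @export
autoplot.fld_cv <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(.data$pred, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey25", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "truth") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.candled_image
#' @export
autoplot.cnn <- function(object, ...) {
  if (is.null(object$log)) abort("the network has no training log yet")
  df <- tidyr::pivot_longer(object$log, c("loss", "train_acc"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
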