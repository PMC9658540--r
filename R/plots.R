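#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot class-aware weight against instance share
#'
#' Shows the multiplying term `(1 - q)/(1 - q^eta)` over the instance
#' share `q = ns/n`, one curve per `eta`. Dominant classes (q near 1)
#' are pushed toward `1/eta`.
#'
#' @param eta Numeric vector of exponents to draw; default `c(1, 2, 4, 8)`.
#' @return A ggplot.
#' @export
plot_weight_curve <- function(eta = c(1, 2, 4, 8)) {
  q <- seq(0.001, 0.999, length.out = 400)
  df <- purrr::map_dfr(eta, function(e) {
    tibble::tibble(q = q, eta = factor(e),
                   weight = class_aware_weight(round(q * 1e6), 1e6, e))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$weight,
                                   colour = .data$eta)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "instance share  q = ns / n",
                  y = "class-aware weight", colour = expression(eta)) +
    ggplot2::theme_minimal()
}

#' Plot a species census as a rank-frequency bar chart
#'
#' @param census A [class_census()].
#' @param log_y Log-scale the count axis; default TRUE (long tails).
#' @return A ggplot.
#' @export
plot_census <- function(census, log_y = TRUE) {
  df <- tibble::tibble(species = factor(census$species,
                                        levels = census$species[order(-census$count)]),
                       count = census$count)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "training instances") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a rendered scene with its annotation boxes
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param boxes Tibble of normalized center-form boxes with `class`.
#' @return A ggplot.
#' @export
plot_scene <- function(image, boxes) {
  b <- if (nrow(boxes) > 0) center_to_corner(boxes) else boxes
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(image, xmin = 0, xmax = 1, ymin = 0, ymax = 1) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
  if (nrow(boxes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = b,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   colour = .data$class),
      fill = NA, linewidth = 0.4)
  }
  p
}

#' @rdname autoplot-ltdetect
#' @method autoplot ssd_detector
#' @export
autoplot.ssd_detector <- function(object, ...) {
  log <- tidy(object)
  df <- tidyr::pivot_longer(log, c("total", "classification", "localization"),
                            names_to = "part", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$part)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for ltdetect result objects
#'
#' `ssd_detector`: per-epoch training-loss curves. `detection_eval`:
#' per-class AP bars. `scheme_comparison`: per-class AP bars grouped by
#' scheme.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-ltdetect
#' @method autoplot detection_eval
#' @export
autoplot.detection_eval <- function(object, ...) {
  df <- object$per_class[!is.na(object$per_class$ap), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$ap)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$map, linetype = 2) +
    ggplot2::labs(x = NULL, y = sprintf("AP @ IoU %.2f", object$iou_threshold)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ltdetect
#' @method autoplot scheme_comparison
#' @export
autoplot.scheme_comparison <- function(object, ...) {
  df <- object$per_class[!is.na(object$per_class$ap), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$ap,
                                   fill = .data$scheme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "AP") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
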