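#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained detector into its per-epoch training log
#'
#' @param x An `ssd_detector`.
#' @param ... Unused.
#' @return A tibble: `epoch`, `total`, `classification`, `localization`,
#'   `lr`.
#' @method tidy ssd_detector
#' @export
tidy.ssd_detector <- function(x, ...) {
  if (is.null(x$log)) {
    return(tibble::tibble(epoch = integer(), total = numeric(),
                          classification = numeric(), localization = numeric(),
                          lr = numeric()))
  }
  x$log
}

#' One-row summary of a trained detector
#'
#' @inheritParams tidy.ssd_detector
#' @return A tibble: `n_params`, `n_classes`, `n_defaults`, `scheme`,
#'   `epochs`, `final_loss`.
#' @method glance ssd_detector
#' @export
glance.ssd_detector <- function(x, ...) {
  tibble::tibble(
    n_params = n_params(x),
    n_classes = length(x$classes),
    n_defaults = nrow(x$grid),
    scheme = if (is.null(x$loss_cfg)) NA_character_ else x$loss_cfg$reweight$scheme,
    epochs = if (is.null(x$log)) 0L else max(x$log$epoch),
    final_loss = if (is.null(x$log)) NA_real_ else x$log$total[nrow(x$log)]
  )
}

#' Tidy an evaluation into its per-class AP table
#'
#' @param x A `detection_eval`.
#' @param ... Unused.
#' @return A tibble: `class`, `ap`, `n_gt`, `n_det`.
#' @method tidy detection_eval
#' @export
tidy.detection_eval <- function(x, ...) x$per_class

#' One-row summary of an evaluation
#'
#' @inheritParams tidy.detection_eval
#' @return A tibble: `map`, `iou_threshold`, `interpolation`,
#'   `n_classes`.
#' @method glance detection_eval
#' @export
glance.detection_eval <- function(x, ...) {
  tibble::tibble(map = x$map, iou_threshold = x$iou_threshold,
                 interpolation = x$interpolation,
                 n_classes = sum(!is.na(x$per_class$ap)))
}

#' Tidy a scheme comparison into the long per-class AP table
#'
#' @param x A `scheme_comparison`.
#' @param ... Unused.
#' @return A tibble: `scheme`, `class`, `ap`, `n_gt`, `n_det`.
#' @method tidy scheme_comparison
#' @export
tidy.scheme_comparison <- function(x, ...) x$per_class

#' Per-scheme summary of a comparison
#'
#' @inheritParams tidy.scheme_comparison
#' @return A tibble: `scheme`, `map`, `rare_map`, `rare_classes`.
#' @method glance scheme_comparison
#' @export
glance.scheme_comparison <- function(x, ...) {
  dplyr::left_join(x$summary, rare_class_map(x$per_class, x$census),
                   by = "scheme")
}
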