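#' Greedy non-maximum suppression
#'
#' Applied independently within each `(image_id, class)` group when
#' those columns are present. Detections are visited in descending
#' score order (ties broken by lower original row index); a detection is
#' kept unless its IoU with an already-kept detection *exceeds* the
#' threshold.
#'
#' @param detections A tibble of center-form boxes with a `score`
#'   column, optionally `image_id` and `class` columns.
#' @param iou_threshold Suppression threshold in `(0, 1]`. At 1 every
#'   detection survives (IoU cannot exceed 1).
#' @return The kept subset of `detections`, original order preserved.
#' @export
nms <- function(detections, iou_threshold = 0.45) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  if (nrow(detections) == 0) return(detections)
  grp <- interaction(
    if ("image_id" %in% names(detections)) detections$image_id else 0,
    if ("class" %in% names(detections)) detections$class else 0,
    drop = TRUE
  )
  xmin <- detections$cx - detections$w / 2; xmax <- detections$cx + detections$w / 2
  ymin <- detections$cy - detections$h / 2; ymax <- detections$cy + detections$h / 2
  area <- (xmax - xmin) * (ymax - ymin)
  keep <- logical(nrow(detections))
  for (g in levels(grp)) {
    ix <- which(grp == g)
    ord <- ix[order(-detections$score[ix], ix)]
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) > 0) {
        iw <- pmax(pmin(xmax[kept], xmax[i]) - pmax(xmin[kept], xmin[i]), 0)
        ih <- pmax(pmin(ymax[kept], ymax[i]) - pmax(ymin[kept], ymin[i]), 0)
        inter <- iw * ih
        un <- area[kept] + area[i] - inter
        if (any(un > 0 & inter / pmax(un, 1e-12) > iou_threshold)) next
      }
      kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  detections[keep, , drop = FALSE]
}

# score-ordered TP/FP flags for one class (VOC protocol); plain-vector
# geometry so the greedy loop stays cheap at thousands of detections
ap_flags <- function(det, gt, iou_threshold) {
  ord <- order(-det$score, seq_len(nrow(det)))
  dx0 <- det$cx - det$w / 2; dx1 <- det$cx + det$w / 2
  dy0 <- det$cy - det$h / 2; dy1 <- det$cy + det$h / 2
  gx0 <- gt$cx - gt$w / 2; gx1 <- gt$cx + gt$w / 2
  gy0 <- gt$cy - gt$h / 2; gy1 <- gt$cy + gt$h / 2
  d_area <- det$w * det$h; g_area <- gt$w * gt$h
  det_img <- det$image_id; gt_img <- gt$image_id
  taken <- rep(FALSE, nrow(gt))
  tp <- logical(nrow(det))
  for (r in seq_along(ord)) {
    i <- ord[r]
    cand <- which(!taken & gt_img == det_img[i])
    if (length(cand) == 0) next
    iw <- pmax(pmin(gx1[cand], dx1[i]) - pmax(gx0[cand], dx0[i]), 0)
    ih <- pmax(pmin(gy1[cand], dy1[i]) - pmax(gy0[cand], dy0[i]), 0)
    inter <- iw * ih
    un <- g_area[cand] + d_area[i] - inter
    ious <- ifelse(un > 0, inter / un, 0)
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[r] <- TRUE
      taken[cand[best]] <- TRUE
    }
  }
  tp
}

pr_area <- function(tp, n_gt, interpolation) {
  if (length(tp) == 0 || n_gt == 0) return(0)
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / n_gt
  if (interpolation == "11point") {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      ok <- rec >= r
      if (any(ok)) max(prec[ok]) else 0
    }, numeric(1)))
  } else {
    # all-point: area under the monotone (right-to-left max) envelope
    env <- rev(cummax(rev(prec)))
    r_prev <- c(0, rec[-length(rec)])
    sum((rec - r_prev) * env)
  }
}

#' Average precision for one class at a fixed IoU threshold
#'
#' Detections of the class are ranked by score; each matches at most one
#' still-unmatched ground truth in its image with IoU at or above the
#' threshold (highest-IoU candidate). A correct-class detection below
#' the IoU threshold is a false positive and does not consume the
#' ground truth. AP is the area under the monotone-interpolated
#' precision-recall curve (or the 11-point VOC2007 average).
#'
#' @param detections Tibble with `image_id`, `class`, `score` and box
#'   columns.
#' @param ground_truths Tibble with `image_id`, `class` and box columns.
#' @param class The class label to score.
#' @param iou_threshold True-positive criterion; default 0.5.
#' @param interpolation `"all_point"` (default) or `"11point"`.
#' @return AP in `[0, 1]`; `NA` if the class has no ground truths.
#' @export
average_precision <- function(detections, ground_truths, class,
                              iou_threshold = 0.5,
                              interpolation = c("all_point", "11point")) {
  interpolation <- match.arg(interpolation)
  gt <- ground_truths[ground_truths$class == class, , drop = FALSE]
  if (nrow(gt) == 0) return(NA_real_)
  det <- detections[detections$class == class, , drop = FALSE]
  if (nrow(det) == 0) return(0)
  tp <- ap_flags(det, gt, iou_threshold)
  pr_area(tp, nrow(gt), interpolation)
}

#' Mean average precision over evaluable classes
#'
#' The unweighted mean of per-class AP over classes with at least one
#' ground truth; classes without ground truths are excluded from the
#' mean, not scored 0 (mirroring how species absent from a test split
#' are dropped from reporting).
#'
#' @inheritParams average_precision
#' @param classes Classes to consider; defaults to all classes present
#'   in `ground_truths`.
#' @return An object of class `detection_eval`: a list with `per_class`
#'   (tibble `class, ap, n_gt, n_det`), `map`, `iou_threshold`,
#'   `interpolation`.
#' @export
mean_ap <- function(detections, ground_truths, classes = NULL,
                    iou_threshold = 0.5,
                    interpolation = c("all_point", "11point")) {
  interpolation <- match.arg(interpolation)
  if (is.null(classes)) classes <- sort(unique(ground_truths$class))
  if (length(classes) == 0) {
    rlang::abort("no evaluable classes: every class has zero ground truths.")
  }
  per <- purrr::map_dfr(classes, function(cl) {
    tibble::tibble(
      class = cl,
      ap = average_precision(detections, ground_truths, cl,
                             iou_threshold, interpolation),
      n_gt = sum(ground_truths$class == cl),
      n_det = sum(detections$class == cl)
    )
  })
  evaluable <- per[!is.na(per$ap), , drop = FALSE]
  if (nrow(evaluable) == 0) {
    rlang::abort("no evaluable classes: every class has zero ground truths.")
  }
  structure(list(per_class = per, map = mean(evaluable$ap),
                 iou_threshold = iou_threshold, interpolation = interpolation),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("<detection_eval> mAP = %.4f at IoU %.2f (%s interpolation, %d classes)\n",
              x$map, x$iou_threshold, x$interpolation,
              sum(!is.na(x$per_class$ap))))
  print(x$per_class)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `ap_report.csv` (`class,ap,n_gt,n_det`) and `summary.json`
#' (`map`, `iou_threshold`, `interpolation`).
#'
#' @param eval A [mean_ap()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(eval, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(eval$per_class, file.path(dir, "ap_report.csv"))
  jsonlite::write_json(
    list(map = eval$map, iou_threshold = eval$iou_threshold,
         interpolation = eval$interpolation),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
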