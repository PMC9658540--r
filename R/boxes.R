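#' Construct a tibble of normalized center-form boxes
#'
#' Boxes are kept internally in center form with coordinates normalized
#' to the image: `cx`, `cy` in `[0, 1]` and positive `w`, `h`. Pixel
#' corner coordinates (e.g. from VOC XML) are converted at the I/O
#' boundary by [read_voc_annotation()].
#'
#' @param cx,cy Box centers, normalized to image width/height.
#' @param w,h Box width/height, normalized; must be positive.
#' @param ... Further columns carried along (e.g. `class`, `score`).
#' @return A tibble with one row per box.
#' @export
boxes_tbl <- function(cx, cy, w, h, ...) {
  if (any(w <= 0) || any(h <= 0)) rlang::abort("box width/height must be positive.")
  if (any(cx < 0 | cx > 1) || any(cy < 0 | cy > 1)) {
    rlang::abort("box centers must lie in [0, 1].")
  }
  tibble::tibble(cx = as.numeric(cx), cy = as.numeric(cy),
                 w = as.numeric(w), h = as.numeric(h), ...)
}

#' Convert center-form boxes to corner form (and back)
#'
#' Corner form is `(xmin, ymin, xmax, ymax)` in the same normalized
#' units. The two conversions are exact inverses.
#'
#' @param boxes A tibble with `cx`, `cy`, `w`, `h` columns (for
#'   `center_to_corner`) or `xmin`, `ymin`, `xmax`, `ymax` columns (for
#'   `corner_to_center`).
#' @return A tibble with the converted columns, other columns preserved.
#' @export
center_to_corner <- function(boxes) {
  dplyr::mutate(boxes,
    xmin = .data$cx - .data$w / 2, ymin = .data$cy - .data$h / 2,
    xmax = .data$cx + .data$w / 2, ymax = .data$cy + .data$h / 2,
    .keep = "unused")
}

#' @rdname center_to_corner
#' @export
corner_to_center <- function(boxes) {
  dplyr::mutate(boxes,
    cx = (.data$xmin + .data$xmax) / 2, cy = (.data$ymin + .data$ymax) / 2,
    w = .data$xmax - .data$xmin, h = .data$ymax - .data$ymin,
    .keep = "unused")
}

#' Pairwise intersection-over-union between two box sets
#'
#' @param a,b Tibbles of center-form boxes ([boxes_tbl()]).
#' @return A `nrow(a) x nrow(b)` matrix of IoU values in `[0, 1]`.
#'   Degenerate (zero-area) overlaps give 0.
#' @examples
#' a <- boxes_tbl(0.5, 0.5, 1, 1)
#' b <- boxes_tbl(1, 0.5, 1, 1)   # corner form (0.5,0,1.5,1), clipped centers aside
#' @export
box_iou <- function(a, b) {
  ac <- center_to_corner(a); bc <- center_to_corner(b)
  iw <- pmax(outer(ac$xmax, bc$xmax, pmin) - outer(ac$xmin, bc$xmin, pmax), 0)
  ih <- pmax(outer(ac$ymax, bc$ymax, pmin) - outer(ac$ymin, bc$ymin, pmax), 0)
  inter <- iw * ih
  area_a <- (ac$xmax - ac$xmin) * (ac$ymax - ac$ymin)
  area_b <- (bc$xmax - bc$xmin) * (bc$ymax - bc$ymin)
  un <- outer(area_a, area_b, `+`) - inter
  iou <- ifelse(un > 0, inter / un, 0)
  matrix(iou, nrow = nrow(a), ncol = nrow(b))
}

#' Specification of a multi-scale default-box lattice
#'
#' Each feature map contributes `size^2` locations; every location emits
#' 4 default boxes: the base scale at aspect ratios 1, 2 and 1/2, plus a
#' fourth square box at the geometric-mean "bump" scale
#' `sqrt(scale * next_scale)`. Defaults suit small (96 px) synthetic
#' scenes with a 3-map pyramid.
#'
#' @param feature_map_sizes Integer grid resolutions, one per map.
#' @param scales Base scale per map, in `(0, 1]`.
#' @param next_scales Scale used for the fourth (bump) box; defaults to
#'   the next map's scale, with 0.85 after the last map.
#' @param aspect_ratios The three base aspect ratios; default `c(1, 2, 0.5)`.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(feature_map_sizes = c(12, 6, 3),
                      scales = c(0.12, 0.3, 0.55),
                      next_scales = c(scales[-1], 0.85),
                      aspect_ratios = c(1, 2, 0.5)) {
  if (length(feature_map_sizes) < 1) rlang::abort("need at least one feature map.")
  stopifnot(length(scales) == length(feature_map_sizes),
            length(next_scales) == length(feature_map_sizes),
            length(aspect_ratios) == 3,
            all(scales > 0), all(scales <= 1))
  structure(list(feature_map_sizes = as.integer(feature_map_sizes),
                 scales = scales, next_scales = next_scales,
                 aspect_ratios = aspect_ratios),
            class = "grid_spec")
}

#' Generate the default-box (anchor) lattice
#'
#' Deterministic ordering: map, then row, then column, then ratio slot
#' (base 1, 2, 1/2, then the bump-scale square). Centers sit at
#' `((col + 0.5)/size, (row + 0.5)/size)`; boxes are clipped to the unit
#' square in corner form.
#'
#' @param spec A [grid_spec()].
#' @return A tibble of class `default_box_grid` with box columns plus
#'   `map`, `row`, `col`, `slot`; the spec is attached as an attribute.
#' @export
default_box_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  per_map <- purrr::map(seq_along(spec$feature_map_sizes), function(m) {
    size <- spec$feature_map_sizes[m]
    s <- spec$scales[m]
    s_bump <- sqrt(s * spec$next_scales[m])
    # 4 (w, h) pairs per location
    wh <- rbind(
      c(s, s),
      c(s * sqrt(spec$aspect_ratios[2]), s / sqrt(spec$aspect_ratios[2])),
      c(s * sqrt(spec$aspect_ratios[3]), s / sqrt(spec$aspect_ratios[3])),
      c(s_bump, s_bump)
    )
    cells <- expand.grid(slot = 1:4, col = seq_len(size) - 1, row = seq_len(size) - 1)
    cells <- cells[order(cells$row, cells$col, cells$slot), ]
    tibble::tibble(
      cx = (cells$col + 0.5) / size,
      cy = (cells$row + 0.5) / size,
      w = wh[cells$slot, 1],
      h = wh[cells$slot, 2],
      map = m, row = cells$row, col = cells$col, slot = cells$slot
    )
  })
  grid <- dplyr::bind_rows(per_map)
  # clip to the unit square in corner form, then return to center form
  grid <- center_to_corner(grid)
  grid$xmin <- pmax(grid$xmin, 0); grid$ymin <- pmax(grid$ymin, 0)
  grid$xmax <- pmin(grid$xmax, 1); grid$ymax <- pmin(grid$ymax, 1)
  grid <- corner_to_center(grid)
  grid <- grid[, c("cx", "cy", "w", "h", "map", "row", "col", "slot")]
  attr(grid, "spec") <- spec
  class(grid) <- c("default_box_grid", class(grid))
  grid
}

#' Encode a ground-truth box against a default box as regression offsets
#'
#' The default `variant = "plain"` encoding is
#' `(g.cx - d.cx, g.cy - d.cy, log(g.w/d.w), log(g.h/d.h))`.
#' `variant = "ssd_standard"` divides the center offsets by the default
#' box's width/height, the convention used by most SSD implementations;
#' it can improve training stability and is recorded in run metadata.
#'
#' @param g,d Tibbles of center-form boxes, row-aligned (recycled if one
#'   has a single row).
#' @param variant `"plain"` (default) or `"ssd_standard"`.
#' @return A tibble with columns `t_cx`, `t_cy`, `t_w`, `t_h`.
#' @export
encode_boxes <- function(g, d, variant = c("plain", "ssd_standard")) {
  variant <- match.arg(variant)
  if (any(g$w <= 0) || any(g$h <= 0)) rlang::abort("ground-truth width/height must be positive.")
  if (variant == "plain") {
    tibble::tibble(t_cx = g$cx - d$cx, t_cy = g$cy - d$cy,
                   t_w = log(g$w / d$w), t_h = log(g$h / d$h))
  } else {
    tibble::tibble(t_cx = (g$cx - d$cx) / d$w, t_cy = (g$cy - d$cy) / d$h,
                   t_w = log(g$w / d$w), t_h = log(g$h / d$h))
  }
}

#' Decode regression offsets against default boxes
#'
#' Exact algebraic inverse of [encode_boxes()] under the same variant.
#'
#' @param offsets A tibble with `t_cx`, `t_cy`, `t_w`, `t_h` columns.
#' @param d Default boxes, row-aligned with `offsets`.
#' @inheritParams encode_boxes
#' @return A tibble of center-form boxes.
#' @export
decode_boxes <- function(offsets, d, variant = c("plain", "ssd_standard")) {
  variant <- match.arg(variant)
  if (variant == "plain") {
    tibble::tibble(cx = offsets$t_cx + d$cx, cy = offsets$t_cy + d$cy,
                   w = exp(offsets$t_w) * d$w, h = exp(offsets$t_h) * d$h)
  } else {
    tibble::tibble(cx = offsets$t_cx * d$w + d$cx, cy = offsets$t_cy * d$h + d$cy,
                   w = exp(offsets$t_w) * d$w, h = exp(offsets$t_h) * d$h)
  }
}

#' Match ground-truth boxes to a default-box grid
#'
#' Two-stage SSD-style assignment. First, every ground truth claims its
#' best-IoU default (guaranteed even below the threshold; among defaults
#' not yet claimed, ties broken by lowest default index). Second, every
#' remaining default whose best IoU to any ground truth reaches
#' `iou_threshold` is assigned to its argmax ground truth (ties to the
#' lowest ground-truth index). All other defaults are background.
#'
#' @param gt A tibble of ground truths: box columns plus `class`.
#' @param grid A [default_box_grid()].
#' @param iou_threshold Matching threshold in `(0, 1)`; default 0.5, the
#'   conventional true-positive criterion.
#' @param encoding Offset-encoding variant passed to [encode_boxes()].
#' @return A tibble of class `match_result`, one row per default box:
#'   `default_ix`, `gt_ix` (NA for background), `class` ("background"
#'   for negatives), encoded targets `t_cx`..`t_h` (NA for background).
#'   `attr(, "n_matched")` holds N, the matched-default count.
#' @export
match_boxes <- function(gt, grid, iou_threshold = 0.5,
                        encoding = c("plain", "ssd_standard")) {
  encoding <- match.arg(encoding)
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  D <- nrow(grid)
  out <- tibble::tibble(
    default_ix = seq_len(D), gt_ix = NA_integer_,
    class = "background",
    t_cx = NA_real_, t_cy = NA_real_, t_w = NA_real_, t_h = NA_real_
  )
  G <- if (is.null(gt)) 0L else nrow(gt)
  if (G > 0) {
    iou <- box_iou(grid, gt)  # D x G
    assigned <- rep(NA_integer_, D)
    # stage 1: best default per ground truth (forced, regardless of threshold)
    claimed <- rep(FALSE, D)
    for (j in seq_len(G)) {
      col <- iou[, j]
      col[claimed] <- -1
      best <- which.max(col)   # lowest index wins ties
      assigned[best] <- j
      claimed[best] <- TRUE
    }
    # stage 2: thresholded argmax for the rest
    free <- which(!claimed)
    if (length(free) > 0) {
      sub <- iou[free, , drop = FALSE]
      best_j <- max.col(sub, ties.method = "first")
      best_v <- sub[cbind(seq_along(free), best_j)]
      ok <- best_v >= iou_threshold
      assigned[free[ok]] <- best_j[ok]
    }
    pos <- which(!is.na(assigned))
    if (length(pos) > 0) {
      j <- assigned[pos]
      out$gt_ix[pos] <- j
      out$class[pos] <- as.character(gt$class[j])
      enc <- encode_boxes(gt[j, , drop = FALSE], grid[pos, , drop = FALSE],
                          variant = encoding)
      out$t_cx[pos] <- enc$t_cx; out$t_cy[pos] <- enc$t_cy
      out$t_w[pos] <- enc$t_w;  out$t_h[pos] <- enc$t_h
    }
  }
  attr(out, "n_matched") <- sum(!is.na(out$gt_ix))
  attr(out, "encoding") <- encoding
  class(out) <- c("match_result", class(out))
  out
}

#' Number of matched default boxes in a match result
#'
#' @param match A [match_boxes()] result.
#' @return Integer N, the multibox-loss normalizer.
#' @export
n_matched <- function(match) {
  as.integer(attr(match, "n_matched"))
}
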