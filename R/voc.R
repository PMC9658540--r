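#' Read a Pascal VOC XML annotation file
#'
#' Parses `<annotation><size>` and every `<object>` record. VOC pixel
#' corners are 1-based inclusive; they are converted to normalized
#' center-form coordinates via `xmin_norm = (xmin - 1)/W`,
#' `xmax_norm = xmax/W` (likewise for y), so a box spanning the full
#' image maps to `[0, 1]`. Optional fields (`pose`, `truncated`,
#' `difficult`) are tolerated and ignored.
#'
#' @param path Path to the XML file.
#' @return A tibble with one row per object: `class`, `cx`, `cy`, `w`,
#'   `h`; the pixel `width`/`height` of the image are attached as
#'   attributes `image_width` / `image_height`.
#' @export
read_voc_annotation <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    rlang::abort(paste0("malformed VOC XML in '", path, "': ", conditionMessage(e)))
  })
  W <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
  H <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
  if (!is.finite(W) || !is.finite(H) || W < 1 || H < 1) {
    rlang::abort(paste0("missing or invalid <size> in '", path, "'."))
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  grab <- function(node, field) {
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, paste0(".//bndbox/", field))))
  }
  rows <- purrr::map(objs, function(o) {
    cls <- xml2::xml_text(xml2::xml_find_first(o, ".//name"))
    xmin <- grab(o, "xmin"); ymin <- grab(o, "ymin")
    xmax <- grab(o, "xmax"); ymax <- grab(o, "ymax")
    if (any(!is.finite(c(xmin, ymin, xmax, ymax)))) {
      rlang::abort(paste0("non-numeric bndbox in '", path, "'."))
    }
    if (xmin > xmax || ymin > ymax) {
      rlang::abort(paste0("inverted bndbox (min > max) in '", path, "'."))
    }
    if (xmin < 1 || ymin < 1 || xmax > W || ymax > H) {
      rlang::abort(paste0("bndbox out of image bounds in '", path, "'."))
    }
    tibble::tibble(class = cls, xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  })
  px <- dplyr::bind_rows(rows)
  out <- if (nrow(px) == 0) {
    tibble::tibble(class = character(), cx = numeric(), cy = numeric(),
                   w = numeric(), h = numeric())
  } else {
    corner_to_center(tibble::tibble(
      class = px$class,
      xmin = (px$xmin - 1) / W, ymin = (px$ymin - 1) / H,
      xmax = px$xmax / W, ymax = px$ymax / H
    ))[, c("class", "cx", "cy", "w", "h")]
  }
  attr(out, "image_width") <- W
  attr(out, "image_height") <- H
  out
}

#' Write objects to a Pascal VOC XML annotation file
#'
#' Inverse of [read_voc_annotation()]: normalized center-form boxes are
#' converted back to 1-based inclusive pixel corners
#' (`xmin = round(xmin_norm * W) + 1`, `xmax = round(xmax_norm * W)`).
#' Round-trips losslessly for boxes that originated on the pixel grid.
#'
#' @param objects A tibble with `class`, `cx`, `cy`, `w`, `h`.
#' @param path Output XML path.
#' @param width,height Image size in pixels.
#' @param filename Value for the `<filename>` element.
#' @return `path`, invisibly.
#' @export
write_voc_annotation <- function(objects, path, width, height,
                                 filename = basename(path)) {
  corners <- if (nrow(objects) > 0) center_to_corner(objects) else objects
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(as.integer(width)))
  xml2::xml_add_child(size, "height", as.character(as.integer(height)))
  xml2::xml_add_child(size, "depth", "3")
  if (nrow(objects) > 0) {
    for (i in seq_len(nrow(objects))) {
      o <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(o, "name", objects$class[i])
      xml2::xml_add_child(o, "difficult", "0")
      bb <- xml2::xml_add_child(o, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(round(corners$xmin[i] * width) + 1))
      xml2::xml_add_child(bb, "ymin", as.character(round(corners$ymin[i] * height) + 1))
      xml2::xml_add_child(bb, "xmax", as.character(round(corners$xmax[i] * width)))
      xml2::xml_add_child(bb, "ymax", as.character(round(corners$ymax[i] * height)))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
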