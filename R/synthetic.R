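#' Specification of a synthetic long-tailed detection dataset
#'
#' The generator emulates the statistical structure of fishery survey
#' imagery: many species with Zipf-distributed instance counts, several
#' objects per image, and low foreground-background contrast. It does
#' not attempt photo-realism; each species has a fixed parametric
#' appearance (shape, hue, stripe texture) so that splits share
#' appearance and differ only by sampling.
#'
#' @param num_species Number of foreground species (>= 2); default 8.
#' @param zipf_exponent Rank-frequency decay exponent; expected counts
#'   are proportional to `rank^(-zipf_exponent)`. Default 1.5, a steep
#'   long tail.
#' @param image_size Square image side in pixels (>= 32); default 96.
#' @param objects_per_image Integer range `c(min, max)` of objects per
#'   scene; default `c(1, 4)`.
#' @param contrast Foreground-background color separation in `(0, 1]`;
#'   default 0.5 (objects visibly but not starkly distinct).
#' @param noise_sd Gaussian pixel noise standard deviation; default 0.05.
#' @param seed Integer seed controlling all sampling.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(num_species = 8, zipf_exponent = 1.5, image_size = 96,
                       objects_per_image = c(1, 4), contrast = 0.5,
                       noise_sd = 0.05, seed = 1L) {
  stopifnot(num_species >= 2, image_size >= 32, zipf_exponent >= 0,
            length(objects_per_image) == 2, objects_per_image[1] >= 1,
            objects_per_image[2] >= objects_per_image[1],
            contrast > 0, contrast <= 1, noise_sd >= 0)
  structure(list(num_species = as.integer(num_species),
                 zipf_exponent = zipf_exponent,
                 image_size = as.integer(image_size),
                 objects_per_image = as.integer(objects_per_image),
                 contrast = contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

species_names <- function(spec) sprintf("sp%02d", seq_len(spec$num_species))

zipf_probs <- function(spec) {
  p <- seq_len(spec$num_species)^(-spec$zipf_exponent)
  p / sum(p)
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a long-tailed species census
#'
#' Draws `total_instances` species labels with probabilities
#' proportional to `rank^(-zipf_exponent)` after guaranteeing every
#' species at least one instance. Deterministic under the spec seed.
#'
#' @param spec A [scene_spec()].
#' @param total_instances Number of instances to draw; default 1000.
#' @return A [class_census()] in species-rank order.
#' @export
sample_long_tail_counts <- function(spec, total_instances = 1000) {
  stopifnot(total_instances >= spec$num_species)
  sp <- species_names(spec)
  with_local_seed(spec$seed, {
    extra <- sample(sp, total_instances - spec$num_species,
                    replace = TRUE, prob = zipf_probs(spec))
    counts <- table(factor(extra, levels = sp)) + 1
    class_census(stats::setNames(as.integer(counts), sp))
  })
}

# fixed per-species appearance derived from the species index only
species_appearance <- function(k) {
  hue <- (k * 0.61803398875) %% 1
  shape <- c("ellipse", "rect", "triangle")[(k - 1) %% 3 + 1]
  stripes <- (k %% 4)          # 0 = plain, else stripe frequency scale
  list(hue = hue, shape = shape, stripes = stripes)
}

hsv_to_rgb1 <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))) / 255
}

draw_object <- function(img, x0, x1, y0, y1, app, fg_col, stripes) {
  # pixel index grids (1-based, inclusive)
  xs <- x0:x1; ys <- y0:y1
  nx <- length(xs); ny <- length(ys)
  gx <- matrix(rep((xs - (x0 + x1) / 2) / (nx / 2), each = ny), ny, nx)
  gy <- matrix(rep((ys - (y0 + y1) / 2) / (ny / 2), times = nx), ny, nx)
  mask <- switch(app$shape,
    ellipse = gx^2 + gy^2 <= 1,
    rect = matrix(TRUE, ny, nx),
    triangle = abs(gy) <= 1 - (gx + 1) / 2   # apex at right edge
  )
  shade <- matrix(1, ny, nx)
  if (stripes > 0) {
    shade <- 0.85 + 0.15 * sin(gx * pi * (stripes + 1))
  }
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    plane[mask] <- (fg_col[ch] * shade)[mask]
    img[ys, xs, ch] <- plane
  }
  img
}

#' Render a synthetic multi-object scene
#'
#' Places one object per requested species instance at a random
#' position and size, over a noisy low-contrast background. Object color
#' is interpolated between the background color and the species hue by
#' the spec's `contrast`, and boxes are the tight pixel extents of the
#' rendered shapes. Objects may overlap (occlusion). Deterministic under
#' `seed`.
#'
#' @param spec A [scene_spec()].
#' @param instances Character vector of species labels to render.
#' @param seed Seed for this scene; defaults to the spec seed.
#' @return A list: `image` (H x W x 3 array in `[0, 1]`) and `objects`,
#'   a tibble of normalized center-form boxes with a `class` column
#'   (pixel-grid aligned, so VOC XML round-trips are lossless).
#' @export
render_scene <- function(spec, instances, seed = spec$seed) {
  S <- spec$image_size
  sp <- species_names(spec)
  bg_col <- c(0.35, 0.45, 0.50)
  with_local_seed(seed, {
    img <- array(rep(bg_col, each = S * S), dim = c(S, S, 3))
    kept <- character(0)
    px <- list()
    for (lab in instances) {
      k <- match(lab, sp)
      if (is.na(k)) rlang::abort(paste0("unknown species '", lab, "'."))
      app <- species_appearance(k)
      placed <- FALSE
      for (try in 1:10) {
        wpx <- sample(10:min(40, S - 2), 1)
        hpx <- sample(10:min(40, S - 2), 1)
        if (wpx > S || hpx > S) next
        x0 <- sample(seq_len(S - wpx + 1), 1); x1 <- x0 + wpx - 1
        y0 <- sample(seq_len(S - hpx + 1), 1); y1 <- y0 + hpx - 1
        placed <- TRUE
        break
      }
      if (!placed) { rlang::inform(paste0("dropped unplaceable instance of ", lab)); next }
      sp_col <- hsv_to_rgb1(app$hue, 0.8, 0.8)
      fg_col <- bg_col + spec$contrast * (sp_col - bg_col)
      img <- draw_object(img, x0, x1, y0, y1, app, fg_col, app$stripes)
      kept <- c(kept, lab)
      px[[length(px) + 1]] <- c(x0, y0, x1, y1)
    }
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    }
    img <- pmin(pmax(img, 0), 1)
    objects <- if (length(kept) == 0) {
      tibble::tibble(class = character(), cx = numeric(), cy = numeric(),
                     w = numeric(), h = numeric())
    } else {
      m <- do.call(rbind, px)
      corner_to_center(tibble::tibble(
        class = kept,
        xmin = (m[, 1] - 1) / S, ymin = (m[, 2] - 1) / S,
        xmax = m[, 3] / S, ymax = m[, 4] / S
      ))[, c("class", "cx", "cy", "w", "h")]
    }
    list(image = img, objects = objects)
  })
}

#' Generate a full synthetic dataset on disk with a 70/15/15 split
#'
#' Writes a VOC-style layout: `JPEGImages/` (PNG files),
#' `Annotations/` (VOC XML), `ImageSets/Main/{train,val,test}.txt`, and
#' `census.csv`, the species census of the *training* annotations.
#' Split sizes are `floor(0.7 T)` train and `floor(0.15 T)` validation,
#' with the remainder assigned to test; membership is a seeded random
#' permutation of image ids.
#'
#' @param spec A [scene_spec()].
#' @param total_images Number of images (>= 10).
#' @param dir Output directory (created if needed).
#' @return A tibble index: `image_id`, `split`, `n_objects`, invisibly
#'   carrying the training census in `attr(, "census")`.
#' @export
generate_dataset <- function(spec, total_images, dir) {
  stopifnot(total_images >= 10)
  for (d in c("JPEGImages", "Annotations", file.path("ImageSets", "Main"))) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  sp <- species_names(spec)
  probs <- zipf_probs(spec)
  n_train <- floor(0.70 * total_images)
  n_val <- floor(0.15 * total_images)
  n_test <- total_images - n_train - n_val
  index <- with_local_seed(spec$seed, {
    split <- sample(rep(c("train", "val", "test"), c(n_train, n_val, n_test)))
    scene_seeds <- sample.int(.Machine$integer.max, total_images)
    rows <- vector("list", total_images)
    for (i in seq_len(total_images)) {
      id <- sprintf("img%05d", i)
      n_obj <- sample(spec$objects_per_image[1]:spec$objects_per_image[2], 1)
      labs <- sample(sp, n_obj, replace = TRUE, prob = probs)
      scene <- render_scene(spec, labs, seed = scene_seeds[i])
      png::writePNG(scene$image, file.path(dir, "JPEGImages", paste0(id, ".png")))
      write_voc_annotation(scene$objects,
                           file.path(dir, "Annotations", paste0(id, ".xml")),
                           width = spec$image_size, height = spec$image_size,
                           filename = paste0(id, ".png"))
      rows[[i]] <- tibble::tibble(image_id = id, split = split[i],
                                  n_objects = nrow(scene$objects))
    }
    dplyr::bind_rows(rows)
  })
  for (s in c("train", "val", "test")) {
    writeLines(index$image_id[index$split == s],
               file.path(dir, "ImageSets", "Main", paste0(s, ".txt")))
  }
  train_ids <- index$image_id[index$split == "train"]
  cls <- unlist(purrr::map(train_ids, function(id) {
    read_voc_annotation(file.path(dir, "Annotations", paste0(id, ".xml")))$class
  }))
  tab <- table(factor(cls, levels = sp))
  tab <- tab[tab > 0]
  census <- class_census(stats::setNames(as.integer(tab), names(tab)))
  write_census_csv(census, file.path(dir, "census.csv"))
  attr(index, "census") <- census
  invisible(index)
}

#' Load a dataset split into memory
#'
#' @param dir Dataset directory written by [generate_dataset()].
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @return A list of class `detection_dataset`: `ids`, `images` (list of
#'   arrays), `annotations` (list of tibbles), `image_size`.
#' @export
load_dataset <- function(dir, split = c("train", "val", "test")) {
  split <- match.arg(split)
  ids <- readLines(file.path(dir, "ImageSets", "Main", paste0(split, ".txt")))
  images <- purrr::map(ids, ~ png::readPNG(file.path(dir, "JPEGImages", paste0(.x, ".png"))))
  ann <- purrr::map(ids, ~ read_voc_annotation(file.path(dir, "Annotations", paste0(.x, ".xml"))))
  structure(list(ids = ids, images = images, annotations = ann,
                 image_size = dim(images[[1]])[1]),
            class = "detection_dataset")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Augment an annotated image
#'
#' Applies, in order: a random crop (box kept iff its center lies in
#' the crop window, then clipped; the crop is resampled up to 10 times
#' if it would drop every box, and skipped after that), a horizontal
#' flip with probability 0.5 (box x-extents mirrored), and photometric
#' jitter (random brightness shift, contrast scaling and hue rotation;
#' pixel values only). Deterministic under `seed`.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param boxes Tibble of normalized center-form boxes with `class`.
#' @param seed Integer seed.
#' @param crop,flip,photometric Logical switches for each stage.
#' @param flip_prob Probability of the horizontal flip; default 0.5.
#' @return A list `(image, boxes)`.
#' @export
augment <- function(image, boxes, seed, crop = TRUE, flip = TRUE,
                    photometric = TRUE, flip_prob = 0.5) {
  with_local_seed(seed, {
    H <- dim(image)[1]; W <- dim(image)[2]
    if (crop && nrow(boxes) > 0) {
      for (try in 1:10) {
        scale <- stats::runif(1, 0.5, 1)
        cw <- max(8L, floor(W * scale)); ch <- max(8L, floor(H * scale))
        x0 <- sample(seq_len(W - cw + 1), 1); y0 <- sample(seq_len(H - ch + 1), 1)
        # crop window in normalized coordinates
        nx0 <- (x0 - 1) / W; nx1 <- (x0 + cw - 1) / W
        ny0 <- (y0 - 1) / H; ny1 <- (y0 + ch - 1) / H
        keep <- boxes$cx >= nx0 & boxes$cx <= nx1 & boxes$cy >= ny0 & boxes$cy <= ny1
        if (any(keep)) {
          image <- image[y0:(y0 + ch - 1), x0:(x0 + cw - 1), , drop = FALSE]
          b <- center_to_corner(boxes[keep, , drop = FALSE])
          b$xmin <- (clamp01((b$xmin - nx0) / (nx1 - nx0)))
          b$xmax <- (clamp01((b$xmax - nx0) / (nx1 - nx0)))
          b$ymin <- (clamp01((b$ymin - ny0) / (ny1 - ny0)))
          b$ymax <- (clamp01((b$ymax - ny0) / (ny1 - ny0)))
          boxes <- corner_to_center(b)[, names(boxes)]
          H <- ch; W <- cw
          break
        }
      }
    }
    if (flip && stats::runif(1) < flip_prob) {
      image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
      if (nrow(boxes) > 0) boxes$cx <- 1 - boxes$cx
    }
    if (photometric) {
      bright <- stats::runif(1, -0.12, 0.12)
      contr <- stats::runif(1, 0.8, 1.2)
      hue_rot <- stats::runif(1, -0.05, 0.05)
      image <- clamp01((image - 0.5) * contr + 0.5 + bright)
      # small hue rotation via channel mixing
      m <- hue_rot
      r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
      image[, , 1] <- clamp01((1 - abs(m)) * r + max(m, 0) * g + max(-m, 0) * b)
      image[, , 2] <- clamp01((1 - abs(m)) * g + max(m, 0) * b + max(-m, 0) * r)
      image[, , 3] <- clamp01((1 - abs(m)) * b + max(m, 0) * r + max(-m, 0) * g)
    }
    list(image = image, boxes = boxes)
  })
}
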