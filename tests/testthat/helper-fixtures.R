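# Shared fixture builders. Everything is generated in code under
# explicit seeds; no stored binary fixtures.

# a small default-box grid (<= 100 boxes) for matching/loss tests
small_grid <- function() {
  default_box_grid(grid_spec(feature_map_sizes = c(4, 2),
                             scales = c(0.25, 0.55),
                             next_scales = c(0.55, 0.85)))
}

# random valid center-form boxes strictly inside the unit square
random_boxes <- function(n) {
  w <- runif(n, 0.05, 0.4)
  h <- runif(n, 0.05, 0.4)
  boxes_tbl(cx = runif(n, w / 2, 1 - w / 2),
            cy = runif(n, h / 2, 1 - h / 2), w = w, h = h)
}

# a random loss fixture: match result against the small grid plus
# simplex confidences and offset predictions
random_loss_fixture <- function(classes = c("spA", "spB", "spC"),
                                n_gt = 3, grid = small_grid()) {
  gt <- dplyr::mutate(random_boxes(n_gt),
                      class = sample(classes, n_gt, replace = TRUE))
  m <- match_boxes(gt, grid)
  D <- nrow(grid)
  K <- length(classes)
  logits <- matrix(rnorm(D * (K + 1)), D, K + 1)
  conf <- exp(logits) / rowSums(exp(logits))
  colnames(conf) <- c(classes, "background")
  loc <- matrix(rnorm(D * 4, sd = 0.3), D, 4)
  counts <- sample(2:30, length(classes), replace = TRUE)
  census <- class_census(stats::setNames(counts, classes))
  list(gt = gt, match = m, conf = conf, loc = loc, census = census,
       batch = loss_batch(conf, loc, m, census))
}

# a perfect-prediction batch for a given match result
perfect_batch <- function(m, classes, census = NULL) {
  D <- nrow(m)
  K <- length(classes)
  conf <- matrix(0, D, K + 1)
  colnames(conf) <- c(classes, "background")
  conf[cbind(seq_len(D), match(m$class, colnames(conf)))] <- 1
  loc <- matrix(0, D, 4)
  pos <- which(m$class != "background")
  loc[pos, ] <- as.matrix(m[pos, c("t_cx", "t_cy", "t_w", "t_h")])
  loss_batch(conf, loc, m, census)
}

# independent brute-force IoU from corner geometry
iou_oracle <- function(a, b) {
  ax0 <- a$cx - a$w / 2; ax1 <- a$cx + a$w / 2
  ay0 <- a$cy - a$h / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; bx1 <- b$cx + b$w / 2
  by0 <- b$cy - b$h / 2; by1 <- b$cy + b$h / 2
  iw <- max(0, min(ax1, bx1) - max(ax0, bx0))
  ih <- max(0, min(ay1, by1) - max(ay0, by0))
  inter <- iw * ih
  un <- a$w * a$h + b$w * b$h - inter
  if (un <= 0) 0 else inter / un
}

# exhaustive greedy NMS oracle over one group of boxes
nms_oracle <- function(det, thr) {
  ord <- order(-det$score, seq_len(nrow(det)))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (iou_oracle(det[i, ], det[j, ]) > thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# brute-force AP oracle: explicit greedy matching then direct
# rectangle integration of the monotone PR envelope
ap_oracle <- function(det, gt, thr) {
  if (nrow(gt) == 0) return(NA_real_)
  if (nrow(det) == 0) return(0)
  ord <- order(-det$score, seq_len(nrow(det)))
  taken <- rep(FALSE, nrow(gt))
  tp <- logical(length(ord))
  for (r in seq_along(ord)) {
    i <- ord[r]
    best <- 0; best_j <- 0
    for (j in seq_len(nrow(gt))) {
      if (taken[j] || gt$image_id[j] != det$image_id[i]) next
      v <- iou_oracle(det[i, ], gt[j, ])
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0 && best >= thr) { tp[r] <- TRUE; taken[best_j] <- TRUE }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / nrow(gt)
  ap <- 0
  prev_r <- 0
  for (r in seq_along(tp)) {
    env <- max(prec[r:length(prec)])
    ap <- ap + (rec[r] - prev_r) * env
    prev_r <- rec[r]
  }
  ap
}

# in-memory dataset splits for detector tests (no disk round trip)
tiny_dataset <- function(spec, n_images, seed_offset = 0) {
  sp <- sprintf("sp%02d", seq_len(spec$num_species))
  p <- seq_len(spec$num_species)^(-spec$zipf_exponent)
  p <- p / sum(p)
  images <- list(); anns <- list()
  withr::with_seed(spec$seed + seed_offset, {
    labs_all <- lapply(seq_len(n_images), function(i) {
      n_obj <- sample(spec$objects_per_image[1]:spec$objects_per_image[2], 1)
      sample(sp, n_obj, replace = TRUE, prob = p)
    })
    seeds <- sample.int(1e6, n_images)
    for (i in seq_len(n_images)) {
      sc <- render_scene(spec, labs_all[[i]], seed = seeds[i])
      images[[i]] <- sc$image
      anns[[i]] <- sc$objects
    }
  })
  structure(list(ids = sprintf("t%04d", seq_len(n_images)), images = images,
                 annotations = anns, image_size = spec$image_size),
            class = "detection_dataset")
}
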