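#' Training hyper-parameters for the reference detector
#'
#' Defaults follow the conventional SSD training recipe: SGD with
#' momentum 0.9, weight decay 5e-4, batch size 32, initial learning
#' rate 1e-3 decayed by `lr_gamma = 0.1` at the milestones, and a
#' linear warm-up. Milestones and warm-up length default to fractions
#' of the total step count (60% / 85% and 5%).
#'
#' @param epochs Number of passes over the training split.
#' @param batch_size Images per SGD step; default 32.
#' @param base_lr Peak learning rate; default 1e-3.
#' @param momentum SGD momentum; default 0.9.
#' @param weight_decay L2 penalty coefficient; default 5e-4.
#' @param lr_gamma Multiplicative decay at each milestone; default 0.1.
#' @param milestones Step indices (strictly increasing) at which the
#'   learning rate decays; `NULL` places them at 60% and 85% of
#'   training.
#' @param warmup_steps Linear warm-up length in steps; `NULL` uses 5%
#'   of training (at least 1 step).
#' @param seed Seed for initialization and data order.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 32, base_lr = 1e-3,
                         momentum = 0.9, weight_decay = 5e-4, lr_gamma = 0.1,
                         milestones = NULL, warmup_steps = NULL, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, base_lr > 0, momentum >= 0,
            weight_decay >= 0, lr_gamma > 0)
  if (!is.null(milestones)) stopifnot(all(diff(milestones) > 0))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 base_lr = base_lr, momentum = momentum,
                 weight_decay = weight_decay, lr_gamma = lr_gamma,
                 milestones = milestones, warmup_steps = warmup_steps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given SGD step
#'
#' Linear warm-up from `base_lr / warmup_steps` to `base_lr`, then
#' multiplicative decay by `lr_gamma` after each milestone.
#'
#' @param step 1-based step index.
#' @param total_steps Total planned steps (used to resolve fractional
#'   defaults).
#' @param config A [train_config()].
#' @return The scalar learning rate.
#' @export
lr_at_step <- function(step, total_steps, config) {
  warm <- config$warmup_steps
  if (is.null(warm)) warm <- max(1L, round(0.05 * total_steps))
  ms <- config$milestones
  if (is.null(ms)) ms <- unique(pmax(1L, round(c(0.6, 0.85) * total_steps)))
  if (step <= warm) return(config$base_lr * step / warm)
  config$base_lr * config$lr_gamma^sum(step > ms)
}

#' Build the tiny single-shot detector
#'
#' A deliberately small CPU-trainable network: a stack of 3x3 stride-2
#' stages with hard-swish activations (optionally depthwise-separable),
#' halving the map at every stage, with 1x1 classification and
#' regression heads at the stages whose resolutions match the
#' default-box grid. Each head location predicts 4 boxes: `(K+1)`
#' confidences and 4 offsets per box.
#'
#' @param grid A [default_box_grid()].
#' @param classes Character vector of foreground class labels.
#' @param image_size Input image side in pixels; the stride-2 chain
#'   from this size must pass through every grid map resolution.
#' @param depthwise Use depthwise-separable stages after the stem;
#'   fewer parameters at equal width.
#' @param seed Seed for weight initialization.
#' @return A list of class `ssd_detector` (untrained).
#' @export
build_detector <- function(grid, classes, image_size = 96, depthwise = FALSE,
                           seed = 1L) {
  spec <- attr(grid, "spec")
  map_sizes <- spec$feature_map_sizes
  sizes <- image_size
  while (sizes[length(sizes)] > min(map_sizes)) {
    sizes <- c(sizes, ceiling(sizes[length(sizes)] / 2))
  }
  if (!all(map_sizes %in% sizes)) {
    rlang::abort("grid map resolutions are unreachable by stride-2 halving from image_size.")
  }
  n_layers <- length(sizes) - 1
  widths <- pmin(8 * 2^(seq_len(n_layers) - 1), 32)
  K <- length(classes)
  with_local_seed(seed, {
    layers <- vector("list", n_layers)
    C_in <- 3
    for (l in seq_len(n_layers)) {
      maker <- if (depthwise && l > 1) make_dwsep else make_conv
      layers[[l]] <- maker(sizes[l], sizes[l], C_in, widths[l])
      C_in <- widths[l]
    }
    head_at <- match(map_sizes, sizes[-1])   # layer index producing each map
    heads <- purrr::map(head_at, function(l) {
      conf <- make_head(widths[l], 4 * (K + 1))
      # start with a strong background prior (p_bg ~ 0.99) so early
      # training is not dominated by mis-scored negatives
      conf$b[4 * (K + 1) - (3:0) * (K + 1)] <- log(99 * K)
      list(conf = conf, loc = make_head(widths[l], 4 * 4))
    })
    structure(list(layers = layers, heads = heads, head_at = head_at,
                   grid = grid, classes = classes, image_size = image_size,
                   depthwise = depthwise, seed = seed, version = "ltdetect-1",
                   log = NULL),
              class = "ssd_detector")
  })
}

#' Parameter count of a detector
#'
#' @param model An `ssd_detector`.
#' @return Integer number of trainable scalars.
#' @export
n_params <- function(model) {
  cnt <- function(layer) sum(vapply(layer[intersect(names(layer),
                c("W", "b", "Wd", "bd", "Wp"))], length, integer(1)))
  sum(vapply(model$layers, cnt, integer(1))) +
    sum(vapply(model$heads, function(h) cnt(h$conf) + cnt(h$loc), integer(1)))
}

# Full forward pass over a batch of images (list of H x W x 3 arrays).
# Returns per-image conf logits (D x (K+1)) and loc (D x 4) in grid
# order, plus caches for backprop.
detector_forward <- function(model, images, keep_cache = FALSE,
                             l1_cols = NULL) {
  B <- length(images)
  K <- length(model$classes)
  X <- if (is.null(l1_cols)) {
    do.call(rbind, lapply(images, function(im) flatten_image(im) - 0.5))
  } else NULL
  acts <- vector("list", length(model$layers))
  A <- X
  for (l in seq_along(model$layers)) {
    fwd <- if (l == 1 && !is.null(l1_cols)) {
      conv_forward(model$layers[[1]], NULL, B, Xcol = do.call(rbind, l1_cols))
    } else {
      conv_forward(model$layers[[l]], A, B)
    }
    acts[[l]] <- if (keep_cache) fwd else list(A = fwd$A)
    A <- fwd$A
  }
  conf <- vector("list", B); loc <- vector("list", B)
  head_Y <- vector("list", length(model$heads))
  for (m in seq_along(model$heads)) {
    l <- model$head_at[m]
    A_m <- acts[[l]]$A
    Yc <- head_forward(model$heads[[m]]$conf, A_m)
    Yl <- head_forward(model$heads[[m]]$loc, A_m)
    head_Y[[m]] <- list(conf = Yc, loc = Yl)
    npos <- nrow(A_m) / B
    for (i in seq_len(B)) {
      rows <- ((i - 1) * npos + 1):(i * npos)
      cb <- head_to_defaults(Yc[rows, , drop = FALSE], K + 1)
      lb <- head_to_defaults(Yl[rows, , drop = FALSE], 4)
      conf[[i]] <- rbind(conf[[i]], cb)
      loc[[i]] <- rbind(loc[[i]], lb)
    }
  }
  for (i in seq_len(B)) colnames(conf[[i]]) <- c(model$classes, "background")
  list(conf = conf, loc = loc, acts = if (keep_cache) acts else NULL,
       head_Y = head_Y, B = B)
}

# Backward pass: d_conf/d_loc are per-image gradient matrices aligned
# with detector_forward output. Returns gradients for every parameter.
detector_backward <- function(model, fwd, d_conf, d_loc) {
  B <- fwd$B
  K <- length(model$classes)
  n_layers <- length(model$layers)
  dA <- vector("list", n_layers)   # accumulated dL/dA per layer
  head_grads <- vector("list", length(model$heads))
  offset <- 0
  for (m in seq_along(model$heads)) {
    l <- model$head_at[m]
    A_m <- fwd$acts[[l]]$A
    npos <- nrow(A_m) / B
    D_m <- npos * 4
    dYc <- matrix(0, nrow(A_m), 4 * (K + 1))
    dYl <- matrix(0, nrow(A_m), 16)
    for (i in seq_len(B)) {
      rows <- ((i - 1) * npos + 1):(i * npos)
      dcb <- d_conf[[i]][(offset + 1):(offset + D_m), , drop = FALSE]
      dlb <- d_loc[[i]][(offset + 1):(offset + D_m), , drop = FALSE]
      dYc[rows, ] <- defaults_to_head(dcb, K + 1, npos)
      dYl[rows, ] <- defaults_to_head(dlb, 4, npos)
    }
    bc <- head_backward(model$heads[[m]]$conf, A_m, dYc)
    bl <- head_backward(model$heads[[m]]$loc, A_m, dYl)
    head_grads[[m]] <- list(conf = bc$grads, loc = bl$grads)
    dA[[l]] <- (if (is.null(dA[[l]])) 0 else dA[[l]]) + bc$dX + bl$dX
    offset <- offset + D_m
  }
  layer_grads <- vector("list", n_layers)
  dA_cur <- dA[[n_layers]]
  if (is.null(dA_cur)) dA_cur <- matrix(0, nrow(fwd$acts[[n_layers]]$A),
                                        ncol(fwd$acts[[n_layers]]$A))
  for (l in rev(seq_len(n_layers))) {
    bk <- conv_backward(model$layers[[l]], dA_cur, fwd$acts[[l]],
                        NULL, B, need_dx = l > 1)
    layer_grads[[l]] <- bk$grads
    if (l > 1) {
      dA_cur <- bk$dX
      if (!is.null(dA[[l - 1]])) dA_cur <- dA_cur + dA[[l - 1]]
    }
  }
  list(layers = layer_grads, heads = head_grads)
}

# map over all (param, grad, velocity) triples of the model
sgd_update <- function(model, grads, vel, lr, momentum, wd) {
  upd <- function(W, g, v) {
    v_new <- momentum * v - lr * (g + wd * W)
    list(W = W + v_new, v = v_new)
  }
  for (l in seq_along(model$layers)) {
    for (nm in intersect(names(model$layers[[l]]), c("W", "b", "Wd", "bd", "Wp"))) {
      r <- upd(model$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               vel$layers[[l]][[nm]])
      model$layers[[l]][[nm]] <- r$W
      vel$layers[[l]][[nm]] <- r$v
    }
  }
  for (m in seq_along(model$heads)) {
    for (part in c("conf", "loc")) {
      for (nm in c("W", "b")) {
        r <- upd(model$heads[[m]][[part]][[nm]], grads$heads[[m]][[part]][[nm]],
                 vel$heads[[m]][[part]][[nm]])
        model$heads[[m]][[part]][[nm]] <- r$W
        vel$heads[[m]][[part]][[nm]] <- r$v
      }
    }
  }
  list(model = model, vel = vel)
}

zero_like_grads <- function(model) {
  zl <- function(layer) {
    out <- list()
    for (nm in intersect(names(layer), c("W", "b", "Wd", "bd", "Wp"))) {
      out[[nm]] <- layer[[nm]] * 0
    }
    out
  }
  list(layers = lapply(model$layers, zl),
       heads = lapply(model$heads, function(h) list(conf = zl(h$conf),
                                                    loc = zl(h$loc))))
}

#' Train the reference detector on a dataset split
#'
#' SGD with momentum, weight decay, linear warm-up and multi-step
#' learning-rate decay. Ground truths of every image are matched to the
#' default-box grid once up front (training does not re-augment), and
#' each step backpropagates the configured multibox objective. The data
#' order, initialization and every random choice derive from the seeds,
#' so swapping the loss scheme changes nothing but the loss.
#'
#' @param dataset A `detection_dataset` ([load_dataset()]).
#' @param census A [class_census()] of the training split (required by
#'   the reweighted schemes; `NULL` derives it from the dataset).
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param model Optionally a pre-built [build_detector()]; built from
#'   the grid spec otherwise.
#' @param grid A [default_box_grid()]; default suits 96 px scenes.
#' @return The trained `ssd_detector` with a per-epoch `log` tibble
#'   (`epoch, total, classification, localization, lr`).
#' @export
train_detector <- function(dataset, census = NULL, loss_cfg = loss_config(),
                           train_cfg = train_config(), model = NULL,
                           grid = default_box_grid()) {
  if (is.null(census)) {
    cls <- unlist(purrr::map(dataset$annotations, "class"))
    tab <- table(cls)
    census <- class_census(stats::setNames(as.integer(tab), names(tab)))
  }
  if (is.null(model)) {
    model <- build_detector(grid, classes = census$species,
                            image_size = dataset$image_size,
                            seed = train_cfg$seed)
  }
  grid <- model$grid
  matches <- purrr::map(dataset$annotations, match_boxes, grid = grid,
                        encoding = loss_cfg$encoding)
  # the input layer sees the same pixels every epoch: im2col once
  l1_cols <- lapply(dataset$images, function(im) {
    im2col(flatten_image(im) - 0.5, model$layers[[1]]$src, 1L)
  })
  n_img <- length(dataset$images)
  steps_per_epoch <- max(1L, ceiling(n_img / train_cfg$batch_size))
  total_steps <- steps_per_epoch * train_cfg$epochs
  vel <- zero_like_grads(model)
  log <- vector("list", train_cfg$epochs)
  step <- 0
  with_local_seed(train_cfg$seed + 1L, {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n_img)
      ep_loss <- c(total = 0, classification = 0, localization = 0)
      n_batches <- 0
      lr_last <- NA_real_
      for (b in seq_len(steps_per_epoch)) {
        ix <- ord[((b - 1) * train_cfg$batch_size + 1):min(b * train_cfg$batch_size, n_img)]
        ix <- ix[!is.na(ix)]
        step <- step + 1
        lr_last <- lr_at_step(step, total_steps, train_cfg)
        fwd <- detector_forward(model, dataset$images[ix], keep_cache = TRUE,
                                l1_cols = l1_cols[ix])
        d_conf <- vector("list", length(ix))
        d_loc <- vector("list", length(ix))
        batch_loss <- c(0, 0, 0)
        for (i in seq_along(ix)) {
          lg <- multibox_loss_grad(fwd$conf[[i]], fwd$loc[[i]],
                                   matches[[ix[i]]], census, loss_cfg)
          d_conf[[i]] <- lg$dlogits / length(ix)
          d_loc[[i]] <- lg$dloc / length(ix)
          batch_loss <- batch_loss + c(lg$loss$total, lg$loss$classification,
                                       lg$loss$localization) / length(ix)
        }
        if (!all(is.finite(batch_loss))) {
          rlang::abort(sprintf("training diverged (non-finite loss) at step %d.", step))
        }
        grads <- detector_backward(model, fwd, d_conf, d_loc)
        r <- sgd_update(model, grads, vel, lr_last, train_cfg$momentum,
                        train_cfg$weight_decay)
        model <- r$model; vel <- r$vel
        ep_loss <- ep_loss + batch_loss
        n_batches <- n_batches + 1
      }
      log[[ep]] <- tibble::tibble(epoch = ep,
                                  total = ep_loss[1] / n_batches,
                                  classification = ep_loss[2] / n_batches,
                                  localization = ep_loss[3] / n_batches,
                                  lr = lr_last)
    }
  })
  model$log <- dplyr::bind_rows(log)
  model$loss_cfg <- loss_cfg
  model$train_cfg <- train_cfg
  model$census <- census
  model
}

#' Run the detector on one image
#'
#' Forward pass, softmax over class confidences, per-default decoding
#' against the matched default box, score thresholding, and per-class
#' greedy NMS. Deterministic for a fixed model and input.
#'
#' @param model A (trained) `ssd_detector`.
#' @param image H x W x 3 array in `[0, 1]`.
#' @param score_threshold Minimum class confidence; default 0.3.
#' @param nms_iou NMS threshold; default 0.45.
#' @param image_id Identifier stamped on the detections.
#' @param top_k Keep at most this many detections per class before NMS.
#' @return A tibble of detections: `image_id`, `class`, `score`, `cx`,
#'   `cy`, `w`, `h`.
#' @export
predict_detector <- function(model, image, score_threshold = 0.3,
                             nms_iou = 0.45, image_id = "img", top_k = 100) {
  detect_batch(model, list(image), image_id, score_threshold, nms_iou, top_k)
}

empty_detections <- function() {
  tibble::tibble(image_id = character(), class = character(),
                 score = numeric(), cx = numeric(), cy = numeric(),
                 w = numeric(), h = numeric())
}

# batched prediction over a list of images (one forward pass)
detect_batch <- function(model, images, image_ids, score_threshold = 0.3,
                         nms_iou = 0.45, top_k = 100) {
  fwd <- detector_forward(model, images)
  variant <- model$loss_cfg$encoding %||% "plain"
  out <- vector("list", length(images))
  K <- length(model$classes)
  g_cx <- model$grid$cx; g_cy <- model$grid$cy
  g_w <- model$grid$w; g_h <- model$grid$h
  for (i in seq_along(images)) {
    logits <- fwd$conf[[i]]
    rmax <- logits[cbind(seq_len(nrow(logits)),
                         max.col(logits, ties.method = "first"))]
    ez <- exp(logits - rmax)
    p <- ez / rowSums(ez)
    loc <- fwd$loc[[i]]
    if (variant == "plain") {
      d_cx <- loc[, 1] + g_cx; d_cy <- loc[, 2] + g_cy
    } else {
      d_cx <- loc[, 1] * g_w + g_cx; d_cy <- loc[, 2] * g_h + g_cy
    }
    d_w <- exp(loc[, 3]) * g_w; d_h <- exp(loc[, 4]) * g_h
    keep_ix <- integer(0); keep_cl <- integer(0)
    for (ci in seq_len(K)) {
      sc <- p[, ci]
      keep <- which(sc >= score_threshold)
      if (length(keep) > top_k) {
        keep <- keep[order(-sc[keep], keep)[seq_len(top_k)]]
      }
      keep_ix <- c(keep_ix, keep)
      keep_cl <- c(keep_cl, rep(ci, length(keep)))
    }
    if (length(keep_ix) == 0) { out[[i]] <- empty_detections(); next }
    dets <- tibble::tibble(
      image_id = image_ids[i],
      class = model$classes[keep_cl],
      score = p[cbind(keep_ix, keep_cl)],
      cx = clamp01(d_cx[keep_ix]), cy = clamp01(d_cy[keep_ix]),
      w = pmin(d_w[keep_ix], 1), h = pmin(d_h[keep_ix], 1))
    out[[i]] <- nms(dets, nms_iou)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty_detections() else res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a detector on a dataset split
#'
#' @param model A trained `ssd_detector`.
#' @param dataset A `detection_dataset`.
#' @param score_threshold,nms_iou Passed to [predict_detector()].
#' @param iou_threshold AP true-positive criterion; default 0.5.
#' @param classes Classes to evaluate; defaults to the model's classes.
#' @return A `detection_eval` from [mean_ap()].
#' @export
evaluate_detector <- function(model, dataset, score_threshold = 0.05,
                              nms_iou = 0.45, iou_threshold = 0.5,
                              classes = model$classes) {
  batches <- split(seq_along(dataset$images),
                   ceiling(seq_along(dataset$images) / 16))
  dets <- purrr::map_dfr(batches, function(ix) {
    detect_batch(model, dataset$images[ix], dataset$ids[ix],
                 score_threshold, nms_iou)
  })
  gts <- purrr::map_dfr(seq_along(dataset$annotations), function(i) {
    a <- dataset$annotations[[i]]
    if (nrow(a) == 0) return(NULL)
    dplyr::mutate(a, image_id = dataset$ids[i])
  })
  mean_ap(dets, gts, classes = intersect(classes, unique(gts$class)),
          iou_threshold = iou_threshold)
}

#' Save / load a detector artifact
#'
#' The artifact is an RDS file carrying a format version tag.
#'
#' @param model An `ssd_detector`.
#' @param path File path.
#' @return `path` (save) or the restored model (load).
#' @export
save_detector <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  m <- readRDS(path)
  if (!identical(m$version, "ltdetect-1")) {
    rlang::abort("unrecognized detector artifact version.")
  }
  m
}
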