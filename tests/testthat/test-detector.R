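# a tiny 32-px detector setup shared by the tests below
tiny_setup <- function(depthwise = FALSE, seed = 1) {
  spec <- grid_spec(feature_map_sizes = c(4, 2), scales = c(0.3, 0.6),
                    next_scales = c(0.6, 0.9))
  grid <- default_box_grid(spec)
  model <- build_detector(grid, classes = c("sp01", "sp02", "sp03"),
                          image_size = 32, depthwise = depthwise, seed = seed)
  list(spec = spec, grid = grid, model = model)
}

test_that("head outputs match the default-box shape contract", {
  ts <- tiny_setup()
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  fwd <- ltdetect:::detector_forward(ts$model, list(img))
  D <- nrow(ts$grid)
  expect_equal(dim(fwd$conf[[1]]), c(D, 4))     # 3 classes + background
  expect_equal(dim(fwd$loc[[1]]), c(D, 4))
  expect_equal(colnames(fwd$conf[[1]]), c("sp01", "sp02", "sp03", "background"))

  # a 3-map 96-px build matches its 756-box grid
  g96 <- default_box_grid()
  m96 <- build_detector(g96, sprintf("sp%02d", 1:8), image_size = 96)
  img96 <- array(0.5, dim = c(96, 96, 3))
  f96 <- ltdetect:::detector_forward(m96, list(img96))
  expect_equal(nrow(f96$conf[[1]]), 756)
  expect_equal(ncol(f96$conf[[1]]), 9)
})

test_that("builds are seeded and the depthwise variant is smaller", {
  m1 <- tiny_setup(seed = 7)$model
  m2 <- tiny_setup(seed = 7)$model
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$heads, m2$heads)
  m3 <- tiny_setup(seed = 8)$model
  expect_false(identical(m1$layers, m3$layers))

  dense <- tiny_setup(depthwise = FALSE)$model
  dw <- tiny_setup(depthwise = TRUE)$model
  expect_lt(n_params(dw), n_params(dense))
})

test_that("batched and single-image forward passes agree", {
  ts <- tiny_setup()
  withr::with_seed(3, {
    imgs <- lapply(1:3, function(i) array(runif(32 * 32 * 3), dim = c(32, 32, 3)))
  })
  fb <- ltdetect:::detector_forward(ts$model, imgs)
  for (i in 1:3) {
    f1 <- ltdetect:::detector_forward(ts$model, imgs[i])
    expect_equal(fb$conf[[i]], f1$conf[[1]], tolerance = 1e-12)
    expect_equal(fb$loc[[i]], f1$loc[[1]], tolerance = 1e-12)
  }
})

test_that("learning-rate schedule warms up then steps down", {
  cfg <- train_config(base_lr = 1e-3, lr_gamma = 0.1,
                      milestones = c(60, 85), warmup_steps = 10)
  expect_lt(lr_at_step(1, 100, cfg), 1e-3)
  expect_equal(lr_at_step(10, 100, cfg), 1e-3)
  expect_equal(lr_at_step(40, 100, cfg), 1e-3)
  expect_equal(lr_at_step(61, 100, cfg), 1e-4)
  expect_equal(lr_at_step(86, 100, cfg), 1e-5)
  # fractional defaults resolve against the planned total
  cfg2 <- train_config(base_lr = 1e-3)
  expect_equal(lr_at_step(5, 100, cfg2), 1e-3)
  expect_equal(lr_at_step(61, 100, cfg2), 1e-4)
})

test_that("network gradients pass a finite-difference spot check", {
  ts <- tiny_setup()
  withr::with_seed(11, {
    img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
    gt <- dplyr::mutate(boxes_tbl(c(0.3, 0.7), c(0.4, 0.6), c(0.3, 0.25), c(0.3, 0.3)),
                        class = c("sp01", "sp02"))
    m <- match_boxes(gt, ts$grid)
    census <- class_census(c(sp01 = 5, sp02 = 20, sp03 = 2))
    cfg <- loss_config(reweight = reweight_config("class_aware", eta = 4))
    loss_of <- function(model) {
      fwd <- ltdetect:::detector_forward(model, list(img))
      ltdetect:::multibox_loss_grad(fwd$conf[[1]], fwd$loc[[1]], m, census, cfg)$loss$total
    }
    fwd <- ltdetect:::detector_forward(ts$model, list(img), keep_cache = TRUE)
    lg <- ltdetect:::multibox_loss_grad(fwd$conf[[1]], fwd$loc[[1]], m, census, cfg)
    grads <- ltdetect:::detector_backward(ts$model, fwd, list(lg$dlogits), list(lg$dloc))
    eps <- 1e-5
    for (probe in 1:10) {
      l <- sample(length(ts$model$layers), 1)
      nm <- sample(c("W", "b"), 1)
      ix <- sample(length(ts$model$layers[[l]][[nm]]), 1)
      mp <- ts$model; mp$layers[[l]][[nm]][ix] <- mp$layers[[l]][[nm]][ix] + eps
      mm <- ts$model; mm$layers[[l]][[nm]][ix] <- mm$layers[[l]][[nm]][ix] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      an <- grads$layers[[l]][[nm]][ix]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  })
})

test_that("depthwise-separable gradients also pass finite differences", {
  ts <- tiny_setup(depthwise = TRUE)
  withr::with_seed(13, {
    img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
    gt <- dplyr::mutate(boxes_tbl(0.5, 0.5, 0.4, 0.4), class = "sp01")
    m <- match_boxes(gt, ts$grid)
    cfg <- loss_config()
    loss_of <- function(model) {
      fwd <- ltdetect:::detector_forward(model, list(img))
      ltdetect:::multibox_loss_grad(fwd$conf[[1]], fwd$loc[[1]], m, NULL, cfg)$loss$total
    }
    fwd <- ltdetect:::detector_forward(ts$model, list(img), keep_cache = TRUE)
    lg <- ltdetect:::multibox_loss_grad(fwd$conf[[1]], fwd$loc[[1]], m, NULL, cfg)
    grads <- ltdetect:::detector_backward(ts$model, fwd, list(lg$dlogits), list(lg$dloc))
    eps <- 1e-5
    for (nm in c("Wd", "bd", "Wp")) {
      l <- 2   # the depthwise stage
      ix <- sample(length(ts$model$layers[[l]][[nm]]), 1)
      mp <- ts$model; mp$layers[[l]][[nm]][ix] <- mp$layers[[l]][[nm]][ix] + eps
      mm <- ts$model; mm$layers[[l]][[nm]][ix] <- mm$layers[[l]][[nm]][ix] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(grads$layers[[l]][[nm]][ix], fd, tolerance = 1e-4)
    }
  })
})

test_that("short seeded training reduces the loss reproducibly", {
  spec <- scene_spec(num_species = 4, image_size = 32, seed = 17,
                     objects_per_image = c(1, 2))
  ds <- tiny_dataset(spec, 24)
  grid <- default_box_grid(grid_spec(feature_map_sizes = c(4, 2),
                                     scales = c(0.3, 0.6),
                                     next_scales = c(0.6, 0.9)))
  cfg <- train_config(epochs = 5, batch_size = 8, base_lr = 0.02, seed = 21)
  m1 <- train_detector(ds, loss_cfg = loss_config(), train_cfg = cfg, grid = grid)
  expect_lt(m1$log$total[5], m1$log$total[1])
  m2 <- train_detector(ds, loss_cfg = loss_config(), train_cfg = cfg, grid = grid)
  expect_equal(m1$log$total, m2$log$total, tolerance = 1e-6)
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)

  # the training log tidies into per-epoch rows
  expect_equal(tidy(m1)$epoch, 1:5)
  expect_equal(glance(m1)$epochs, 5L)
})

test_that("swapping the loss scheme changes only the loss computation", {
  spec <- scene_spec(num_species = 4, image_size = 32, seed = 19,
                     objects_per_image = c(1, 2))
  ds <- tiny_dataset(spec, 12)
  grid <- default_box_grid(grid_spec(feature_map_sizes = c(4, 2),
                                     scales = c(0.3, 0.6),
                                     next_scales = c(0.6, 0.9)))
  cfg <- train_config(epochs = 1, batch_size = 8, seed = 23)
  m_none <- train_detector(ds, loss_cfg = loss_config(), train_cfg = cfg, grid = grid)
  m_ca <- train_detector(ds,
    loss_cfg = loss_config(reweight = reweight_config("class_aware", eta = 4)),
    train_cfg = cfg, grid = grid)
  # identical initial weights under the same seed
  init1 <- build_detector(grid, m_none$classes, image_size = 32, seed = cfg$seed)
  init2 <- build_detector(grid, m_ca$classes, image_size = 32, seed = cfg$seed)
  expect_identical(init1$layers, init2$layers)
  # but the trained weights differ because the objective differs
  expect_false(identical(m_none$layers[[1]]$W, m_ca$layers[[1]]$W))
})

test_that("prediction respects thresholds and is deterministic", {
  ts <- tiny_setup()
  ts$model$loss_cfg <- loss_config()
  withr::with_seed(29, {
    img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  })
  none <- predict_detector(ts$model, img, score_threshold = 1)
  expect_equal(nrow(none), 0)
  d1 <- predict_detector(ts$model, img, score_threshold = 0.1)
  d2 <- predict_detector(ts$model, img, score_threshold = 0.1)
  expect_identical(d1, d2)
  # with NMS at 1.0 every thresholded detection survives
  raw <- predict_detector(ts$model, img, score_threshold = 0.1, nms_iou = 1)
  expect_gte(nrow(raw), nrow(d1))
  if (nrow(d1) > 0) {
    expect_true(all(d1$score >= 0.1))
    expect_true(all(d1$w > 0 & d1$h > 0))
  }
})

test_that("detector artifacts survive a save/load round trip", {
  ts <- tiny_setup()
  path <- withr::local_tempfile(fileext = ".rds")
  save_detector(ts$model, path)
  back <- load_detector(path)
  expect_identical(back$layers, ts$model$layers)
  stale <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "something-else"), stale)
  expect_error(load_detector(stale), "version")
})
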