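test_that("smooth_l1 follows its two branches and joins smoothly", {
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(0.5), 0.125)
  expect_equal(smooth_l1(-2), 1.5)
  expect_equal(smooth_l1(c(1, -1)), c(0.5, 0.5))
  # continuity and C1 join at |x| = 1
  eps <- 1e-8
  expect_equal(smooth_l1(1 - eps), smooth_l1(1 + eps), tolerance = 1e-7)
})

test_that("localization loss sums SmoothL1 residuals over matched defaults", {
  grid <- small_grid()
  gt <- dplyr::mutate(grid[3, 1:4], class = "spA")
  m <- match_boxes(gt, grid)
  batch <- perfect_batch(m, "spA")
  expect_equal(localization_loss(batch), 0)

  # perturb one matched default's cx prediction by 0.5:
  # contribution smooth_l1(0.5) = 0.125 for that default, N-normalized
  pos <- which(m$class != "background")
  loc <- batch$loc
  loc[pos[1], 1] <- loc[pos[1], 1] + 0.5
  b2 <- loss_batch(batch$conf, loc, m)
  expect_equal(localization_loss(b2), 0.125 / n_matched(m))

  # all-background match gives zero
  m0 <- match_boxes(gt[0, ], grid)
  b0 <- perfect_batch(m0, "spA")
  expect_equal(localization_loss(b0), 0)
})

test_that("classification loss averages cross-entropy over contributors", {
  grid <- small_grid()
  gt <- dplyr::bind_rows(
    dplyr::mutate(grid[3, 1:4], class = "spA"),
    dplyr::mutate(grid[30, 1:4], class = "spB")
  )
  m <- match_boxes(gt, grid)
  batch <- perfect_batch(m, c("spA", "spB", "spC"))
  expect_equal(classification_loss(batch), 0)

  # uniform confidences over the 4 columns at the positives with
  # perfect negatives: only the positives contribute, each -log(1/4)
  N <- n_matched(m)
  conf <- batch$conf
  pos <- which(m$class != "background")
  conf[pos, ] <- 1 / 4
  b2 <- loss_batch(conf, batch$loc, m)
  expect_equal(classification_loss(b2), log(4) * length(pos) / N)

  # two contributing defaults at p_true = 0.5 each -> mean ln 2
  conf2 <- batch$conf
  true_ix <- match(m$class, colnames(conf2))
  for (i in pos[1:2]) {
    conf2[i, ] <- 0.5 / 3
    conf2[i, true_ix[i]] <- 0.5
  }
  # rescale remaining rows stay one-hot; only perturbed rows contribute
  b3 <- loss_batch(conf2, batch$loc, m)
  expect_equal(classification_loss(b3), 2 * log(2) / N)
})

test_that("combined loss is the alpha-weighted sum under one normalizer", {
  withr::with_seed(5, {
    fx <- random_loss_fixture()
    cfg <- loss_config()
    res <- combined_loss(fx$batch, cfg)
    expect_equal(res$total, res$classification + res$localization)
    expect_equal(res$classification, classification_loss(fx$batch, cfg))
    expect_equal(res$localization, localization_loss(fx$batch, cfg))
    res0 <- combined_loss(fx$batch, loss_config(alpha = 0))
    expect_equal(res0$total, res0$classification)
    # perfect predictions give exactly zero everywhere
    pb <- perfect_batch(fx$match, c("spA", "spB", "spC"))
    z <- combined_loss(pb, cfg)
    expect_equal(unlist(z[, 1:3]), c(total = 0, classification = 0, localization = 0))
  })
})

test_that("class-aware loss reduces to the combined loss at eta = 1", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      fx <- random_loss_fixture()
      cfg1 <- loss_config(reweight = reweight_config("class_aware", eta = 1))
      expect_equal(class_aware_loss(fx$batch, cfg1)$total,
                   combined_loss(fx$batch, loss_config())$total,
                   tolerance = 1e-10)
    }
  })
})

test_that("class-aware loss scales each part by the species weight", {
  grid <- small_grid()
  gt <- dplyr::mutate(grid[3, 1:4], class = "spA")
  m <- match_boxes(gt, grid)
  census <- class_census(c(spA = 50, spB = 50))   # ns/n = 0.5
  conf <- matrix(0, nrow(grid), 3,
                 dimnames = list(NULL, c("spA", "spB", "background")))
  conf[, "background"] <- 1
  pos <- which(m$class != "background")
  conf[pos, ] <- 1 / 3   # imperfect at positives, perfect negatives
  loc <- matrix(0, nrow(grid), 4)
  loc[pos, ] <- as.matrix(m[pos, c("t_cx", "t_cy", "t_w", "t_h")]) + 0.3
  batch <- loss_batch(conf, loc, m, census)
  plain <- combined_loss(batch, loss_config())
  ca <- class_aware_loss(batch, loss_config(reweight = reweight_config("class_aware", eta = 4)))
  w <- class_aware_weight(50, 100, eta = 4)
  expect_equal(ca$classification, w * plain$classification)
  expect_equal(ca$localization, w * plain$localization)
})

test_that("class-balanced objective reduces to combined loss at ny = 1", {
  withr::with_seed(43, {
    for (rep in 1:50) {
      fx <- random_loss_fixture()
      census1 <- class_census(stats::setNames(rep(1, 3), fx$census$species))
      batch <- loss_batch(fx$conf, fx$loc, fx$match, census1)
      cb <- class_balanced_objective(batch, loss_config(reweight = reweight_config("class_balanced", beta = 2)))
      expect_equal(cb$total, combined_loss(batch, loss_config())$total,
                   tolerance = 1e-10)
    }
  })
})

test_that("class-balanced objective scales by (1-beta)/(1-beta^ny)", {
  grid <- small_grid()
  gt <- dplyr::mutate(grid[3, 1:4], class = "spA")
  m <- match_boxes(gt, grid)
  census <- class_census(c(spA = 3))
  conf <- matrix(0, nrow(grid), 2,
                 dimnames = list(NULL, c("spA", "background")))
  conf[, "background"] <- 1
  pos <- which(m$class != "background")
  conf[pos, ] <- 1 / 2
  loc <- matrix(0, nrow(grid), 4)
  loc[pos, ] <- as.matrix(m[pos, c("t_cx", "t_cy", "t_w", "t_h")]) + 0.2
  batch <- loss_batch(conf, loc, m, census)
  plain <- combined_loss(batch, loss_config())
  cb <- class_balanced_objective(batch, loss_config(reweight = reweight_config("class_balanced", beta = 2)))
  expect_equal(cb$classification, plain$classification / 7)
  expect_equal(cb$localization, plain$localization / 7)
  cb0 <- class_balanced_objective(batch, loss_config(alpha = 0, reweight = reweight_config("class_balanced", beta = 2)))
  expect_equal(cb0$total, cb0$classification)
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches hand values", {
  withr::with_seed(44, {
    fx <- random_loss_fixture()
    cfg0 <- loss_config(focal_gamma = 0)
    expect_equal(focal_loss(fx$batch, cfg0), classification_loss(fx$batch, cfg0))
  })
  # single contributing sample at p_true = 0.5, gamma = 2
  grid <- small_grid()
  gt <- dplyr::mutate(grid[3, 1:4], class = "spA")
  m <- match_boxes(gt, grid)
  conf <- matrix(0, nrow(grid), 2, dimnames = list(NULL, c("spA", "background")))
  conf[, "background"] <- 1
  pos <- which(m$class != "background")
  conf[pos, ] <- 0.5
  loc <- matrix(0, nrow(grid), 4)
  batch <- loss_batch(conf, loc, m)
  N <- n_matched(m)
  expect_equal(focal_loss(batch, loss_config(focal_gamma = 2)),
               N * 0.25 * log(2) / N)
  # perfect confidence gives zero focal loss
  pb <- perfect_batch(m, "spA")
  expect_equal(focal_loss(pb, loss_config(focal_gamma = 2)), 0)
})

test_that("reweighting rescales but never changes the contributing set", {
  withr::with_seed(45, {
    fx <- random_loss_fixture()
    cfg <- loss_config()
    parts_by_scheme <- lapply(c("none", "class_aware", "class_balanced", "focal"),
      function(sch) {
        cfgs <- loss_config(reweight = reweight_config(sch))
        ltdetect:::loss_parts(fx$batch, cfgs)$contributing
      })
    for (p in parts_by_scheme[-1]) expect_identical(p, parts_by_scheme[[1]])
  })
})

test_that("increasing a matched residual never decreases localization loss", {
  withr::with_seed(46, {
    fx <- random_loss_fixture()
    pos <- which(fx$match$class != "background")
    base <- localization_loss(fx$batch)
    for (i in pos) {
      loc2 <- fx$loc
      tgt <- as.numeric(fx$match[i, c("t_cx", "t_cy", "t_w", "t_h")])
      loc2[i, ] <- tgt + (loc2[i, ] - tgt) * 2   # double the residual
      b2 <- loss_batch(fx$conf, loc2, fx$match, fx$census)
      expect_gte(localization_loss(b2), base)
    }
  })
})

test_that("a species missing from the census is reported by name", {
  withr::with_seed(47, {
    fx <- random_loss_fixture()
    census <- class_census(c(spA = 5))  # missing spB/spC
    batch <- loss_batch(fx$conf, fx$loc, fx$match, census)
    expect_error(
      class_aware_loss(batch, loss_config(reweight = reweight_config("class_aware"))),
      "sp[BC]")
  })
})

test_that("analytic loss gradients agree with finite differences", {
  withr::with_seed(48, {
    fx <- random_loss_fixture()
    logits <- matrix(rnorm(nrow(fx$conf) * ncol(fx$conf)), nrow(fx$conf))
    colnames(logits) <- colnames(fx$conf)
    for (sch in c("none", "class_aware", "class_balanced", "focal")) {
      cfg <- loss_config(reweight = reweight_config(sch))
      lg <- ltdetect:::multibox_loss_grad(logits, fx$loc, fx$match, fx$census, cfg)
      loss_at <- function(lg2, lc2) {
        ltdetect:::multibox_loss_grad(lg2, lc2, fx$match, fx$census, cfg)$loss$total
      }
      eps <- 1e-6
      # probe random logit and loc entries, avoiding mining-boundary flips
      for (probe in 1:5) {
        i <- sample(nrow(logits), 1); j <- sample(ncol(logits), 1)
        lp <- logits; lp[i, j] <- lp[i, j] + eps
        lm <- logits; lm[i, j] <- lm[i, j] - eps
        fd <- (loss_at(lp, fx$loc) - loss_at(lm, fx$loc)) / (2 * eps)
        expect_equal(unname(lg$dlogits[i, j]), fd, tolerance = 1e-4)
      }
      pos <- which(fx$match$class != "background")
      for (probe in 1:5) {
        i <- sample(pos, 1); j <- sample(4, 1)
        lp <- fx$loc; lp[i, j] <- lp[i, j] + eps
        lm <- fx$loc; lm[i, j] <- lm[i, j] - eps
        fd <- (loss_at(logits, lp) - loss_at(logits, lm)) / (2 * eps)
        expect_equal(lg$dloc[i, j], fd, tolerance = 1e-4)
      }
    }
  })
})
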