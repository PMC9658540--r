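test_that("long-tail census sampling is flat at exponent 0 and seeded", {
  spec0 <- scene_spec(num_species = 10, zipf_exponent = 0, seed = 3)
  cen <- sample_long_tail_counts(spec0, total_instances = 10000)
  expect_equal(census_total(cen), 10000L)
  expect_lt(max(cen$count) / min(cen$count), 2)

  spec <- scene_spec(seed = 5)
  c1 <- sample_long_tail_counts(spec, 500)
  c2 <- sample_long_tail_counts(spec, 500)
  expect_identical(c1$count, c2$count)
  expect_true(all(c1$count >= 1))
})

test_that("sampled counts follow the requested rank-frequency slope", {
  spec <- scene_spec(num_species = 8, zipf_exponent = 1.5, seed = 9)
  cen <- sample_long_tail_counts(spec, 2000)
  fit <- stats::lm(log(count) ~ log(rank),
                   data = data.frame(rank = seq_len(8), count = cen$count))
  expect_lt(abs(unname(stats::coef(fit)[2]) - (-1.5)), 0.2)
})

test_that("rendered scenes are deterministic with in-bounds annotated objects", {
  spec <- scene_spec(seed = 13)
  s1 <- render_scene(spec, c("sp01", "sp03", "sp07"), seed = 99)
  s2 <- render_scene(spec, c("sp01", "sp03", "sp07"), seed = 99)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$objects, s2$objects)
  expect_equal(nrow(s1$objects), 3)
  corners <- center_to_corner(s1$objects)
  expect_true(all(corners$xmin >= 0 & corners$xmax <= 1 &
                    corners$ymin >= 0 & corners$ymax <= 1))
  expect_true(all(s1$objects$w * spec$image_size >= 8))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
})

test_that("full-contrast noiseless objects differ from the background", {
  spec <- scene_spec(contrast = 1, noise_sd = 0, seed = 17)
  s <- render_scene(spec, "sp02", seed = 4)
  b <- center_to_corner(s$objects)
  S <- spec$image_size
  xs <- (round(b$xmin * S) + 1):round(b$xmax * S)
  ys <- (round(b$ymin * S) + 1):round(b$ymax * S)
  # compare per channel: hue shifts can cancel in a grand mean
  inside <- apply(s$image[ys, xs, , drop = FALSE], 3, mean)
  bg <- apply(s$image[1:5, 1:5, , drop = FALSE], 3, mean)
  expect_gt(max(abs(inside - bg)), 0.05)
})

test_that("dataset generation writes the documented split sizes", {
  spec <- scene_spec(seed = 23)
  dir <- withr::local_tempdir()
  idx <- generate_dataset(spec, 20, dir)
  expect_equal(unname(table(idx$split)[c("train", "val", "test")]),
               c(14L, 3L, 3L), ignore_attr = TRUE)
  splits <- lapply(c("train", "val", "test"), function(s) {
    readLines(file.path(dir, "ImageSets", "Main", paste0(s, ".txt")))
  })
  expect_equal(lengths(splits), c(14L, 3L, 3L))
  expect_equal(sort(unlist(splits)), sort(idx$image_id))

  # floor-then-remainder-to-test rule at total 10: 7 / 1 / 2
  dir2 <- withr::local_tempdir()
  idx2 <- generate_dataset(scene_spec(seed = 24), 10, dir2)
  expect_equal(unname(table(idx2$split)[c("train", "val", "test")]),
               c(7L, 1L, 2L), ignore_attr = TRUE)
})

test_that("training census equals the object records of training XMLs", {
  spec <- scene_spec(seed = 29)
  dir <- withr::local_tempdir()
  idx <- generate_dataset(spec, 20, dir)
  census <- read_census_csv(file.path(dir, "census.csv"))
  train_ids <- idx$image_id[idx$split == "train"]
  objs <- unlist(lapply(train_ids, function(id) {
    read_voc_annotation(file.path(dir, "Annotations", paste0(id, ".xml")))$class
  }))
  expect_equal(census_total(census), length(objs))
  expect_equal(sort(census$species), sort(names(table(objs))))
  expect_equal(census$count[order(census$species)],
               unname(as.integer(table(objs))))
})

test_that("generation is byte-reproducible under the same seed", {
  spec <- scene_spec(seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(spec, 10, d1)
  generate_dataset(spec, 10, d2)
  for (f in list.files(file.path(d1, "Annotations"))) {
    expect_identical(readLines(file.path(d1, "Annotations", f)),
                     readLines(file.path(d2, "Annotations", f)))
  }
  f1 <- file.path(d1, "JPEGImages", "img00001.png")
  f2 <- file.path(d2, "JPEGImages", "img00001.png")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("forced double flip is the identity on boxes", {
  spec <- scene_spec(seed = 37)
  s <- render_scene(spec, c("sp01", "sp02"), seed = 1)
  once <- augment(s$image, s$objects, seed = 2, crop = FALSE,
                  photometric = FALSE, flip_prob = 1)
  twice <- augment(once$image, once$boxes, seed = 3, crop = FALSE,
                   photometric = FALSE, flip_prob = 1)
  expect_equal(twice$boxes, s$objects)
  expect_identical(twice$image, s$image)
})

test_that("photometric-only augmentation leaves boxes bit-identical", {
  spec <- scene_spec(seed = 41)
  s <- render_scene(spec, c("sp04", "sp05"), seed = 1)
  out <- augment(s$image, s$objects, seed = 7, crop = FALSE, flip = FALSE,
                 photometric = TRUE)
  expect_identical(out$boxes, s$objects)
  expect_false(identical(out$image, s$image))
  expect_true(all(out$image >= 0 & out$image <= 1))
  # deterministic under seed
  out2 <- augment(s$image, s$objects, seed = 7, crop = FALSE, flip = FALSE,
                  photometric = TRUE)
  expect_identical(out$image, out2$image)
})

test_that("cropping keeps only boxes whose center lies in the window", {
  # synthetic annotated image: two boxes, left and right halves
  img <- array(0.5, dim = c(64, 64, 3))
  boxes <- dplyr::mutate(
    boxes_tbl(cx = c(0.2, 0.8), cy = c(0.5, 0.5), w = c(0.2, 0.2), h = c(0.2, 0.2)),
    class = c("left", "right"))
  # force a crop of the left half by trying seeds until the window lands there
  hit <- FALSE
  for (seed in 1:200) {
    out <- augment(img, boxes, seed = seed, flip = FALSE, photometric = FALSE)
    if (ncol(out$image) < 60 && "left" %in% out$boxes$class &&
        !"right" %in% out$boxes$class) { hit <- TRUE; break }
  }
  expect_true(hit)
  # crops never return zero boxes when any box existed
  for (seed in 1:20) {
    out <- augment(img, boxes, seed = seed, flip = FALSE, photometric = FALSE)
    expect_gt(nrow(out$boxes), 0)
  }
})
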