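test_that("geometric transforms are exact pixel permutations", {
  img <- gradient_image(16, 16)
  expect_identical(apply_geometric(img, 0, "none"), img)
  # group property: four quarter turns restore the original
  r <- img
  for (i in 1:4) r <- apply_geometric(r, 90)
  expect_identical(r, img)
  # corner pixel after a half turn lands in the opposite corner
  big <- gradient_image(256, 256)
  rot <- apply_geometric(big, 180)
  expect_equal(rot[256, 256, ], big[1, 1, ])
  expect_equal(rot[1, 1, ], big[256, 256, ])
  # permutation: multiset of pixel values unchanged for every family member
  for (rotation in c(0, 90, 180, 270)) {
    for (flip in c("none", "horizontal")) {
      out <- apply_geometric(img, rotation, flip)
      expect_identical(sort(as.vector(out)), sort(as.vector(img)))
    }
  }
  expect_error(apply_geometric(gradient_image(8, 16), 90), "square")
  expect_error(apply_geometric(img, 45), "rotation")
})

test_that("color gains scale channels and clip at 255", {
  img <- constant_image(4, 4, c(100, 50, 50))
  expect_identical(apply_color_gain(img, c(1, 1, 1)), img)
  out <- apply_color_gain(img, c(2, 1, 1))
  expect_equal(out[1, 1, ], c(200, 50, 50))
  hot <- constant_image(4, 4, c(200, 0, 0))
  expect_equal(apply_color_gain(hot, c(2, 1, 1))[1, 1, ], c(255, 0, 0))
  expect_error(apply_color_gain(img, c(0, 1, 1)), "positive")
})

test_that("spatial filters behave as blur and unsharp mask", {
  flat <- constant_image(9, 9)
  expect_equal(apply_filter(flat, "gaussian", sigma = 1), flat)
  expect_equal(apply_filter(flat, "edge_enhance", sigma = 1), flat)
  expect_identical(apply_filter(flat, "identity"), flat)
  expect_error(apply_filter(flat, "median"), "unknown filter")

  # impulse response: center value equals the normalized 2-D kernel's peak
  imp <- array(0, dim = c(9, 9, 3))
  imp[5, 5, ] <- 1
  out <- apply_filter(imp, "gaussian", sigma = 1)
  r <- ceiling(3 * 1)
  g2 <- outer(exp(-(-r:r)^2 / 2), exp(-(-r:r)^2 / 2))
  g2 <- g2 / sum(g2)
  expect_equal(out[5, 5, 1], max(g2), tolerance = 1e-12)

  # blur preserves mean intensity away from clipping (kernel sums to 1)
  set.seed(1)
  noisy <- array(runif(16 * 16 * 3, 50, 200), dim = c(16, 16, 3))
  blurred <- apply_filter(noisy, "gaussian", sigma = 1.5)
  expect_equal(mean(blurred), mean(noisy), tolerance = 1e-10)
})

test_that("variant enumeration is the Cartesian product with identity first", {
  img <- gradient_image(8, 8)
  cfg <- augment_config(color_gains = list(c(1, 1, 1)),
                        target_count_per_class = NULL)
  v <- enumerate_variants(img, cfg)
  expect_length(v, 4 * 2 * 1 * 3)                 # 24 variants
  descs <- vapply(v, function(x) paste(x$descriptor$rotation,
                                       x$descriptor$flip,
                                       paste(x$descriptor$gains,
                                             collapse = ":"),
                                       x$descriptor$filter), character(1))
  expect_equal(anyDuplicated(descs), 0L)
  expect_true(cytogan:::is_identity_descriptor(v[[1]]$descriptor))
  expect_identical(v[[1]]$image, img)

  idcfg <- augment_config(rotations = 0, flips = "none",
                          color_gains = list(c(1, 1, 1)),
                          filters = "identity")
  vid <- enumerate_variants(img, idcfg)
  expect_length(vid, 1L)
  expect_identical(vid[[1]]$image, img)

  expect_error(augment_config(rotations = c(90, 180)), "identity")
})

test_that("the augmented set hits the target exactly, originals included", {
  # descriptor-level planning on the study-sized benign set
  man <- fake_manifest(391)
  cfg <- augment_config(target_count_per_class = 10000L, seed = 4)
  aug <- build_augmented_set(man, cfg)
  expect_equal(nrow(aug), 10000L)
  expect_equal(sum(aug$filter == "identity" & aug$rotation == 0 &
                     aug$flip == "none" & aug$gains == "1:1:1"), 391L)
  # every original appears exactly once untransformed
  expect_setequal(aug$origin_path[aug$filter == "identity" &
                                    aug$rotation == 0 &
                                    aug$flip == "none" &
                                    aug$gains == "1:1:1"], man$path)
  # no duplicated (source, descriptor) pairs
  key <- paste(aug$origin_path, aug$rotation, aug$flip, aug$gains,
               aug$filter)
  expect_equal(anyDuplicated(key), 0L)
  # determinism
  aug2 <- build_augmented_set(man, cfg)
  expect_equal(aug, aug2)
})

test_that("degenerate targets and capacity violations are handled", {
  man <- fake_manifest(10, 10)
  cfg <- augment_config(target_count_per_class = 10L)
  aug <- build_augmented_set(man, cfg)
  expect_equal(nrow(aug), 20L)
  expect_true(all(aug$filter == "identity"))
  expect_equal(aug$path, man$path)

  expect_error(build_augmented_set(
    man, augment_config(target_count_per_class = 9L)), "must lie between")
  expect_error(build_augmented_set(
    man, augment_config(rotations = 0, flips = "none",
                        color_gains = list(c(1, 1, 1)),
                        filters = "identity",
                        target_count_per_class = 11L)), "must lie between")
})

test_that("rendered augmented images are written and transformed", {
  dir <- withr::local_tempdir()
  spec <- synthetic_dataset_spec(n_per_class = 3, image_size = 32, seed = 2)
  man <- generate_dataset(spec, dir)
  out <- file.path(dir, "aug")
  cfg <- augment_config(target_count_per_class = 6L, seed = 1)
  aug <- build_augmented_set(man, cfg, out_dir = out)
  expect_equal(nrow(aug), 12L)
  variants <- aug[aug$filter != "identity" | aug$rotation != 0 |
                    aug$flip != "none" | aug$gains != "1:1:1", ]
  expect_true(all(file.exists(variants$path)))
  img <- load_image(variants$path[1])
  expect_equal(dim(img), c(32L, 32L, 3L))
})
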