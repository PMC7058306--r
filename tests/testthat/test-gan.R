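test_that("the growth schedule doubles resolution with the standard widths", {
  sch <- stage_schedule(256)
  expect_equal(sch$resolutions, c(4L, 8L, 16L, 32L, 64L, 128L, 256L))
  expect_equal(sch$feature_maps, c(512L, 512L, 512L, 256L, 128L, 64L, 32L))
  expect_error(stage_schedule(100), "power of 2")
  expect_error(stage_schedule(16, feature_maps = c(8L, 8L)), "one channel")
})

test_that("the generator starts at 4x4 and doubles at each grown stage", {
  sch <- stage_schedule(16, feature_maps = c(16L, 16L, 16L),
                        epochs_per_stage = 1L)
  b <- build_pggan(sch, latent_spec(8L), seed = 1)
  expect_equal(gan_resolution(b), 4L)
  s0 <- sample_images(b, 2, seed = 1)
  expect_equal(dim(s0[[1]]), c(4L, 4L, 3L))
  b <- grow_stage(b)
  expect_equal(dim(sample_images(b, 1, seed = 1)[[1]]), c(8L, 8L, 3L))
  b <- grow_stage(b)
  expect_equal(dim(sample_images(b, 1, seed = 1)[[1]]), c(16L, 16L, 3L))
  expect_error(grow_stage(b), "final resolution")
})

test_that("a full-depth bundle reaches 256x256 through 7 stages", {
  b <- build_pggan(stage_schedule(256), latent_spec(128L), seed = 1)
  expect_length(b$schedule$resolutions, 7L)
  b$stage <- 7L
  img <- sample_images(b, 1, seed = 3)[[1]]
  expect_equal(dim(img), c(256L, 256L, 3L))
  expect_true(all(img >= 0 & img <= 255))
})

test_that("fade-in alpha ramps linearly and clamps to [0, 1]", {
  expect_equal(fade_in_alpha(0, 100), 0)
  expect_equal(fade_in_alpha(50, 100), 0.5)
  expect_equal(fade_in_alpha(100, 100), 1)
  expect_equal(fade_in_alpha(500, 100), 1)
  a <- fade_in_alpha(0:300, 200)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(fade_in_alpha(-1, 10), "non-negative")
  expect_error(fade_in_alpha(5, 0), ">= 1")
})

test_that("Wasserstein losses follow the critic/generator formulas", {
  same <- wasserstein_losses(c(1, 2, 3), c(1, 2, 3), 0)
  expect_equal(same$d_loss, 0)
  expect_equal(wasserstein_losses(c(1, 1), c(0, 0), 0)$d_loss, -1)
  expect_equal(wasserstein_losses(c(1, 1), c(0, 0), 0)$g_loss, 0)
  expect_equal(wasserstein_losses(rnorm(5), c(0, 0, 0), 0)$g_loss, 0)
  # closed form on fixed vectors, with penalty
  r <- c(0.3, 0.7, 1.1)
  f <- c(-0.2, 0.4, 0.1)
  wl <- wasserstein_losses(r, f, gradient_penalty = 0.25, gp_weight = 10)
  expect_equal(wl$d_loss, mean(f) - mean(r) + 10 * 0.25)
  expect_equal(wl$g_loss, -mean(f))
  expect_error(wasserstein_losses(numeric(0), 1), "non-empty")
})

test_that("sliced Wasserstein distance is a pseudometric matching the 1-D oracle", {
  set.seed(2)
  a <- matrix(rnorm(40 * 6), 40, 6)
  expect_equal(sliced_wasserstein_distance(a, a), 0)
  b <- matrix(rnorm(40 * 6, mean = 1), 40, 6)
  ab <- sliced_wasserstein_distance(a, b, seed = 9)
  ba <- sliced_wasserstein_distance(b, a, seed = 9)
  expect_gt(ab, 0)
  expect_equal(ab, ba)
  # 1-D data: every unit projection is +/- 1, so SWD equals the sorted
  # mean-absolute-difference oracle exactly
  x <- matrix(c(0, 1), 2, 1)
  y <- matrix(c(2, 3), 2, 1)
  expect_equal(sliced_wasserstein_distance(x, y, n_projections = 1,
                                           seed = 1), 2.0, tolerance = 1e-9)
  for (s in 1:5) {
    set.seed(s)
    u <- matrix(rnorm(17), 17, 1)
    v <- matrix(rnorm(17, sd = 2), 17, 1)
    expect_equal(sliced_wasserstein_distance(u, v, n_projections = 32,
                                             seed = s),
                 wasserstein_1d(u, v), tolerance = 1e-9)
  }
  expect_error(sliced_wasserstein_distance(a, b[1:10, ]), "equal")
})

test_that("two-stage progressive training completes deterministically", {
  imgs <- rendered_set("benign", n = 16L, size = 16L, seed0 = 700L)
  sch <- stage_schedule(8, feature_maps = c(8L, 8L), epochs_per_stage = 2L)
  cfg <- gan_train_config(minibatch = 8L, seed = 3)
  b1 <- train_pggan(build_pggan(sch, latent_spec(8L), seed = 3), imgs, cfg,
                    swd_samples = 8L)
  expect_equal(nrow(b1$log), 2L)
  expect_equal(b1$log$resolution, c(4L, 8L))
  expect_true(all(is.finite(b1$log$swd)))
  expect_true(all(b1$log$gradient_penalty >= 0))
  s <- sample_images(b1, 2, seed = 5)
  expect_equal(dim(s[[1]]), c(8L, 8L, 3L))
  expect_length(b1$checkpoints, 2L)

  b2 <- train_pggan(build_pggan(sch, latent_spec(8L), seed = 3), imgs, cfg,
                    swd_samples = 8L)
  expect_identical(lapply(b1$generator, cytogan:::net_params),
                   lapply(b2$generator, cytogan:::net_params))
  expect_identical(sample_images(b1, 2, seed = 5), s)

  # seeded sampling is deterministic but different seeds differ
  expect_false(identical(sample_images(b1, 1, seed = 1),
                         sample_images(b1, 1, seed = 2)))
  small <- lapply(rendered_set("benign", 4L, 32L), function(x) x)
  expect_error(train_pggan(build_pggan(stage_schedule(
    64, feature_maps = rep(8L, 5L), epochs_per_stage = 1L),
    latent_spec(4L)), small, cfg), "at least 64")
})

test_that("trained samples are closer to the real set than a noise baseline", {
  # stochastic, asserted with margin: after training, the generated
  # distribution beats uniform noise under the sliced Wasserstein metric
  real <- rendered_set("malignant", 32L, 16L, seed0 = 200L)
  sch <- stage_schedule(8, feature_maps = c(16L, 16L),
                        epochs_per_stage = 30L)
  b <- train_pggan(build_pggan(sch, latent_spec(16L),
                               class_tag = "malignant", seed = 2),
                   real, gan_train_config(minibatch = 16L, seed = 2),
                   swd_samples = 32L)
  fake <- sample_images(b, 32, seed = 7)
  real8 <- lapply(real, function(im) cytogan:::tensor_to_img8(
    cytogan:::downsample_to(cytogan:::img8_to_tensor(list(im)), 8L))[[1]])
  set.seed(2)
  noise <- lapply(1:32, function(k) array(runif(192, 0, 255), c(8, 8, 3)))
  swd_fake <- swd_images(real8, fake, seed = 2)
  swd_noise <- swd_images(real8, noise, seed = 2)
  expect_lt(swd_fake, swd_noise)
})

test_that("the DCGAN baseline has 5+4 generator and 6+1 discriminator layers", {
  b <- build_dcgan(latent_spec(128L), resolution = 256L,
                   g_feature_maps = c(16L, 16L, 8L, 8L),
                   d_feature_maps = c(4L, 4L, 8L, 8L, 16L, 16L), seed = 2)
  counts <- dcgan_layer_counts(b)
  expect_equal(counts$g_conv, 5L)
  expect_equal(counts$g_scale, 4L)
  expect_equal(counts$d_conv, 6L)
  expect_equal(counts$d_output, 1L)
  img <- sample_images(b, 1, seed = 4)[[1]]
  expect_equal(dim(img), c(256L, 256L, 3L))
  expect_identical(img, sample_images(b, 1, seed = 4)[[1]])
})

test_that("DCGAN training runs at reduced scale and scores real vs fake", {
  imgs <- lapply(rendered_set("benign", 12L, 32L),
                 cytogan:::resize_nearest, size = 64L)
  b <- build_dcgan(latent_spec(8L), resolution = 64L,
                   g_feature_maps = c(8L, 8L, 8L, 8L),
                   d_feature_maps = rep(4L, 6L), seed = 1)
  bt <- train_dcgan(b, imgs, epochs = 2L,
                    config = gan_train_config(learning_rate = 2e-4,
                                              beta1 = 0.5, minibatch = 6L,
                                              seed = 1))
  expect_true(is.finite(bt$log$d_loss))
  expect_equal(dim(sample_images(bt, 1, seed = 1)[[1]]), c(64L, 64L, 3L))
})

test_that("gan checkpoints survive a save/load round trip", {
  sch <- stage_schedule(4, feature_maps = 8L, epochs_per_stage = 1L)
  b <- build_pggan(sch, latent_spec(4L), seed = 6)
  f <- withr::local_tempfile(fileext = ".rds")
  save_gan(b, f)
  b2 <- load_gan(f)
  expect_identical(sample_images(b, 3, seed = 8),
                   sample_images(b2, 3, seed = 8))
})
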