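test_that("the VGG-16 head replaces the original fully connected layers", {
  cfg <- backbone_config("vgg16", input_size = 256)
  model <- build_classifier(cfg, seed = 1)
  dense <- Filter(function(l) l$type == "dense", model$net$layers)
  expect_length(dense, 3L)
  # after five poolings a 256 input leaves an 8x8x512 map
  expect_equal(dim(dense[[1]]$w), c(1024L, 8L * 8L * 512L))
  expect_equal(dim(dense[[2]]$w), c(256L, 1024L))
  expect_equal(dim(dense[[3]]$w), c(2L, 256L))
  convs <- Filter(function(l) l$type == "conv", model$net$layers)
  expect_length(convs, 13L)
  groups <- cytogan:::net_param_groups(model$net)
  expect_setequal(unique(groups[groups != ""]), c("conv", "head"))
})

test_that("the tiny backbone runs forward and outputs class probabilities", {
  model <- build_classifier(backbone_config("vgg_tiny"), seed = 1)
  imgs <- rendered_set("benign", 4L, 32L)
  preds <- predict_patches(model, list(images = imgs))
  expect_equal(nrow(preds), 4L)
  expect_true(all(preds$score >= 0 & preds$score <= 1))
  # duplicate patch scores identically (deterministic inference)
  dup <- predict_patches(model, list(images = imgs[c(1, 1)]))
  expect_equal(dup$score[1], dup$score[2])
  expect_error(backbone_config("vgg_tiny", input_size = 4), "too small")
  expect_error(backbone_config("vgg16", head_units = c(10, 5, 3)),
               "2 units")
})

test_that("pretraining updates every layer and learns separable data", {
  model <- build_classifier(backbone_config("vgg_tiny"), seed = 2)
  data <- list(images = c(rendered_set("benign", 16L, 32L),
                          rendered_set("malignant", 16L, 32L, seed0 = 900L)),
               labels = rep(c("benign", "malignant"), each = 16))
  plan <- two_step_plan(pretrain_epochs = 15L, learning_rate = 3e-4,
                        minibatch = 16L, seed = 2)
  before <- cytogan:::net_params(model$net)
  fit <- pretrain(model, data, plan)
  after <- cytogan:::net_params(fit$net)
  groups <- cytogan:::net_param_groups(fit$net)
  changed <- mapply(function(a, b) !identical(a, b), before, after)
  # both conv and head parameters moved
  expect_true(any(changed[grep("conv", names(before))]))
  expect_true(any(changed[grep("dense", names(before))]))
  # training loss falls from its initial epoch
  expect_lt(tail(fit$loss_curve, 1), fit$loss_curve[1])
  # determinism: same seed gives identical parameters
  fit2 <- pretrain(model, data, plan)
  expect_identical(cytogan:::net_params(fit$net),
                   cytogan:::net_params(fit2$net))
  expect_error(pretrain(model, list(images = list(), labels = character(0)),
                        plan), "empty")
})

test_that("fine-tuning freezes every convolutional parameter bitwise", {
  model <- build_classifier(backbone_config("vgg_tiny"), seed = 3)
  data <- list(images = c(rendered_set("benign", 8L, 32L),
                          rendered_set("malignant", 8L, 32L, seed0 = 900L)),
               labels = rep(c("benign", "malignant"), each = 8))
  plan <- two_step_plan(finetune_epochs = 3L, learning_rate = 3e-4,
                        minibatch = 8L, seed = 3)
  tuned <- fine_tune(model, data, plan)
  conv_idx <- which(vapply(model$net$layers, function(l)
    identical(l$group, "conv"), logical(1)))
  for (i in conv_idx) {
    expect_identical(tuned$net$layers[[i]]$w, model$net$layers[[i]]$w)
    expect_identical(tuned$net$layers[[i]]$b, model$net$layers[[i]]$b)
  }
  head_idx <- which(vapply(model$net$layers, function(l)
    identical(l$group, "head"), logical(1)))
  expect_false(identical(tuned$net$layers[[head_idx[1]]]$w,
                         model$net$layers[[head_idx[1]]]$w))
  # contrast: the same data with all groups trainable moves conv weights
  full <- pretrain(model, data,
                   two_step_plan(pretrain_epochs = 3L,
                                 learning_rate = 3e-4, minibatch = 8L,
                                 seed = 3))
  expect_false(identical(full$net$layers[[conv_idx[1]]]$w,
                         model$net$layers[[conv_idx[1]]]$w))
})

test_that("scores at the cut-off classify as malignant", {
  model <- build_classifier(backbone_config("vgg_tiny"), seed = 4)
  imgs <- rendered_set("benign", 3L, 32L)
  p <- predict_patches(model, list(images = imgs))
  # re-scoring with the cut-off placed exactly at an observed score must
  # label that patch malignant (ties go to malignant)
  p2 <- predict_patches(model, list(images = imgs), cutoff = p$score[2])
  expect_equal(p2$pred_label[2], "malignant")
})

test_that("pretraining on pure-noise images completes without error", {
  set.seed(9)
  noise <- lapply(1:8, function(i)
    array(runif(32 * 32 * 3, 0, 255), dim = c(32, 32, 3)))
  model <- build_classifier(backbone_config("vgg_tiny"), seed = 5)
  plan <- two_step_plan(pretrain_epochs = 1L, finetune_epochs = 1L,
                        learning_rate = 3e-4, minibatch = 8L, seed = 5)
  fit <- pretrain(model, list(images = noise,
                              labels = rep(c("benign", "malignant"), 4)),
                  plan)
  real <- list(images = rendered_set("benign", 4L, 32L),
               labels = rep("benign", 4))
  expect_no_error(fine_tune(fit, real, plan))
})

test_that("imagenet-style initialisation falls back loudly when offline", {
  cfg <- backbone_config("vgg_tiny", init = "imagenet_weights")
  expect_warning(model <- build_classifier(cfg, seed = 1),
                 "falling back to random")
  expect_equal(model$init_effective, "random")
  # a converted checkpoint round-trips through load_conv_weights
  donor <- build_classifier(backbone_config("vgg_tiny"), seed = 99)
  ws <- lapply(Filter(function(l) l$type == "conv", donor$net$layers),
               function(l) list(w = l$w, b = l$b))
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(ws, f)
  expect_no_warning(m2 <- build_classifier(cfg, seed = 1,
                                           weights_path = f))
  expect_equal(m2$init_effective, "imagenet_weights")
  convs <- which(vapply(m2$net$layers, function(l) l$type == "conv",
                        logical(1)))
  expect_identical(m2$net$layers[[convs[1]]]$w, ws[[1]]$w)
})

test_that("classifier checkpoints round-trip through save/load", {
  model <- build_classifier(backbone_config("vgg_tiny"), seed = 6)
  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(model, f)
  m2 <- load_classifier(f)
  imgs <- rendered_set("benign", 2L, 32L)
  expect_identical(predict_patches(model, list(images = imgs)),
                   predict_patches(m2, list(images = imgs)))
})
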