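#' Run a scaled-down two-step training experiment end to end
#'
#' Orchestrates the full pipeline on synthetic cytology data at desk scale:
#' renders seeded benign/malignant training and held-out patches, trains one
#' GAN per class on the training patches, samples synthetic images labeled
#' by their generating GAN's class, pretrains the whole classifier on them,
#' fine-tunes only the fully connected head on the real training patches,
#' and scores the held-out patches.
#'
#' With `pretraining = "none"` the pretraining step is skipped and only the
#' head is trained from random initialisation — the offline stand-in for the
#' generic-pretraining baseline (no bundled ImageNet weights are shipped).
#' `"dcgan"` uses the conventional single-resolution GAN baseline.
#'
#' Progressive GAN stages are trained up to `gan_stages` resolutions
#' (4 * 2^(gan_stages-1) pixels); generated samples are smoothly upsampled
#' to the classifier input size before pretraining (nearest-neighbour plus a
#' scale-matched Gaussian blur), so their smoothness statistics resemble the
#' focus-blurred real patches rather than hard pixel-replication blocks.
#'
#' @param seed master seed; all randomness derives from it.
#' @param pretraining `"pggan"`, `"dcgan"` or `"none"`.
#' @param image_size classifier input resolution (default 32).
#' @param n_real_per_class real training patches per class (default 60).
#' @param n_heldout_per_class held-out evaluation patches per class
#'   (default 30).
#' @param n_gan_per_class GAN samples per class for pretraining
#'   (default 150).
#' @param gan_stages progressive stages to train (default 2, i.e. up to
#'   8x8).
#' @param gan_epochs epochs per scaling step (default 20).
#' @param pretrain_epochs,finetune_epochs classifier epoch counts.
#' @param learning_rate classifier Adam learning rate for the desk-scale
#'   networks (default 3e-4; the full-scale protocol value 1e-6 is tuned to
#'   VGG-16-sized networks and pretrained starting points).
#' @param cutoff malignancy cut-off (default 0.5).
#' @return A list with `accuracy`, `auc`, `predictions`, `gan_log` (named
#'   per class; `NULL` when pretraining is `"none"`), and `model`.
#' @export
two_step_experiment <- function(seed = 1L,
                                pretraining = c("pggan", "none", "dcgan"),
                                image_size = 32L,
                                n_real_per_class = 60L,
                                n_heldout_per_class = 30L,
                                n_gan_per_class = 150L,
                                gan_stages = 2L,
                                gan_epochs = 20L,
                                pretrain_epochs = 8L,
                                finetune_epochs = 12L,
                                learning_rate = 3e-4,
                                cutoff = 0.5) {
  pretraining <- match.arg(pretraining)
  seed <- as.integer(seed)
  render_set <- function(n, params, seed0) {
    lapply(seq_len(n), function(i)
      render_patch(params, image_size, seed = seed0 + i)$image)
  }
  real <- list(
    benign = render_set(n_real_per_class, benign_render_params(),
                        seed * 10000L),
    malignant = render_set(n_real_per_class, malignant_render_params(),
                           seed * 10000L + 2000L))
  held <- list(
    benign = render_set(n_heldout_per_class, benign_render_params(),
                        seed * 10000L + 4000L),
    malignant = render_set(n_heldout_per_class, malignant_render_params(),
                           seed * 10000L + 6000L))

  model <- build_classifier(backbone_config("vgg_tiny",
                                            input_size = image_size),
                            seed = seed)
  plan <- two_step_plan(pretrain_epochs = pretrain_epochs,
                        finetune_epochs = finetune_epochs,
                        learning_rate = learning_rate,
                        minibatch = 32L, seed = seed)
  gan_log <- NULL
  if (pretraining != "none") {
    gan_imgs <- list()
    gan_log <- list()
    for (cls in c("benign", "malignant")) {
      cls_seed <- seed + if (cls == "benign") 0L else 500L
      if (pretraining == "pggan") {
        sch <- stage_schedule(4L * 2L^(gan_stages - 1L),
                              feature_maps = rep(32L, gan_stages),
                              epochs_per_stage = gan_epochs)
        bundle <- build_pggan(sch, latent_spec(64L), class_tag = cls,
                              seed = cls_seed)
        bundle <- train_pggan(bundle, real[[cls]],
                              gan_train_config(minibatch = 16L,
                                               seed = cls_seed),
                              swd_samples = min(32L, n_real_per_class))
        gan_log[[cls]] <- bundle$log
      } else {
        bundle <- build_dcgan(latent_spec(64L), resolution = 64L,
                              g_feature_maps = c(32L, 24L, 16L, 12L),
                              d_feature_maps = c(8L, 12L, 16L, 24L, 32L,
                                                 32L),
                              class_tag = cls, seed = cls_seed)
        small <- lapply(real[[cls]], resize_nearest, size = 64L)
        bundle <- train_dcgan(bundle, small, epochs = gan_epochs,
                              config = gan_train_config(
                                learning_rate = 2e-4, beta1 = 0.5,
                                beta2 = 0.999, minibatch = 16L,
                                seed = cls_seed))
        gan_log[[cls]] <- bundle$log
      }
      gan_imgs[[cls]] <- lapply(
        sample_images(bundle, n_gan_per_class, seed = cls_seed + 9L),
        upscale_smooth, size = image_size)
    }
    model <- pretrain(model, list(
      images = c(gan_imgs$benign, gan_imgs$malignant),
      labels = rep(c("benign", "malignant"),
                   times = c(length(gan_imgs$benign),
                             length(gan_imgs$malignant)))), plan)
  }
  model <- fine_tune(model, list(
    images = c(real$benign, real$malignant),
    labels = rep(c("benign", "malignant"), each = n_real_per_class)), plan)
  preds <- predict_patches(model, list(
    images = c(held$benign, held$malignant),
    labels = rep(c("benign", "malignant"), each = n_heldout_per_class)),
    cutoff = cutoff)
  list(accuracy = mean(preds$pred_label == preds$true_label),
       auc = roc_auc(preds)$auc,
       predictions = preds, gan_log = gan_log, model = model)
}
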