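#' Backbone configuration for the patch classifier
#'
#' A VGG-style convolutional stack with a new three-layer fully connected
#' head of 1024, 256 and 2 units replacing the original fully connected
#' layers; the 2-unit softmax outputs benign/malignant probabilities. Two
#' families are available behind the same interface: `vgg16` (the full
#' 13-convolution backbone, 224/256-pixel inputs) and `vgg_tiny`, a
#' width/depth-reduced backbone with the same block structure for
#' desk-scale work (three blocks, 32-pixel inputs, smaller head).
#'
#' @param family `"vgg_tiny"` or `"vgg16"`.
#' @param input_size input side length in pixels; must be divisible by
#'   `2^blocks`.
#' @param conv_blocks list of `c(n_convs, channels)` per block; defaults by
#'   family.
#' @param head_units three fully connected layer sizes ending in 2.
#' @param init `"random"` or `"imagenet_weights"`. Bundled weights are not
#'   shipped; `imagenet_weights` loads a user-supplied converted checkpoint
#'   via [load_conv_weights()] and otherwise falls back to random
#'   initialisation with a warning (recorded in the model as
#'   `init_effective`).
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(family = c("vgg_tiny", "vgg16"),
                            input_size = NULL, conv_blocks = NULL,
                            head_units = NULL,
                            init = c("random", "imagenet_weights")) {
  family <- match.arg(family)
  init <- match.arg(init)
  if (is.null(conv_blocks)) {
    conv_blocks <- if (family == "vgg16") {
      list(c(2L, 64L), c(2L, 128L), c(3L, 256L), c(3L, 512L), c(3L, 512L))
    } else {
      list(c(1L, 16L), c(1L, 32L), c(1L, 64L))
    }
  }
  if (is.null(head_units)) {
    head_units <- if (family == "vgg16") c(1024L, 256L, 2L) else
      c(64L, 32L, 2L)
  }
  if (is.null(input_size)) {
    input_size <- if (family == "vgg16") 256L else 32L
  }
  input_size <- as.integer(input_size)
  if (length(head_units) != 3L || head_units[3L] != 2L) {
    stop("head must be three fully connected layers ending in 2 units",
         call. = FALSE)
  }
  depth <- length(conv_blocks)
  if (input_size %% 2L^depth != 0L || input_size %/% 2L^depth < 1L) {
    stop("input_size too small for the pooling depth", call. = FALSE)
  }
  structure(list(family = family, input_size = input_size,
                 conv_blocks = conv_blocks,
                 head_units = as.integer(head_units), init = init),
            class = "backbone_config")
}

#' Build the patch classifier network
#'
#' Convolutional layers are tagged group `"conv"` and the fully connected
#' head group `"head"`; the two-step layer-freeze policy operates on these
#' tags. The final 2-unit layer feeds a softmax so outputs are class
#' probabilities summing to 1.
#'
#' @param config a [backbone_config()].
#' @param seed initialisation seed.
#' @param weights_path optional path to a converted conv-weight checkpoint
#'   for `init = "imagenet_weights"`.
#' @return An object of class `cyto_classifier`.
#' @export
build_classifier <- function(config = backbone_config(), seed = 1L,
                             weights_path = NULL) {
  stopifnot(inherits(config, "backbone_config"))
  with_seed(seed, {
    layers <- list()
    cin <- 3L
    res <- config$input_size
    for (b in config$conv_blocks) {
      for (i in seq_len(b[1L])) {
        layers <- c(layers, list(nn_conv(cin, b[2L], eqlr = FALSE,
                                         group = "conv"), nn_relu()))
        cin <- b[2L]
      }
      layers <- c(layers, list(nn_maxpool()))
      res <- res %/% 2L
    }
    flat <- res * res * cin
    hu <- config$head_units
    layers <- c(layers, list(
      nn_flatten(),
      nn_dense(flat, hu[1L], eqlr = FALSE, group = "head"), nn_relu(),
      nn_dense(hu[1L], hu[2L], eqlr = FALSE, group = "head"), nn_relu(),
      nn_dense(hu[2L], hu[3L], gain = 1, eqlr = FALSE, group = "head")))
    net <- nn_sequential(layers)
    init_effective <- "random"
    if (config$init == "imagenet_weights") {
      if (!is.null(weights_path) && file.exists(weights_path)) {
        net <- load_conv_weights(net, weights_path)
        init_effective <- "imagenet_weights"
      } else {
        warning("no converted checkpoint available; falling back to random ",
                "conv initialisation (recorded as init_effective = 'random')")
      }
    }
    structure(list(net = net, config = config,
                   init_effective = init_effective,
                   classes = c("benign", "malignant")),
              class = "cyto_classifier")
  })
}

#' Load convolutional weights from a converted checkpoint
#'
#' Reads an RDS list of `list(w, b)` pairs, one per convolutional layer in
#' network order, and copies them into the conv layers (shapes must match).
#'
#' @param net an `nn_sequential` network.
#' @param path RDS checkpoint path.
#' @return The network with replaced conv weights.
#' @export
load_conv_weights <- function(net, path) {
  ws <- readRDS(path)
  conv_idx <- which(vapply(net$layers, function(l)
    l$type == "conv", logical(1L)))
  if (length(ws) != length(conv_idx)) {
    stop("checkpoint has ", length(ws), " conv layers; network has ",
         length(conv_idx), call. = FALSE)
  }
  for (i in seq_along(conv_idx)) {
    l <- net$layers[[conv_idx[i]]]
    if (!all(dim(l$w) == dim(ws[[i]]$w))) {
      stop("conv layer ", i, " shape mismatch", call. = FALSE)
    }
    l$w <- ws[[i]]$w
    l$b <- ws[[i]]$b
    net$layers[[conv_idx[i]]] <- l
  }
  net
}

#' Two-step training plan
#'
#' Hyperparameters shared by both steps (minibatch 32, Adam with learning
#' rate 1e-6, beta1 0.9, beta2 0.999 in the full-scale protocol) plus the
#' layer-freeze policy: pretraining updates every layer, fine-tuning only
#' the fully connected head.
#'
#' @param pretrain_epochs,finetune_epochs epoch counts (exposed because the
#'   protocol fixes them only implicitly via validation behaviour).
#' @param learning_rate,beta1,beta2 Adam settings, identical across steps.
#' @param minibatch minibatch size.
#' @param seed integer seed.
#' @return An object of class `two_step_plan`.
#' @export
two_step_plan <- function(pretrain_epochs = 10L, finetune_epochs = 10L,
                          learning_rate = 1e-6, beta1 = 0.9, beta2 = 0.999,
                          minibatch = 32L, seed = 1L) {
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 minibatch = as.integer(minibatch), seed = as.integer(seed),
                 pretrain_trainable = c("conv", "head"),
                 finetune_trainable = "head"),
            class = "two_step_plan")
}

# Resolve training data: either list(images=list of img8, labels=chr) or a
# manifest data.frame whose `path` column points at PNG patches.
resolve_patch_data <- function(data, input_size) {
  if (is.data.frame(data)) {
    keep <- data$label %in% c("benign", "malignant")
    data <- data[keep, , drop = FALSE]
    if (nrow(data) == 0L) stop("no labeled patches in manifest",
                               call. = FALSE)
    imgs <- lapply(data$path, load_image)
    labels <- data$label
  } else {
    imgs <- data$images
    labels <- data$labels
    if (length(imgs) == 0L) stop("empty training data", call. = FALSE)
  }
  imgs <- lapply(imgs, function(im) {
    if (dim(im)[1L] != input_size) {
      im <- resize_nearest(im, input_size)
    }
    im
  })
  list(x = img8_to_tensor(imgs),
       y = ifelse(labels == "malignant", 2L, 1L))
}

# Nearest-neighbour resize of an img8 to a square target side.
resize_nearest <- function(img, size) {
  H <- dim(img)[1L]
  W <- dim(img)[2L]
  ri <- pmin(H, pmax(1L, round((seq_len(size) - 0.5) * H / size + 0.5)))
  ci <- pmin(W, pmax(1L, round((seq_len(size) - 0.5) * W / size + 0.5)))
  img[ri, ci, , drop = FALSE]
}

# Shared minibatch training loop with a trainable-group filter.
train_classifier_loop <- function(model, data, epochs, lr, beta1, beta2,
                                  minibatch, trainable_groups, seed) {
  x <- data$x
  y <- data$y
  n <- dim(x)[4L]
  mb <- min(minibatch, n)
  state <- adam_init(model$net)
  losses <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = mb)) {
        idx <- ord[start:min(start + mb - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        fw <- net_forward(model$net, xb, keep_cache = TRUE)
        sx <- softmax_xent(fw$y, y[idx])
        bw <- net_backward(model$net, sx$dz, fw$caches)
        up <- adam_step(model$net, bw$grads, state, lr = lr, beta1 = beta1,
                        beta2 = beta2, trainable_groups = trainable_groups)
        model$net <- up$net
        state <- up$state
        ep_loss <- ep_loss + sx$loss
        nb <- nb + 1L
      }
      losses <- c(losses, ep_loss / nb)
    }
  })
  model$loss_curve <- losses
  model
}

#' Pretrain the classifier on GAN-generated images (step one)
#'
#' Updates the weights of the entire network (conv stack and head) on
#' synthetic images labeled by the class of the GAN that generated them.
#'
#' @param model a `cyto_classifier`.
#' @param data a manifest data.frame (`path`, `label`) or a list with
#'   `images` (list of H x W x 3 arrays) and `labels`
#'   (`"benign"`/`"malignant"`).
#' @param plan a [two_step_plan()].
#' @return The trained model with `$loss_curve`.
#' @export
pretrain <- function(model, data, plan = two_step_plan()) {
  stopifnot(inherits(model, "cyto_classifier"),
            inherits(plan, "two_step_plan"))
  d <- resolve_patch_data(data, model$config$input_size)
  train_classifier_loop(model, d, plan$pretrain_epochs, plan$learning_rate,
                        plan$beta1, plan$beta2, plan$minibatch,
                        plan$pretrain_trainable, plan$seed)
}

#' Fine-tune only the fully connected head on real patches (step two)
#'
#' Convolutional parameters are frozen — bitwise unchanged after the call —
#' and only the head receives updates, with the same optimizer settings as
#' pretraining.
#'
#' @inheritParams pretrain
#' @return The fine-tuned model.
#' @export
fine_tune <- function(model, data, plan = two_step_plan()) {
  stopifnot(inherits(model, "cyto_classifier"),
            inherits(plan, "two_step_plan"))
  d <- resolve_patch_data(data, model$config$input_size)
  train_classifier_loop(model, d, plan$finetune_epochs, plan$learning_rate,
                        plan$beta1, plan$beta2, plan$minibatch,
                        plan$finetune_trainable, plan$seed + 1L)
}

#' Score patches with the classifier
#'
#' Deterministic inference: the malignancy score is the softmax probability
#' of the malignant unit; the predicted label is malignant when the score is
#' at or above the cut-off (ties classify as malignant, favouring
#' sensitivity in a screening setting).
#'
#' @param model a `cyto_classifier`.
#' @param data manifest or `list(images, labels)` (labels optional).
#' @param cutoff malignancy cut-off (default 0.5).
#' @param batch scoring batch size.
#' @return A data.frame of prediction records: `patch_id, score,
#'   pred_label, true_label`.
#' @export
predict_patches <- function(model, data, cutoff = 0.5, batch = 64L) {
  stopifnot(inherits(model, "cyto_classifier"))
  if (is.data.frame(data)) {
    ids <- if (all(nzchar(data$path))) data$path else seq_len(nrow(data))
    true <- if ("label" %in% names(data)) data$label else NA_character_
    d <- resolve_patch_data(data, model$config$input_size)
    keep <- data$label %in% c("benign", "malignant")
    ids <- ids[keep]
    true <- true[keep]
  } else {
    d <- resolve_patch_data(data, model$config$input_size)
    ids <- data$ids %||% seq_along(data$images)
    true <- if (!is.null(data$labels)) data$labels else NA_character_
  }
  n <- dim(d$x)[4L]
  scores <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- net_forward(model$net, d$x[, , , idx, drop = FALSE],
                      train = FALSE, keep_cache = FALSE)
    scores[idx] <- softmax_cols(fw$y)[2L, ]
  }
  data.frame(patch_id = as.character(ids), score = scores,
             pred_label = ifelse(scores >= cutoff, "malignant", "benign"),
             true_label = rep(true, length.out = n),
             stringsAsFactors = FALSE)
}

#' Save / load a classifier checkpoint
#' @param model a `cyto_classifier`.
#' @param path RDS file path.
#' @return `load_classifier` returns the model; `save_classifier` returns
#'   `path` invisibly.
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cyto_classifier"))
  model
}
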