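#' Progressive growth schedule
#'
#' The growth plan of a progressively grown GAN: square resolutions doubling
#' from 4 up to `max_resolution`, per-resolution feature-map counts, epochs
#' per scaling step, and the fraction of each step spent fading the new
#' block in. Default feature maps are 512 at 4-16 px, then 256, 128, 64 and
#' 32 at 32, 64, 128 and 256 px.
#'
#' @param max_resolution final square resolution (power of 2, >= 4).
#' @param feature_maps integer vector, one entry per resolution; default as
#'   above.
#' @param epochs_per_stage training epochs per scaling step (default 100).
#' @param fadein_fraction fraction of each stage spent blending in the new
#'   block (default 0.5).
#' @return An object of class `stage_schedule`.
#' @export
stage_schedule <- function(max_resolution = 256L, feature_maps = NULL,
                           epochs_per_stage = 100L, fadein_fraction = 0.5) {
  max_resolution <- as.integer(max_resolution)
  if (max_resolution < 4L ||
      bitwAnd(max_resolution, max_resolution - 1L) != 0L) {
    stop("max_resolution must be a power of 2 and >= 4", call. = FALSE)
  }
  res <- 4L
  resolutions <- integer(0)
  while (res <= max_resolution) {
    resolutions <- c(resolutions, res)
    res <- res * 2L
  }
  if (is.null(feature_maps)) {
    default_map <- c(`4` = 512L, `8` = 512L, `16` = 512L, `32` = 256L,
                     `64` = 128L, `128` = 64L, `256` = 32L)
    feature_maps <- unname(default_map[as.character(resolutions)])
  }
  feature_maps <- as.integer(feature_maps)
  if (length(feature_maps) != length(resolutions) || anyNA(feature_maps)) {
    stop("feature_maps must give one channel count per resolution",
         call. = FALSE)
  }
  stopifnot(epochs_per_stage >= 1L, fadein_fraction >= 0, fadein_fraction <= 1)
  structure(list(resolutions = resolutions, feature_maps = feature_maps,
                 epochs_per_stage = as.integer(epochs_per_stage),
                 fadein_fraction = fadein_fraction),
            class = "stage_schedule")
}

#' Latent input specification
#'
#' @param dimension latent dimensionality (default 128, standard normal).
#' @return An object of class `latent_spec`.
#' @export
latent_spec <- function(dimension = 128L) {
  dimension <- as.integer(dimension)
  if (dimension < 1L) stop("latent dimension must be >= 1", call. = FALSE)
  structure(list(dimension = dimension, distribution = "standard normal"),
            class = "latent_spec")
}

#' GAN training configuration
#'
#' Adam settings plus the Wasserstein-specific knobs. Progressive-GAN
#' defaults follow the study protocol: learning rate 0.001, beta1 0, beta2
#' 0.999. The discriminator's Lipschitz constraint is enforced by weight
#' clipping (`clip_weights`); `gp_weight` scales the gradient-penalty term
#' in the reported Wasserstein loss diagnostics.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param beta1,beta2 Adam moment decays in \[0, 1).
#' @param minibatch minibatch size at low resolutions; halved at 128 px and
#'   quartered at 256 px.
#' @param gp_weight gradient-penalty coefficient for loss reporting
#'   (default 10).
#' @param clip_weights discriminator weight-clipping bound (default 1.0,
#'   about half the unit initialisation scale used under equalized learning
#'   rate; clipping far below the initialisation scale collapses the critic
#'   to a near-constant function).
#' @param n_critic discriminator updates per generator update (default 1).
#' @param seed integer seed controlling all training randomness.
#' @return An object of class `gan_train_config`.
#' @export
gan_train_config <- function(learning_rate = 0.001, beta1 = 0, beta2 = 0.999,
                             minibatch = 32L, gp_weight = 10,
                             clip_weights = 1.0, n_critic = 1L, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    stop("beta1 and beta2 must lie in [0, 1)", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 minibatch = as.integer(minibatch), gp_weight = gp_weight,
                 clip_weights = clip_weights, n_critic = as.integer(n_critic),
                 seed = as.integer(seed)),
            class = "gan_train_config")
}

minibatch_for_res <- function(minibatch, res) {
  div <- if (res >= 256L) 4L else if (res >= 128L) 2L else 1L
  max(2L, minibatch %/% div)
}

#' Build a progressively grown GAN (one class)
#'
#' Constructs the full stack of generator/discriminator blocks for every
#' resolution of the schedule. The generator maps a latent vector to a 4x4
#' image through a dense layer plus convolution; each later stage adds an
#' upsample-conv-conv block that doubles the resolution, with a 1x1 toRGB
#' head per stage. The discriminator mirrors this with fromRGB heads,
#' conv-conv-downsample blocks, an optional minibatch-stddev layer and a
#' dense critic output. The progressive-GAN stabilizers (generator pixel
#' normalization, minibatch standard deviation, equalized learning rate) are
#' individually switchable.
#'
#' @param schedule a [stage_schedule()].
#' @param latent a [latent_spec()].
#' @param class_tag `"benign"` or `"malignant"` (bookkeeping tag).
#' @param pixelnorm,mbstd,eqlr enable the respective stabilizer.
#' @param seed seed for weight initialisation.
#' @return An object of class `gan_bundle` at stage 1 (4x4), `alpha = 1`.
#' @export
build_pggan <- function(schedule, latent = latent_spec(128L),
                        class_tag = "benign", pixelnorm = TRUE, mbstd = TRUE,
                        eqlr = TRUE, seed = 1L) {
  stopifnot(inherits(schedule, "stage_schedule"), inherits(latent, "latent_spec"))
  fm <- schedule$feature_maps
  S <- length(schedule$resolutions)
  pn <- function() if (pixelnorm) list(nn_pixelnorm()) else list()
  with_seed(seed, {
    g <- list()
    g$base <- nn_sequential(c(
      list(nn_dense(latent$dimension, 16L * fm[1L], eqlr = eqlr,
                    group = "conv"),
           nn_reshape(c(4L, 4L, fm[1L])), nn_lrelu(0.2)), pn(),
      list(nn_conv(fm[1L], fm[1L], eqlr = eqlr), nn_lrelu(0.2)), pn()))
    if (S > 1L) {
      for (s in 2:S) {
        g[[paste0("block", s)]] <- nn_sequential(c(
          list(nn_upsample(),
               nn_conv(fm[s - 1L], fm[s], eqlr = eqlr), nn_lrelu(0.2)), pn(),
          list(nn_conv(fm[s], fm[s], eqlr = eqlr), nn_lrelu(0.2)), pn()))
      }
    }
    for (s in 1:S) {
      g[[paste0("to_rgb", s)]] <- nn_sequential(list(
        nn_conv(fm[s], 3L, k = 1L, pad = 0L, gain = 1, eqlr = eqlr)))
    }
    d <- list()
    for (s in 1:S) {
      d[[paste0("from_rgb", s)]] <- nn_sequential(list(
        nn_conv(3L, fm[s], k = 1L, pad = 0L, eqlr = eqlr), nn_lrelu(0.2)))
    }
    if (S > 1L) {
      for (s in 2:S) {
        d[[paste0("block", s)]] <- nn_sequential(list(
          nn_conv(fm[s], fm[s], eqlr = eqlr), nn_lrelu(0.2),
          nn_conv(fm[s], fm[s - 1L], eqlr = eqlr), nn_lrelu(0.2),
          nn_avgpool()))
      }
    }
    din <- fm[1L] + if (mbstd) 1L else 0L
    d$final <- nn_sequential(c(
      if (mbstd) list(nn_mbstd()) else list(),
      list(nn_conv(din, fm[1L], eqlr = eqlr), nn_lrelu(0.2),
           nn_flatten(),
           nn_dense(16L * fm[1L], 1L, gain = 1, eqlr = eqlr))))
    structure(list(arch = "pggan", generator = g, discriminator = d,
                   schedule = schedule, latent = latent, stage = 1L,
                   alpha = 1, class_tag = class_tag,
                   options = list(pixelnorm = pixelnorm, mbstd = mbstd,
                                  eqlr = eqlr)),
              class = "gan_bundle")
  })
}

#' Grow a progressive GAN bundle by one stage
#'
#' Advances to the next resolution of the schedule and resets the fade-in
#' coefficient to 0 (the new block is blended in during training).
#'
#' @param bundle a `gan_bundle`.
#' @return The grown bundle.
#' @export
grow_stage <- function(bundle) {
  if (bundle$stage >= length(bundle$schedule$resolutions)) {
    stop("bundle is already at the final resolution", call. = FALSE)
  }
  bundle$stage <- bundle$stage + 1L
  bundle$alpha <- 0
  bundle
}

#' Current output resolution of a GAN bundle
#' @param bundle a `gan_bundle`.
#' @return Side length in pixels.
#' @export
gan_resolution <- function(bundle) {
  bundle$schedule$resolutions[bundle$stage]
}

#' Fade-in coefficient for progressive growth
#'
#' Linear ramp `alpha = min(step / fade_steps, 1)` used to blend a newly
#' added block with the upsampled previous-stage pathway.
#'
#' @param step non-negative training step index within the stage.
#' @param fade_steps number of steps over which to fade (>= 1).
#' @return `alpha` in \[0, 1\], non-decreasing in `step`.
#' @export
fade_in_alpha <- function(step, fade_steps) {
  if (fade_steps < 1) stop("fade_steps must be >= 1", call. = FALSE)
  if (any(step < 0)) stop("step must be non-negative", call. = FALSE)
  pmin(step / fade_steps, 1)
}

# --- forward / backward through the progressive structure ------------------

# Generator forward at (stage, alpha). Returns y (H,W,3,N) and caches.
pggan_g_forward <- function(bundle, z, keep_cache = FALSE) {
  g <- bundle$generator
  s <- bundle$stage
  a <- bundle$alpha
  caches <- list()
  r <- net_forward(g$base, z, keep_cache = keep_cache)
  x <- r$y
  caches$base <- r$caches
  if (s == 1L) {
    r <- net_forward(g$to_rgb1, x, keep_cache = keep_cache)
    caches$rgb_new <- r$caches
    return(list(y = r$y, caches = caches))
  }
  if (s > 2L) {
    caches$mid <- vector("list", s - 2L)
    for (k in 2:(s - 1L)) {
      r <- net_forward(g[[paste0("block", k)]], x, keep_cache = keep_cache)
      x <- r$y
      caches$mid[[k - 1L]] <- r$caches
    }
  }
  x_prev <- x
  rb <- net_forward(g[[paste0("block", s)]], x_prev, keep_cache = keep_cache)
  caches$new <- rb$caches
  rn <- net_forward(g[[paste0("to_rgb", s)]], rb$y, keep_cache = keep_cache)
  caches$rgb_new <- rn$caches
  if (a < 1) {
    ro <- net_forward(g[[paste0("to_rgb", s - 1L)]], x_prev,
                      keep_cache = keep_cache)
    caches$rgb_old <- ro$caches
    y <- a * rn$y + (1 - a) * upsample2x(ro$y)
  } else {
    y <- rn$y
  }
  list(y = y, caches = caches)
}

# Generator backward; returns named list of per-segment grads.
pggan_g_backward <- function(bundle, caches, dy) {
  g <- bundle$generator
  s <- bundle$stage
  a <- bundle$alpha
  grads <- list()
  if (s == 1L) {
    bw <- net_backward(g$to_rgb1, dy, caches$rgb_new)
    grads$to_rgb1 <- bw$grads
    dx <- bw$dx
  } else {
    dx_old <- NULL
    if (a < 1) {
      bo <- net_backward(g[[paste0("to_rgb", s - 1L)]],
                         upsample2x_backward((1 - a) * dy), caches$rgb_old)
      grads[[paste0("to_rgb", s - 1L)]] <- bo$grads
      dx_old <- bo$dx
      dy <- a * dy
    }
    bn <- net_backward(g[[paste0("to_rgb", s)]], dy, caches$rgb_new)
    grads[[paste0("to_rgb", s)]] <- bn$grads
    bb <- net_backward(g[[paste0("block", s)]], bn$dx, caches$new)
    grads[[paste0("block", s)]] <- bb$grads
    dx <- bb$dx
    if (!is.null(dx_old)) dx <- dx + dx_old
    if (s > 2L) {
      for (k in (s - 1L):2L) {
        bm <- net_backward(g[[paste0("block", k)]], dx, caches$mid[[k - 1L]])
        grads[[paste0("block", k)]] <- bm$grads
        dx <- bm$dx
      }
    }
  }
  bb <- net_backward(g$base, dx, caches$base)
  grads$base <- bb$grads
  grads
}

# Discriminator forward at (stage, alpha) on images x; returns scores (1 x N).
pggan_d_forward <- function(bundle, x, keep_cache = FALSE) {
  d <- bundle$discriminator
  s <- bundle$stage
  a <- bundle$alpha
  caches <- list()
  if (s == 1L) {
    r <- net_forward(d$from_rgb1, x, keep_cache = keep_cache)
    caches$rgb_new <- r$caches
    h <- r$y
  } else {
    rn <- net_forward(d[[paste0("from_rgb", s)]], x, keep_cache = keep_cache)
    caches$rgb_new <- rn$caches
    rb <- net_forward(d[[paste0("block", s)]], rn$y, keep_cache = keep_cache)
    caches$new <- rb$caches
    h <- rb$y
    if (a < 1) {
      xd <- avgpool2x(x)
      ro <- net_forward(d[[paste0("from_rgb", s - 1L)]], xd,
                        keep_cache = keep_cache)
      caches$rgb_old <- ro$caches
      h <- a * h + (1 - a) * ro$y
    }
    if (s > 2L) {
      caches$mid <- vector("list", s - 2L)
      for (k in (s - 1L):2L) {
        r <- net_forward(d[[paste0("block", k)]], h, keep_cache = keep_cache)
        h <- r$y
        caches$mid[[k - 1L]] <- r$caches
      }
    }
  }
  r <- net_forward(d$final, h, keep_cache = keep_cache)
  caches$final <- r$caches
  list(y = r$y, caches = caches)
}

# Discriminator backward; returns grads and the gradient w.r.t. the input
# image batch (used by the gradient-penalty diagnostic).
pggan_d_backward <- function(bundle, caches, dy) {
  d <- bundle$discriminator
  s <- bundle$stage
  a <- bundle$alpha
  grads <- list()
  bf <- net_backward(d$final, dy, caches$final)
  grads$final <- bf$grads
  dh <- bf$dx
  if (s == 1L) {
    br <- net_backward(d$from_rgb1, dh, caches$rgb_new)
    grads$from_rgb1 <- br$grads
    return(list(grads = grads, dx = br$dx))
  }
  if (s > 2L) {
    for (k in 2:(s - 1L)) {
      bm <- net_backward(d[[paste0("block", k)]], dh, caches$mid[[k - 1L]])
      grads[[paste0("block", k)]] <- bm$grads
      dh <- bm$dx
    }
  }
  dx_in <- NULL
  if (a < 1) {
    bo <- net_backward(d[[paste0("from_rgb", s - 1L)]], (1 - a) * dh,
                       caches$rgb_old)
    grads[[paste0("from_rgb", s - 1L)]] <- bo$grads
    dx_in <- avgpool2x_backward(bo$dx)
    dh <- a * dh
  }
  bb <- net_backward(d[[paste0("block", s)]], dh, caches$new)
  grads[[paste0("block", s)]] <- bb$grads
  br <- net_backward(d[[paste0("from_rgb", s)]], bb$dx, caches$rgb_new)
  grads[[paste0("from_rgb", s)]] <- br$grads
  dx <- br$dx
  if (!is.null(dx_in)) dx <- dx + dx_in
  list(grads = grads, dx = dx)
}

# --- DCGAN baseline --------------------------------------------------------

#' Build the DCGAN baseline
#'
#' A conventional (non-progressive) GAN: the generator produces 256x256 RGB
#' images directly from the latent vector through five convolutional and
#' four upscaling layers (dense projection to 16x16, then four
#' upsample+conv blocks and a 1x1 RGB output convolution); the discriminator
#' has six convolutional layers (with average-pool downscaling) and one
#' dense output layer.
#'
#' @param latent a [latent_spec()].
#' @param resolution output resolution (default 256; must be 16 * 2^4 style
#'   power of 2 >= 64... any power of 2 >= 64 works by scaling the dense
#'   projection to `resolution / 16`).
#' @param g_feature_maps channel counts for the generator's four conv
#'   blocks (default 256, 128, 64, 32).
#' @param d_feature_maps channel counts for the discriminator's six conv
#'   layers (default 32, 64, 128, 256, 512, 512).
#' @param class_tag bookkeeping class tag.
#' @param seed initialisation seed.
#' @return An object of class `gan_bundle` with `arch = "dcgan"`.
#' @export
build_dcgan <- function(latent = latent_spec(128L), resolution = 256L,
                        g_feature_maps = c(256L, 128L, 64L, 32L),
                        d_feature_maps = c(32L, 64L, 128L, 256L, 512L, 512L),
                        class_tag = "benign", seed = 1L) {
  stopifnot(inherits(latent, "latent_spec"), length(g_feature_maps) == 4L,
            length(d_feature_maps) == 6L)
  resolution <- as.integer(resolution)
  base_res <- resolution %/% 16L
  if (base_res < 1L || bitwAnd(resolution, resolution - 1L) != 0L) {
    stop("resolution must be a power of 2 and >= 16", call. = FALSE)
  }
  gf <- as.integer(g_feature_maps)
  df <- as.integer(d_feature_maps)
  with_seed(seed, {
    glayers <- list(
      nn_dense(latent$dimension, base_res^2 * gf[1L], group = "conv"),
      nn_reshape(c(base_res, base_res, gf[1L])), nn_lrelu(0.2))
    cin <- gf[1L]
    for (i in 1:4) {
      glayers <- c(glayers, list(nn_upsample(),
                                 nn_conv(cin, gf[min(i + 1L, 4L)]),
                                 nn_lrelu(0.2)))
      cin <- gf[min(i + 1L, 4L)]
    }
    glayers <- c(glayers, list(nn_conv(cin, 3L, k = 1L, pad = 0L, gain = 1)))
    g <- nn_sequential(glayers)
    dlayers <- list(nn_conv(3L, df[1L]), nn_lrelu(0.2))
    for (i in 2:6) {
      dlayers <- c(dlayers, list(nn_avgpool(), nn_conv(df[i - 1L], df[i]),
                                 nn_lrelu(0.2)))
    }
    final_res <- resolution %/% 32L
    dlayers <- c(dlayers, list(nn_avgpool(), nn_flatten(),
                               nn_dense((final_res %/% 2L)^2 * df[6L], 1L,
                                        gain = 1)))
    d <- nn_sequential(dlayers)
    structure(list(arch = "dcgan", generator = list(net = g),
                   discriminator = list(net = d),
                   resolution = resolution, latent = latent,
                   stage = NA_integer_, alpha = 1, class_tag = class_tag),
              class = "gan_bundle")
  })
}

#' Layer counts of a DCGAN bundle
#'
#' Introspects the generator/discriminator structure: convolutional layers,
#' scaling (upsample) layers and output layers.
#'
#' @param bundle a DCGAN `gan_bundle`.
#' @return A list with `g_conv`, `g_scale`, `d_conv`, `d_output`.
#' @export
dcgan_layer_counts <- function(bundle) {
  stopifnot(bundle$arch == "dcgan")
  gt <- vapply(bundle$generator$net$layers, `[[`, character(1L), "type")
  dt <- vapply(bundle$discriminator$net$layers, `[[`, character(1L), "type")
  list(g_conv = sum(gt == "conv"), g_scale = sum(gt == "upsample"),
       d_conv = sum(dt == "conv"), d_output = sum(dt == "dense"))
}
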