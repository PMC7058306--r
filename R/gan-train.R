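#' Wasserstein critic and generator losses
#'
#' `d_loss = mean(fake) - mean(real) + gp_weight * gradient_penalty` and
#' `g_loss = -mean(fake)`, the standard Wasserstein GAN objective with an
#' optional gradient-penalty term.
#'
#' @param real_scores,fake_scores numeric vectors of critic scores
#'   (non-empty).
#' @param gradient_penalty penalty value (default 0).
#' @param gp_weight penalty coefficient (default 10).
#' @return A list with `d_loss` and `g_loss`.
#' @export
wasserstein_losses <- function(real_scores, fake_scores,
                               gradient_penalty = 0, gp_weight = 10) {
  if (length(real_scores) == 0L || length(fake_scores) == 0L) {
    stop("score vectors must be non-empty", call. = FALSE)
  }
  list(d_loss = mean(fake_scores) - mean(real_scores) +
         gp_weight * gradient_penalty,
       g_loss = -mean(fake_scores))
}

#' Sliced Wasserstein distance between two sample sets
#'
#' Averages, over `n_projections` random unit directions, the 1-D
#' Wasserstein-1 distance between the projected samples (mean absolute
#' difference of the sorted projections). A cheap pseudometric on equal-size
#' sample sets: non-negative, symmetric, zero on identical sets, and
#' deterministic given the seed.
#'
#' @param samples_a,samples_b numeric matrices with one sample per row;
#'   equal row and column counts required.
#' @param n_projections number of random projections (default 64).
#' @param seed integer seed for the projection directions.
#' @return A non-negative scalar.
#' @export
sliced_wasserstein_distance <- function(samples_a, samples_b,
                                        n_projections = 64L, seed = 1L) {
  samples_a <- as.matrix(samples_a)
  samples_b <- as.matrix(samples_b)
  if (!all(dim(samples_a) == dim(samples_b))) {
    stop("sample sets must have equal counts and feature dimension",
         call. = FALSE)
  }
  d <- ncol(samples_a)
  with_seed(seed, {
    proj <- matrix(rnorm(d * n_projections), d, n_projections)
    proj <- sweep(proj, 2L, sqrt(colSums(proj^2)), "/")
    pa <- samples_a %*% proj
    pb <- samples_b %*% proj
    mean(vapply(seq_len(n_projections), function(j) {
      mean(abs(sort(pa[, j]) - sort(pb[, j])))
    }, numeric(1L)))
  })
}

#' Sliced Wasserstein distance between two image sets
#'
#' Flattens each image (0-255 RGB) to a feature row, rescales to \[-1, 1\]
#' and calls [sliced_wasserstein_distance()].
#'
#' @param images_a,images_b lists of H x W x 3 arrays (equal counts/sizes).
#' @inheritParams sliced_wasserstein_distance
#' @return A non-negative scalar.
#' @export
swd_images <- function(images_a, images_b, n_projections = 64L, seed = 1L) {
  flat <- function(imgs) {
    t(vapply(imgs, function(im) as.vector(im) / 127.5 - 1,
             numeric(length(imgs[[1L]]))))
  }
  sliced_wasserstein_distance(flat(images_a), flat(images_b),
                              n_projections, seed)
}

# Sample a latent batch: dimension x n matrix of standard normals.
draw_latent <- function(latent, n) {
  matrix(rnorm(latent$dimension * n), latent$dimension, n)
}

# Dispatch generator / discriminator forward+backward over both archs.
gan_g_forward <- function(bundle, z, keep_cache = FALSE) {
  if (bundle$arch == "pggan") {
    pggan_g_forward(bundle, z, keep_cache)
  } else {
    r <- net_forward(bundle$generator$net, z, keep_cache = keep_cache)
    list(y = r$y, caches = r$caches)
  }
}

gan_d_forward <- function(bundle, x, keep_cache = FALSE) {
  if (bundle$arch == "pggan") {
    pggan_d_forward(bundle, x, keep_cache)
  } else {
    r <- net_forward(bundle$discriminator$net, x, keep_cache = keep_cache)
    list(y = r$y, caches = r$caches)
  }
}

gan_g_backward <- function(bundle, caches, dy) {
  if (bundle$arch == "pggan") {
    pggan_g_backward(bundle, caches, dy)
  } else {
    list(net = net_backward(bundle$generator$net, dy, caches)$grads)
  }
}

gan_d_backward <- function(bundle, caches, dy) {
  if (bundle$arch == "pggan") {
    pggan_d_backward(bundle, caches, dy)
  } else {
    bw <- net_backward(bundle$discriminator$net, dy, caches)
    list(grads = list(net = bw$grads), dx = bw$dx)
  }
}

# Sum two named per-segment grad lists.
add_grads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) {
      a[[nm]] <- b[[nm]]
    } else {
      for (i in seq_along(b[[nm]])) {
        if (is.null(b[[nm]][[i]])) next
        a[[nm]][[i]]$w <- a[[nm]][[i]]$w + b[[nm]][[i]]$w
        a[[nm]][[i]]$b <- a[[nm]][[i]]$b + b[[nm]][[i]]$b
      }
    }
  }
  a
}

# Adam update of a named collection of sequential segments.
gan_update <- function(segs, grads, states, config, clip = NULL) {
  for (nm in names(grads)) {
    if (is.null(segs[[nm]])) next
    if (is.null(states[[nm]])) states[[nm]] <- adam_init(segs[[nm]])
    up <- adam_step(segs[[nm]], grads[[nm]], states[[nm]],
                    lr = config$learning_rate, beta1 = config$beta1,
                    beta2 = config$beta2, clip_weights = clip)
    segs[[nm]] <- up$net
    states[[nm]] <- up$state
  }
  list(segs = segs, states = states)
}

#' Gradient penalty of the critic at interpolated points
#'
#' Computes `mean((||grad_x D(x_hat)|| - 1)^2)` where `x_hat` are random
#' convex combinations of real and generated images — the penalty value of
#' gradient-penalized Wasserstein training, reported here as a Lipschitz
#' diagnostic of the critic.
#'
#' @param bundle a `gan_bundle`.
#' @param real,fake image tensors (H, W, 3, N) in \[-1, 1\], equal batch.
#' @param seed seed for the interpolation coefficients.
#' @return A non-negative scalar.
#' @export
gradient_penalty <- function(bundle, real, fake, seed = 1L) {
  n <- dim(real)[4L]
  with_seed(seed, {
    eps <- runif(n)
    xh <- real
    for (i in seq_len(n)) {
      xh[, , , i] <- eps[i] * real[, , , i] + (1 - eps[i]) * fake[, , , i]
    }
    fw <- gan_d_forward(bundle, xh, keep_cache = TRUE)
    dy <- matrix(1, 1L, n)
    bw <- gan_d_backward(bundle, fw$caches, dy)
    norms <- sqrt(apply(bw$dx^2, 4L, sum))
    mean((norms - 1)^2)
  })
}

#' Train a progressively grown Wasserstein GAN
#'
#' Runs the scaling steps of the schedule in order. Each stage after the
#' first begins with a fade-in phase in which the new block's contribution
#' ramps linearly (see [fade_in_alpha()]) followed by stabilization at
#' `alpha = 1`. The critic is trained on the Wasserstein objective with
#' weight clipping as its Lipschitz constraint; real images are
#' average-pooled down to each stage's resolution. After every stage the
#' sliced Wasserstein distance between real and generated samples is logged
#' and a parameter checkpoint is stored. Fully deterministic given
#' `config$seed`.
#'
#' @param bundle a `gan_bundle` from [build_pggan()] (at stage 1).
#' @param images list of H x W x 3 arrays (0-255) of the bundle's class, all
#'   square and at least the schedule's final resolution.
#' @param config a [gan_train_config()].
#' @param n_stages how many stages to run (default: all in the schedule).
#' @param swd_samples sample count for the per-stage SWD log (default 64).
#' @return The trained bundle, with `$log` (per-stage data.frame: stage,
#'   resolution, d_loss, g_loss, swd, gradient_penalty) and `$checkpoints`
#'   (per-stage parameter snapshots).
#' @export
train_pggan <- function(bundle, images, config = gan_train_config(),
                        n_stages = NULL, swd_samples = 64L) {
  stopifnot(inherits(bundle, "gan_bundle"), bundle$arch == "pggan")
  sch <- bundle$schedule
  S <- n_stages %||% length(sch$resolutions)
  rmax <- sch$resolutions[S]
  sizes <- vapply(images, function(im) dim(im)[1L], integer(1L))
  if (any(sizes < rmax)) {
    stop("all training images must be at least ", rmax, " pixels square",
         call. = FALSE)
  }
  x_full <- img8_to_tensor(images)
  n <- dim(x_full)[4L]
  g_states <- list()
  d_states <- list()
  log <- list()
  checkpoints <- list()
  with_seed(config$seed, {
    for (s in seq_len(S)) {
      res <- sch$resolutions[s]
      if (s > 1L) bundle <- grow_stage(bundle)
      x_res <- downsample_to(x_full, res)
      mb <- minibatch_for_res(config$minibatch, res)
      steps_per_epoch <- max(1L, n %/% mb)
      total_steps <- sch$epochs_per_stage * steps_per_epoch
      fade_steps <- if (s == 1L) 0L else
        max(1L, round(sch$fadein_fraction * total_steps))
      d_losses <- g_losses <- numeric(0)
      for (step in seq_len(total_steps)) {
        bundle$alpha <- if (s == 1L) 1 else
          fade_in_alpha(step - 1L, fade_steps)
        for (ic in seq_len(config$n_critic)) {
          idx <- sample.int(n, mb, replace = mb > n)
          real <- x_res[, , , idx, drop = FALSE]
          z <- draw_latent(bundle$latent, mb)
          fake <- gan_g_forward(bundle, z, keep_cache = FALSE)$y
          fr <- gan_d_forward(bundle, real, keep_cache = TRUE)
          ff <- gan_d_forward(bundle, fake, keep_cache = TRUE)
          wl <- wasserstein_losses(fr$y, ff$y, 0, config$gp_weight)
          d_losses <- c(d_losses, wl$d_loss)
          br <- gan_d_backward(bundle, fr$caches, matrix(-1 / mb, 1L, mb))
          bf <- gan_d_backward(bundle, ff$caches, matrix(1 / mb, 1L, mb))
          dgr <- add_grads(br$grads, bf$grads)
          up <- gan_update(bundle$discriminator, dgr, d_states, config,
                           clip = config$clip_weights)
          bundle$discriminator <- up$segs
          d_states <- up$states
        }
        z <- draw_latent(bundle$latent, mb)
        gf <- gan_g_forward(bundle, z, keep_cache = TRUE)
        df <- gan_d_forward(bundle, gf$y, keep_cache = TRUE)
        g_losses <- c(g_losses, -mean(df$y))
        bw <- gan_d_backward(bundle, df$caches, matrix(-1 / mb, 1L, mb))
        ggr <- gan_g_backward(bundle, gf$caches, bw$dx)
        up <- gan_update(bundle$generator, ggr, g_states, config)
        bundle$generator <- up$segs
        g_states <- up$states
      }
      bundle$alpha <- 1
      m <- min(swd_samples, n)
      z <- draw_latent(bundle$latent, m)
      fake <- gan_g_forward(bundle, z, keep_cache = FALSE)$y
      ridx <- sample.int(n, m)
      real_m <- x_res[, , , ridx, drop = FALSE]
      swd <- sliced_wasserstein_distance(
        t(matrix(real_m, ncol = m)), t(matrix(fake, ncol = m)),
        seed = config$seed)
      gp <- gradient_penalty(bundle, real_m, fake, seed = config$seed)
      log[[s]] <- data.frame(stage = s, resolution = res,
                             d_loss = mean(tail(d_losses, 50L)),
                             g_loss = mean(tail(g_losses, 50L)),
                             swd = swd, gradient_penalty = gp)
      checkpoints[[s]] <- list(stage = s, resolution = res,
                               generator = bundle$generator,
                               discriminator = bundle$discriminator)
    }
  })
  bundle$log <- do.call(rbind, log)
  bundle$checkpoints <- checkpoints
  bundle
}

#' Train the DCGAN baseline
#'
#' Conventional (non-progressive) adversarial training with the
#' non-saturating logistic GAN loss and Adam, at the bundle's fixed output
#' resolution. Defaults follow the baseline protocol (learning rate 2e-5,
#' beta1 0.5, beta2 0.999, minibatch 32); pass fewer epochs for desk-scale
#' runs.
#'
#' @param bundle a `gan_bundle` from [build_dcgan()].
#' @param images list of H x W x 3 arrays (0-255).
#' @param config a [gan_train_config()]; DCGAN defaults applied when
#'   omitted.
#' @param epochs training epochs (default 5000 in the full protocol).
#' @return The trained bundle with a `$log` data.frame.
#' @export
train_dcgan <- function(bundle, images,
                        config = gan_train_config(learning_rate = 2e-5,
                                                  beta1 = 0.5, beta2 = 0.999,
                                                  minibatch = 32L),
                        epochs = 5000L) {
  stopifnot(inherits(bundle, "gan_bundle"), bundle$arch == "dcgan")
  x <- img8_to_tensor(images)
  if (dim(x)[1L] != bundle$resolution) {
    stop("training images must match the DCGAN resolution ",
         bundle$resolution, call. = FALSE)
  }
  n <- dim(x)[4L]
  mb <- min(config$minibatch, n)
  sigmoid <- function(z) 1 / (1 + exp(-z))
  g_states <- d_states <- list()
  d_losses <- g_losses <- numeric(0)
  with_seed(config$seed, {
    steps <- max(1L, n %/% mb) * epochs
    for (step in seq_len(steps)) {
      idx <- sample.int(n, mb, replace = mb > n)
      real <- x[, , , idx, drop = FALSE]
      z <- draw_latent(bundle$latent, mb)
      fake <- gan_g_forward(bundle, z, keep_cache = FALSE)$y
      fr <- gan_d_forward(bundle, real, keep_cache = TRUE)
      ff <- gan_d_forward(bundle, fake, keep_cache = TRUE)
      d_losses <- c(d_losses,
                    mean(log1p(exp(-fr$y))) + mean(log1p(exp(ff$y))))
      br <- gan_d_backward(bundle, fr$caches,
                           matrix(-sigmoid(-fr$y) / mb, 1L, mb))
      bf <- gan_d_backward(bundle, ff$caches,
                           matrix(sigmoid(ff$y) / mb, 1L, mb))
      up <- gan_update(bundle$discriminator, add_grads(br$grads, bf$grads),
                       d_states, config)
      bundle$discriminator <- up$segs
      d_states <- up$states
      z <- draw_latent(bundle$latent, mb)
      gf <- gan_g_forward(bundle, z, keep_cache = TRUE)
      df <- gan_d_forward(bundle, gf$y, keep_cache = TRUE)
      g_losses <- c(g_losses, mean(log1p(exp(-df$y))))
      bw <- gan_d_backward(bundle, df$caches,
                           matrix(-sigmoid(-df$y) / mb, 1L, mb))
      up <- gan_update(bundle$generator,
                       gan_g_backward(bundle, gf$caches, bw$dx),
                       g_states, config)
      bundle$generator <- up$segs
      g_states <- up$states
    }
  })
  bundle$log <- data.frame(d_loss = mean(tail(d_losses, 50L)),
                           g_loss = mean(tail(g_losses, 50L)))
  bundle
}

#' Sample images from a GAN bundle
#'
#' Draws `n` latent vectors (seeded) and maps them through the generator at
#' the bundle's current stage; outputs are de-normalized to 8-bit RGB.
#'
#' @param bundle a trained (or fresh) `gan_bundle`.
#' @param n number of images (>= 1).
#' @param seed integer seed.
#' @return A list of H x W x 3 arrays with values in 0-255.
#' @export
sample_images <- function(bundle, n, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, {
    z <- draw_latent(bundle$latent, n)
    y <- gan_g_forward(bundle, z, keep_cache = FALSE)$y
    y[y < -1] <- -1
    y[y > 1] <- 1
    tensor_to_img8(y)
  })
}

#' Save / load a GAN bundle checkpoint
#'
#' The checkpoint is a self-describing RDS archive holding the schedule,
#' stage, fade-in alpha, all parameters and the class tag.
#'
#' @param bundle a `gan_bundle`.
#' @param path file path (`.rds`).
#' @return `load_gan` returns the bundle; `save_gan` returns `path`
#'   invisibly.
#' @export
save_gan <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_gan
#' @export
load_gan <- function(path) {
  bundle <- readRDS(path)
  stopifnot(inherits(bundle, "gan_bundle"))
  bundle
}
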