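# Minimal reverse-mode neural-network core.
#
# A layer is a plain list with a `type`, optional parameters (`w`, `b`), and a
# `group` tag ("conv" or "head") used by the layer-freeze policy of two-step
# training. Convolutions are stride-1 (resolution changes are explicit
# upsample/pool layers, as in progressive GANs and VGG) and are computed as
# im2col + BLAS matrix products; every backward pass is the exact adjoint of
# its forward pass, verified by finite-difference tests.
#
# Equalized learning rate (He-constant runtime weight scaling, a progressive
# GAN stabilizer) is supported per layer via `scale`: the effective weight is
# scale * w, with w initialised as standard normal.

nn_conv <- function(cin, cout, k = 3L, pad = (k - 1L) %/% 2L, stride = 1L,
                    gain = sqrt(2), eqlr = TRUE, group = "conv") {
  fan_in <- k * k * cin
  if (eqlr) {
    w <- array(rnorm(k * k * cin * cout), dim = c(k, k, cin, cout))
    scale <- gain / sqrt(fan_in)
  } else {
    w <- array(rnorm(k * k * cin * cout, sd = gain / sqrt(fan_in)),
               dim = c(k, k, cin, cout))
    scale <- 1
  }
  list(type = "conv", w = w, b = numeric(cout), k = as.integer(k),
       pad = as.integer(pad), stride = as.integer(stride),
       scale = scale, group = group)
}

nn_dense <- function(nin, nout, gain = sqrt(2), eqlr = TRUE, group = "head") {
  if (eqlr) {
    w <- matrix(rnorm(nout * nin), nout, nin)
    scale <- gain / sqrt(nin)
  } else {
    w <- matrix(rnorm(nout * nin, sd = gain / sqrt(nin)), nout, nin)
    scale <- 1
  }
  list(type = "dense", w = w, b = numeric(nout), scale = scale, group = group)
}

nn_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nn_relu <- function() list(type = "lrelu", alpha = 0)
nn_tanh <- function() list(type = "tanh")
nn_pixelnorm <- function(eps = 1e-8) list(type = "pixelnorm", eps = eps)
nn_upsample <- function() list(type = "upsample")
nn_avgpool <- function() list(type = "avgpool")
nn_maxpool <- function() list(type = "maxpool")
nn_flatten <- function() list(type = "flatten")
nn_reshape <- function(shape) list(type = "reshape", shape = as.integer(shape))
nn_mbstd <- function(eps = 1e-8) list(type = "mbstd", eps = eps)

layer_forward <- function(layer, x, train = TRUE) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      k <- layer$k; pad <- layer$pad; stride <- layer$stride
      Ho <- (d[1L] + 2L * pad - k) %/% stride + 1L
      Wo <- (d[2L] + 2L * pad - k) %/% stride + 1L
      cols <- im2col_cpp(x, d[1L], d[2L], d[3L], d[4L], k, stride, pad)
      cout <- dim(layer$w)[4L]
      wm <- matrix(layer$w, nrow = k * k * d[3L], ncol = cout) * layer$scale
      ym <- crossprod(wm, cols) + layer$b
      y <- aperm(array(ym, dim = c(cout, Ho, Wo, d[4L])), c(2L, 3L, 1L, 4L))
      list(y = y, cache = list(cols = cols, din = d))
    },
    dense = {
      y <- (layer$w * layer$scale) %*% x + layer$b
      list(y = y, cache = list(x = x))
    },
    lrelu = {
      pos <- x > 0
      y <- x
      y[!pos] <- layer$alpha * y[!pos]
      list(y = y, cache = list(pos = pos))
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = list(y = y))
    },
    pixelnorm = {
      d <- dim(x)
      s2 <- array(0, dim = c(d[1L], d[2L], 1L, d[4L]))
      for (c in seq_len(d[3L])) s2 <- s2 + x[, , c, , drop = FALSE]^2
      s <- sqrt(s2 / d[3L] + layer$eps)
      sf <- s[, , rep(1L, d[3L]), , drop = FALSE]
      y <- x / sf
      list(y = y, cache = list(y = y, s = s))
    },
    upsample = list(y = upsample2x(x), cache = NULL),
    avgpool = list(y = avgpool2x(x), cache = NULL),
    maxpool = {
      d <- dim(x)
      o1 <- seq(1L, d[1L] - 1L, by = 2L); o2 <- o1 + 1L
      p1 <- seq(1L, d[2L] - 1L, by = 2L); p2 <- p1 + 1L
      s1 <- x[o1, p1, , , drop = FALSE]; s2 <- x[o2, p1, , , drop = FALSE]
      s3 <- x[o1, p2, , , drop = FALSE]; s4 <- x[o2, p2, , , drop = FALSE]
      y <- pmax(s1, s2, s3, s4)
      dim(y) <- dim(s1)
      list(y = y, cache = list(s = list(s1, s2, s3, s4), y = y))
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(prod(d[1:3]), d[4L])
      list(y = y, cache = list(din = d))
    },
    reshape = {
      n <- ncol(x)
      y <- x
      dim(y) <- c(layer$shape, n)
      list(y = y, cache = list(din = dim(x)))
    },
    mbstd = {
      d <- dim(x)
      if (d[4L] > 1L) {
        mu <- apply(x, c(1L, 2L, 3L), mean)
        v <- apply(x, c(1L, 2L, 3L), function(z) mean((z - mean(z))^2))
        stat <- mean(sqrt(v + layer$eps))
      } else {
        stat <- 0
      }
      y <- array(0, dim = c(d[1L], d[2L], d[3L] + 1L, d[4L]))
      y[, , seq_len(d[3L]), ] <- x
      y[, , d[3L] + 1L, ] <- stat
      list(y = y, cache = list(cin = d[3L]))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dy, cache) {
  switch(layer$type,
    conv = {
      d <- cache$din
      k <- layer$k
      cout <- dim(layer$w)[4L]
      dym <- aperm(dy, c(3L, 1L, 2L, 4L))
      dim(dym) <- c(cout, length(dym) %/% cout)
      dwm <- tcrossprod(dym, cache$cols)           # cout x K
      dw <- array(t(dwm) * layer$scale, dim = dim(layer$w))
      db <- rowSums(dym)
      wm <- matrix(layer$w, nrow = k * k * d[3L], ncol = cout) * layer$scale
      dcols <- wm %*% dym
      dx <- col2im_cpp(dcols, d[1L], d[2L], d[3L], d[4L], k, layer$stride,
                       layer$pad)
      list(dx = dx, grads = list(w = dw, b = db))
    },
    dense = {
      dw <- tcrossprod(dy, cache$x) * layer$scale
      db <- rowSums(dy)
      dx <- crossprod(layer$w * layer$scale, dy)
      list(dx = dx, grads = list(w = dw, b = db))
    },
    lrelu = {
      dx <- dy
      dx[!cache$pos] <- layer$alpha * dx[!cache$pos]
      list(dx = dx, grads = NULL)
    },
    tanh = list(dx = dy * (1 - cache$y^2), grads = NULL),
    pixelnorm = {
      d <- dim(dy)
      m <- array(0, dim = c(d[1L], d[2L], 1L, d[4L]))
      for (c in seq_len(d[3L])) {
        m <- m + dy[, , c, , drop = FALSE] * cache$y[, , c, , drop = FALSE]
      }
      m <- m / d[3L]
      mf <- m[, , rep(1L, d[3L]), , drop = FALSE]
      sf <- cache$s[, , rep(1L, d[3L]), , drop = FALSE]
      list(dx = (dy - cache$y * mf) / sf, grads = NULL)
    },
    upsample = list(dx = upsample2x_backward(dy), grads = NULL),
    avgpool = list(dx = avgpool2x_backward(dy), grads = NULL),
    maxpool = {
      s <- cache$s
      y <- cache$y
      d <- dim(y)
      H <- 2L * d[1L]; W <- 2L * d[2L]
      dx <- array(0, dim = c(H, W, d[3L], d[4L]))
      o1 <- seq(1L, H, by = 2L); o2 <- o1 + 1L
      p1 <- seq(1L, W, by = 2L); p2 <- p1 + 1L
      taken <- array(FALSE, dim = d)
      put <- function(dx, rows, cols, slice) {
        hit <- (slice == y) & !taken
        taken <<- taken | hit
        g <- array(0, dim = d)
        g[hit] <- dy[hit]
        dx[rows, cols, , ] <- dx[rows, cols, , ] + g
        dx
      }
      dx <- put(dx, o1, p1, s[[1L]])
      dx <- put(dx, o2, p1, s[[2L]])
      dx <- put(dx, o1, p2, s[[3L]])
      dx <- put(dx, o2, p2, s[[4L]])
      list(dx = dx, grads = NULL)
    },
    flatten = {
      dx <- dy
      dim(dx) <- cache$din
      list(dx = dx, grads = NULL)
    },
    reshape = {
      dx <- dy
      dim(dx) <- cache$din
      list(dx = dx, grads = NULL)
    },
    mbstd = {
      # The batch-stddev statistic channel is treated as a constant in the
      # backward pass (stop-gradient).
      dx <- dy[, , seq_len(cache$cin), , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    stop("unknown layer type: ", layer$type)
  )
}

# --- sequential network container -----------------------------------------

nn_sequential <- function(layers) {
  structure(list(layers = layers), class = "nn_sequential")
}

net_forward <- function(net, x, train = TRUE, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], x, train = train)
    x <- fw$y
    if (keep_cache) caches[i] <- list(fw$cache)
  }
  list(y = x, caches = caches)
}

net_backward <- function(net, dy, caches) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    bw <- layer_backward(net$layers[[i]], dy, caches[[i]])
    dy <- bw$dx
    grads[i] <- list(bw$grads)
  }
  list(dx = dy, grads = grads)
}

# Named flat list of all parameters (for determinism / freeze assertions).
net_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (!is.null(l$w)) {
      out[[sprintf("L%02d.%s.w", i, l$type)]] <- l$w
      out[[sprintf("L%02d.%s.b", i, l$type)]] <- l$b
    }
  }
  out
}

net_param_groups <- function(net) {
  vapply(net$layers, function(l) l$group %||% "", character(1L))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (is.null(l$w)) return(NULL)
    list(mw = array(0, dim = dim(l$w)), vw = array(0, dim = dim(l$w)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b)), t = 0L)
  })
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, trainable_groups = NULL,
                      clip_weights = NULL) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- net$layers[[i]]
    if (!is.null(trainable_groups) && !(l$group %in% trainable_groups)) next
    s <- state[[i]]
    s$t <- s$t + 1L
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^s$t
    c2 <- 1 - beta2^s$t
    l$w <- l$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    l$b <- l$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    if (!is.null(clip_weights)) {
      l$w[l$w > clip_weights] <- clip_weights
      l$w[l$w < -clip_weights] <- -clip_weights
      l$b[l$b > clip_weights] <- clip_weights
      l$b[l$b < -clip_weights] <- -clip_weights
    }
    net$layers[[i]] <- l
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# --- losses ----------------------------------------------------------------

# Row-wise softmax of a 2 x N score matrix (numerically stabilised).
softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Cross-entropy over softmax outputs; labels are 1-based class indices.
# Returns the mean loss and the gradient w.r.t. the pre-softmax scores.
softmax_xent <- function(z, labels) {
  p <- softmax_cols(z)
  n <- ncol(z)
  idx <- matrix(c(labels, seq_len(n)), ncol = 2L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dz <- p
  dz[idx] <- dz[idx] - 1
  dz <- dz / n
  list(loss = loss, dz = dz, probs = p)
}
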