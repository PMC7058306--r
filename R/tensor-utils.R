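# Internal tensor helpers.
#
# Two image representations are used throughout:
#   * "img8": a numeric H x W x 3 array with values in [0, 255] (8-bit RGB),
#     the on-disk / user-facing form;
#   * "tensor": a numeric H x W x C x N array with values in [-1, 1], the
#     network-facing form (N = batch size).

img8_to_tensor <- function(imgs) {
  if (is.array(imgs) && length(dim(imgs)) == 3L) imgs <- list(imgs)
  n <- length(imgs)
  d <- dim(imgs[[1L]])
  out <- array(0, dim = c(d[1L], d[2L], d[3L], n))
  for (i in seq_len(n)) out[, , , i] <- imgs[[i]] / 127.5 - 1
  out
}

tensor_to_img8 <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[4L]), function(i) {
    img <- (x[, , , i, drop = FALSE])[, , , 1L]
    dim(img) <- d[1:3]
    img <- (img + 1) * 127.5
    img[img < 0] <- 0
    img[img > 255] <- 255
    img
  })
}

# Nearest-neighbour 2x upsampling of an (H, W, C, N) tensor.
upsample2x <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

upsample2x_backward <- function(dy) {
  d <- dim(dy)
  H <- d[1L] %/% 2L
  W <- d[2L] %/% 2L
  o1 <- seq(1L, 2L * H, by = 2L)
  o2 <- seq(2L, 2L * H, by = 2L)
  p1 <- seq(1L, 2L * W, by = 2L)
  p2 <- seq(2L, 2L * W, by = 2L)
  dy[o1, p1, , , drop = FALSE] + dy[o2, p1, , , drop = FALSE] +
    dy[o1, p2, , , drop = FALSE] + dy[o2, p2, , , drop = FALSE]
}

# 2x average pooling of an (H, W, C, N) tensor.
avgpool2x <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1L] - 1L, by = 2L)
  o2 <- o1 + 1L
  p1 <- seq(1L, d[2L] - 1L, by = 2L)
  p2 <- p1 + 1L
  (x[o1, p1, , , drop = FALSE] + x[o2, p1, , , drop = FALSE] +
     x[o1, p2, , , drop = FALSE] + x[o2, p2, , , drop = FALSE]) / 4
}

avgpool2x_backward <- function(dy) {
  upsample2x(dy) / 4
}

# Average-pool an (H, W, C, N) tensor down to a target square resolution
# (must divide the current resolution by a power of 2).
downsample_to <- function(x, res) {
  while (dim(x)[1L] > res) x <- avgpool2x(x)
  x
}

# Nearest-neighbour upsample to a target square resolution (power-of-2 ratio).
upsample_to <- function(x, res) {
  while (dim(x)[1L] < res) x <- upsample2x(x)
  x
}

# 1-D Gaussian kernel, truncated at ceiling(3*sigma) and normalised to sum 1.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- as.integer(ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable Gaussian blur of one H x W plane with reflected edges.
blur_plane <- function(plane, sigma) {
  g <- gaussian_kernel_1d(sigma)
  r <- (length(g) - 1L) %/% 2L
  if (r == 0L) return(plane)
  H <- nrow(plane)
  W <- ncol(plane)
  refl <- function(idx, n) {
    idx <- ((idx - 1L) %% (2L * n))
    ifelse(idx >= n, 2L * n - 1L - idx, idx) + 1L
  }
  rows <- refl(seq(1L - r, H + r), H)
  padded <- plane[rows, , drop = FALSE]
  tmp <- matrix(0, H, W)
  for (i in seq_along(g)) {
    tmp <- tmp + g[i] * padded[seq(i, i + H - 1L), , drop = FALSE]
  }
  cols <- refl(seq(1L - r, W + r), W)
  padded <- tmp[, cols, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(g)) {
    out <- out + g[i] * padded[, seq(i, i + W - 1L), drop = FALSE]
  }
  out
}

# Gaussian blur of an H x W x 3 img8 array.
blur_img8 <- function(img, sigma) {
  if (sigma <= 0) return(img)
  for (c in 1:3) img[, , c] <- blur_plane(img[, , c], sigma)
  img
}

# Smooth upscaling of an img8 to a square target side: nearest-neighbour
# resize followed by a Gaussian blur matched to the scale factor, so the
# result has smoothness comparable to an optically blurred image rather than
# hard pixel-replication blocks.
upscale_smooth <- function(img, size) {
  factor <- size / dim(img)[1L]
  img <- resize_nearest(img, size)
  if (factor > 1) img <- blur_img8(img, sigma = factor / 2)
  clip255(img)
}

clip255 <- function(img) {
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

stopifnot_img8 <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop(what, " must be an H x W x 3 RGB array", call. = FALSE)
  }
  if (dim(img)[1L] == 0L || dim(img)[2L] == 0L) {
    stop(what, " is empty", call. = FALSE)
  }
  invisible(TRUE)
}
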