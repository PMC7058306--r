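#' Augmentation configuration
#'
#' The augmentation family combines four groups: right-angle rotations,
#' horizontal flip, per-channel color gains (emulating staining-intensity
#' variation), and two focus-variation spatial filters (Gaussian blur and
#' unsharp-mask edge enhancement). Every group contains its identity member,
#' so the original image is always reachable; vertical flip is omitted
#' because it equals horizontal flip composed with a 180-degree rotation.
#'
#' @param rotations subset of `c(0, 90, 180, 270)` degrees; must include 0.
#' @param flips subset of `c("none", "horizontal")`; must include `"none"`.
#' @param color_gains list of RGB gain triples; must include `c(1, 1, 1)`.
#'   The default jitters each channel by -10/+10 percent.
#' @param filters subset of `c("identity", "edge_enhance", "gaussian")`;
#'   must include `"identity"`.
#' @param gaussian_sigma blur sigma in pixels (default 1.5).
#' @param edge_amount unsharp-mask strength (default 1.0).
#' @param target_count_per_class augmented set size per class (originals
#'   included).
#' @param seed integer seed for variant sampling.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotations = c(0, 90, 180, 270),
                           flips = c("none", "horizontal"),
                           color_gains = list(c(1, 1, 1), c(0.9, 1, 1.1),
                                              c(1.1, 1, 0.9), c(1, 0.9, 1),
                                              c(1, 1.1, 1)),
                           filters = c("identity", "edge_enhance", "gaussian"),
                           gaussian_sigma = 1.5,
                           edge_amount = 1.0,
                           target_count_per_class = NULL,
                           seed = 1L) {
  stopifnot(all(rotations %in% c(0, 90, 180, 270)),
            all(flips %in% c("none", "horizontal")),
            all(filters %in% c("identity", "edge_enhance", "gaussian")))
  if (!0 %in% rotations || !"none" %in% flips || !"identity" %in% filters ||
      !any(vapply(color_gains, function(g) all(g == 1), logical(1L)))) {
    stop("each augmentation family must contain its identity member",
         call. = FALSE)
  }
  structure(list(rotations = rotations, flips = flips,
                 color_gains = color_gains, filters = filters,
                 gaussian_sigma = gaussian_sigma, edge_amount = edge_amount,
                 target_count_per_class = target_count_per_class,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Rotate (right angles) and flip a square patch
#'
#' A lossless pixel permutation: rotation is applied first, then the flip.
#' Rotation is clockwise in raster coordinates (x right, y down).
#'
#' @param image H x W x 3 array; must be square.
#' @param rotation one of 0, 90, 180, 270 (degrees).
#' @param flip `"none"` or `"horizontal"`.
#' @return The transformed image, same size.
#' @export
apply_geometric <- function(image, rotation = 0, flip = "none") {
  stopifnot_img8(image)
  if (dim(image)[1L] != dim(image)[2L]) {
    stop("geometric augmentation requires a square image", call. = FALSE)
  }
  if (!rotation %in% c(0, 90, 180, 270)) {
    stop("rotation must be one of 0, 90, 180, 270", call. = FALSE)
  }
  flip <- match.arg(flip, c("none", "horizontal"))
  n <- dim(image)[1L]
  rot1 <- function(img) {          # 90 degrees clockwise per channel
    out <- img
    for (c in 1:3) out[, , c] <- t(img[n:1, , c])
    out
  }
  k <- (rotation / 90) %% 4
  for (i in seq_len(k)) image <- rot1(image)
  if (flip == "horizontal") image <- image[, n:1, , drop = FALSE]
  image
}

#' Scale RGB channels by per-channel gains
#'
#' @param image H x W x 3 array in 0-255.
#' @param gains positive RGB gain triple.
#' @return The gained image, clipped to 0-255.
#' @export
apply_color_gain <- function(image, gains) {
  stopifnot_img8(image)
  if (length(gains) != 3L || any(gains <= 0)) {
    stop("gains must be three positive values", call. = FALSE)
  }
  for (c in 1:3) image[, , c] <- image[, , c] * gains[c]
  clip255(image)
}

#' Apply a focus-variation spatial filter
#'
#' `"gaussian"` convolves with a normalized 2-D Gaussian kernel of the given
#' sigma (separable, reflected edges); `"edge_enhance"` is the unsharp mask
#' `I + edge_amount * (I - gaussian(I))`, clipped to 0-255; `"identity"`
#' returns the input.
#'
#' @param image H x W x 3 array in 0-255.
#' @param filter `"identity"`, `"edge_enhance"` or `"gaussian"`.
#' @param sigma blur sigma in pixels.
#' @param edge_amount unsharp-mask strength.
#' @return The filtered image.
#' @export
apply_filter <- function(image, filter, sigma = 1.5, edge_amount = 1.0) {
  stopifnot_img8(image)
  if (!filter %in% c("identity", "edge_enhance", "gaussian")) {
    stop("unknown filter: ", filter, call. = FALSE)
  }
  switch(filter,
         identity = image,
         gaussian = blur_img8(image, sigma),
         edge_enhance = clip255(image + edge_amount *
                                  (image - blur_img8(image, sigma))))
}

#' Enumerate all augmentation variants of one patch
#'
#' Cartesian product rotations x flips x color gains x filters. The first
#' descriptor is always the identity.
#'
#' @param patch H x W x 3 array.
#' @param config an [augment_config()].
#' @param render if `FALSE`, return descriptors only (images `NULL`).
#' @return A list of `list(descriptor, image)`; descriptors are lists with
#'   fields `rotation, flip, gains, filter` and are pairwise distinct.
#' @export
enumerate_variants <- function(patch, config, render = TRUE) {
  descs <- variant_descriptors(config)
  lapply(descs, function(d) {
    img <- if (render) apply_variant(patch, d, config) else NULL
    list(descriptor = d, image = img)
  })
}

# All descriptors of the config's Cartesian product, identity first.
variant_descriptors <- function(config) {
  grid <- expand.grid(fi = seq_along(config$filters),
                      gi = seq_along(config$color_gains),
                      fl = seq_along(config$flips),
                      ro = seq_along(config$rotations))
  # reorder so the full-identity tuple comes first
  is_id <- with(grid, config$rotations[ro] == 0 & config$flips[fl] == "none" &
                  vapply(gi, function(i) all(config$color_gains[[i]] == 1),
                         logical(1L)) & config$filters[fi] == "identity")
  grid <- rbind(grid[is_id, , drop = FALSE], grid[!is_id, , drop = FALSE])
  lapply(seq_len(nrow(grid)), function(i) {
    list(rotation = config$rotations[grid$ro[i]],
         flip = config$flips[grid$fl[i]],
         gains = config$color_gains[[grid$gi[i]]],
         filter = config$filters[grid$fi[i]])
  })
}

is_identity_descriptor <- function(d) {
  d$rotation == 0 && d$flip == "none" && all(d$gains == 1) &&
    d$filter == "identity"
}

# Apply one descriptor: geometry, then color gain, then spatial filter.
apply_variant <- function(patch, d, config) {
  img <- apply_geometric(patch, d$rotation, d$flip)
  img <- apply_color_gain(img, d$gains)
  apply_filter(img, d$filter, config$gaussian_sigma, config$edge_amount)
}

#' Build a fixed-size augmented training set
#'
#' Produces exactly `target_count_per_class` images per class: every original
#' appears once untransformed, and the remainder is drawn without
#' replacement (seeded) from the pool of non-identity variants, maximizing
#' diversity. Rows labeled `excluded` are ignored. Intended for training
#' partitions only; evaluation patches should never be augmented.
#'
#' @param manifest patch manifest (columns `path, case_id, label, split`).
#' @param config an [augment_config()] with `target_count_per_class` set.
#' @param out_dir if non-`NULL`, variant images are rendered and written as
#'   PNG (originals are referenced in place).
#' @return The augmented manifest with added columns
#'   `origin_path, rotation, flip, gains, filter`.
#' @export
build_augmented_set <- function(manifest, config, out_dir = NULL) {
  stopifnot(inherits(config, "augment_config"))
  target <- config$target_count_per_class
  if (is.null(target)) stop("config$target_count_per_class must be set",
                            call. = FALSE)
  descs <- variant_descriptors(config)
  n_var <- length(descs)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  out <- list()
  for (cls in c("benign", "malignant")) {
    rows <- manifest[manifest$label == cls, , drop = FALSE]
    n_orig <- nrow(rows)
    if (n_orig == 0L) next
    if (target < n_orig || target > n_orig * n_var) {
      stop(sprintf(paste0("target_count_per_class (%d) must lie between the ",
                          "number of %s originals (%d) and the enumerable ",
                          "pool (%d)"),
                   target, cls, n_orig, n_orig * n_var), call. = FALSE)
    }
    # pool of (original, non-identity variant) pairs
    pool_idx <- with_seed(config$seed + match(cls, c("benign", "malignant")),
                          sample(n_orig * (n_var - 1L), target - n_orig))
    orig_part <- data.frame(rows, origin_path = rows$path,
                            rotation = 0, flip = "none", gains = "1:1:1",
                            filter = "identity", stringsAsFactors = FALSE)
    oi <- (pool_idx - 1L) %% n_orig + 1L
    vi <- (pool_idx - 1L) %/% n_orig + 2L  # descriptor index (skip identity)
    var_part <- rows[oi, , drop = FALSE]
    var_part$origin_path <- rows$path[oi]
    var_part$rotation <- vapply(vi, function(j) descs[[j]]$rotation,
                                numeric(1L))
    var_part$flip <- vapply(vi, function(j) descs[[j]]$flip, character(1L))
    var_part$gains <- vapply(vi, function(j)
      paste(descs[[j]]$gains, collapse = ":"), character(1L))
    var_part$filter <- vapply(vi, function(j) descs[[j]]$filter,
                              character(1L))
    if (nrow(var_part) > 0L) {
      var_part$path <- sprintf("%s_aug%05d.png",
                               file.path(out_dir %||% "", cls),
                               seq_len(nrow(var_part)))
      if (!is.null(out_dir)) {
        for (j in seq_len(nrow(var_part))) {
          img <- load_image(var_part$origin_path[j])
          d <- descs[[vi[j]]]
          png::writePNG(apply_variant(img, d, config) / 255,
                        target = var_part$path[j])
        }
      }
    }
    rownames(orig_part) <- rownames(var_part) <- NULL
    out[[cls]] <- rbind(orig_part, var_part)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
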