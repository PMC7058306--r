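#' Rendering parameters for synthetic cytology patches
#'
#' Describes how one class of Papanicolaou-like cell clumps is drawn:
#' nucleus size, nucleus-to-cytoplasm (N:C) area ratio, chromatin speckle
#' strength, clump spread, focus blur, and the stain palette. Malignancy cues
#' follow standard cytomorphology: malignant defaults have larger nuclei,
#' higher N:C ratio and stronger/coarser chromatin texture.
#'
#' @param nucleus_radius_range length-2 numeric, nucleus radius in pixels.
#' @param n_cells_range length-2 integer, number of cells per patch.
#' @param nc_ratio_range length-2 numeric in (0, 1], nucleus-to-cytoplasm
#'   area ratio.
#' @param chromatin_noise_sd standard deviation (intensity units, 0-255
#'   scale) of the chromatin speckle added inside nuclei.
#' @param clump_spread standard deviation in pixels of cell-centre scatter
#'   around the clump centre.
#' @param focus_blur_sd_range length-2 numeric, range of the global Gaussian
#'   focus-blur sigma in pixels.
#' @param stain_palette list with elements `cytoplasm` and `nucleus`, each an
#'   RGB triple in 0-255.
#' @return An object of class `cell_render_params`.
#' @export
cell_render_params <- function(nucleus_radius_range = c(5, 9),
                               n_cells_range = c(6, 12),
                               nc_ratio_range = c(0.2, 0.4),
                               chromatin_noise_sd = 12,
                               clump_spread = 40,
                               focus_blur_sd_range = c(0, 1.5),
                               stain_palette = list(
                                 cytoplasm = c(150, 190, 200),
                                 nucleus = c(60, 40, 90))) {
  stopifnot(length(nucleus_radius_range) == 2L,
            length(n_cells_range) == 2L,
            length(nc_ratio_range) == 2L,
            length(focus_blur_sd_range) == 2L)
  if (nucleus_radius_range[1L] > nucleus_radius_range[2L] ||
      n_cells_range[1L] > n_cells_range[2L] ||
      nc_ratio_range[1L] > nc_ratio_range[2L] ||
      focus_blur_sd_range[1L] > focus_blur_sd_range[2L]) {
    stop("all ranges must satisfy low <= high", call. = FALSE)
  }
  if (nucleus_radius_range[1L] <= 0) stop("nucleus radii must be positive",
                                          call. = FALSE)
  if (nc_ratio_range[1L] <= 0 || nc_ratio_range[2L] > 1) {
    stop("nc_ratio_range must lie in (0, 1]", call. = FALSE)
  }
  if (n_cells_range[1L] < 0) stop("n_cells_range must be non-negative",
                                  call. = FALSE)
  structure(list(nucleus_radius_range = nucleus_radius_range,
                 n_cells_range = as.integer(n_cells_range),
                 nc_ratio_range = nc_ratio_range,
                 chromatin_noise_sd = chromatin_noise_sd,
                 clump_spread = clump_spread,
                 focus_blur_sd_range = focus_blur_sd_range,
                 stain_palette = stain_palette),
            class = "cell_render_params")
}

#' Default rendering parameters for the benign class
#' @return A [cell_render_params()] object.
#' @export
benign_render_params <- function() {
  cell_render_params(nucleus_radius_range = c(5, 9),
                     nc_ratio_range = c(0.2, 0.4),
                     chromatin_noise_sd = 10)
}

#' Default rendering parameters for the malignant class
#'
#' Larger nuclei, higher N:C ratio and stronger chromatin speckle than
#' [benign_render_params()]; the speckle is smoothed at a scale tied to the
#' nucleus radius, so larger nuclei also give coarser texture.
#' @return A [cell_render_params()] object.
#' @export
malignant_render_params <- function() {
  cell_render_params(nucleus_radius_range = c(11, 17),
                     nc_ratio_range = c(0.5, 0.8),
                     chromatin_noise_sd = 28,
                     n_cells_range = c(6, 12))
}

# Alpha-blend an ellipse into the canvas; returns updated canvas and the
# logical fill mask. Ellipse: centre (cx, cy), semi-axes (a, b), rotation th.
blend_ellipse <- function(canvas, cx, cy, a, b, th, rgb, alpha) {
  H <- dim(canvas)[1L]
  W <- dim(canvas)[2L]
  r <- ceiling(max(a, b)) + 1
  ylo <- max(1L, floor(cy - r)); yhi <- min(H, ceiling(cy + r))
  xlo <- max(1L, floor(cx - r)); xhi <- min(W, ceiling(cx + r))
  mask_full <- matrix(FALSE, H, W)
  if (ylo > yhi || xlo > xhi) return(list(canvas = canvas, mask = mask_full))
  ys <- ylo:yhi
  xs <- xlo:xhi
  Y <- matrix(ys - cy, length(ys), length(xs))
  X <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- X * cos(th) + Y * sin(th)
  v <- -X * sin(th) + Y * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  for (c in 1:3) {
    sub <- canvas[ys, xs, c]
    sub[inside] <- (1 - alpha) * sub[inside] + alpha * rgb[c]
    canvas[ys, xs, c] <- sub
  }
  mask_full[ys, xs] <- inside
  list(canvas = canvas, mask = mask_full)
}

#' Render one synthetic cytology patch
#'
#' Draws a clump of cells as overlapping cytoplasm ellipses with interior
#' nucleus ellipses plus chromatin speckle, on a pale slide background with
#' mild per-image brightness jitter, then applies one global Gaussian focus
#' blur. Output is a pure function of `(params, size, seed)`.
#'
#' @param params a [cell_render_params()] object.
#' @param size patch side length in pixels (>= 16).
#' @param seed integer seed.
#' @return A list with `image` (size x size x 3 array, values in 0-255,
#'   integer-rounded) and `mask` (logical size x size matrix marking nucleus
#'   pixels).
#' @export
render_patch <- function(params, size = 256L, seed = 1L) {
  if (!inherits(params, "cell_render_params")) {
    stop("params must be a cell_render_params object", call. = FALSE)
  }
  size <- as.integer(size)
  if (size < 16L) stop("size must be at least 16 pixels", call. = FALSE)
  with_seed(seed, {
    bg <- c(236, 232, 238)
    jitter <- runif(1, -8, 8)
    canvas <- array(rep(bg + jitter, each = size * size),
                    dim = c(size, size, 3L))
    mask <- matrix(FALSE, size, size)
    n_cells <- if (params$n_cells_range[2L] == 0L) 0L else
      sample(params$n_cells_range[1L]:params$n_cells_range[2L], 1L)
    if (n_cells > 0L) {
      ccx <- size / 2 + runif(1, -size / 8, size / 8)
      ccy <- size / 2 + runif(1, -size / 8, size / 8)
      pal <- params$stain_palette
      for (i in seq_len(n_cells)) {
        cx <- min(max(ccx + rnorm(1, sd = params$clump_spread), 2), size - 1)
        cy <- min(max(ccy + rnorm(1, sd = params$clump_spread), 2), size - 1)
        rn <- runif(1, params$nucleus_radius_range[1L],
                    params$nucleus_radius_range[2L])
        q <- runif(1, params$nc_ratio_range[1L], params$nc_ratio_range[2L])
        rc <- rn / sqrt(q)              # cytoplasm radius: area ratio = q
        ecc <- runif(2, 0.85, 1.18)     # mild ellipticity
        th <- runif(1, 0, pi)
        cy_tint <- pal$cytoplasm * runif(1, 0.9, 1.1)
        bl <- blend_ellipse(canvas, cx, cy, rc * ecc[1L], rc * ecc[2L], th,
                            cy_tint, alpha = 0.55)
        canvas <- bl$canvas
        necc <- runif(2, 0.9, 1.1)
        nb <- blend_ellipse(canvas, cx, cy, rn * necc[1L], rn * necc[2L], th,
                            pal$nucleus, alpha = 0.85)
        canvas <- nb$canvas
        if (params$chromatin_noise_sd > 0 && any(nb$mask)) {
          speckle <- matrix(rnorm(size * size, sd = params$chromatin_noise_sd),
                            size, size)
          speckle <- blur_plane(speckle, max(0.5, rn / 8))
          for (c in 1:3) {
            pl <- canvas[, , c]
            pl[nb$mask] <- pl[nb$mask] + speckle[nb$mask]
            canvas[, , c] <- pl
          }
        }
        mask <- mask | nb$mask
      }
    }
    sig <- runif(1, params$focus_blur_sd_range[1L],
                 params$focus_blur_sd_range[2L])
    canvas <- blur_img8(canvas, sig)
    list(image = round(clip255(canvas)), mask = mask)
  })
}

#' Specification of a synthetic two-class patch dataset
#'
#' @param n_per_class number of patches per class (>= 1).
#' @param image_size patch side in pixels; must be a power of 2, >= 4, so
#'   progressive GAN stages align.
#' @param benign_params,malignant_params [cell_render_params()] objects.
#' @param patches_per_case how many patches share one synthetic case id
#'   (enables case-grouped cross-validation).
#' @param seed integer master seed.
#' @return An object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_per_class,
                                   image_size = 256L,
                                   benign_params = benign_render_params(),
                                   malignant_params = malignant_render_params(),
                                   patches_per_case = 5L,
                                   seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  image_size <- as.integer(image_size)
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (image_size < 4L || bitwAnd(image_size, image_size - 1L) != 0L) {
    stop("image_size must be a power of 2 and >= 4", call. = FALSE)
  }
  structure(list(n_per_class = n_per_class, image_size = image_size,
                 benign_params = benign_params,
                 malignant_params = malignant_params,
                 patches_per_case = as.integer(patches_per_case),
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

#' Generate a synthetic patch dataset on disk
#'
#' Renders `2 * n_per_class` patches (benign and malignant), writes them as
#' 8-bit RGB PNG files and returns (and writes) a patch manifest. Patches are
#' grouped into synthetic "cases" of `patches_per_case` images each. The
#' whole dataset is a deterministic function of the spec.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @param out_dir output directory (created if missing).
#' @return The manifest as a data.frame with columns
#'   `path, case_id, label, split`; also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  rows <- list()
  k <- 0L
  for (cls in c("benign", "malignant")) {
    params <- if (cls == "benign") spec$benign_params else
      spec$malignant_params
    offset <- if (cls == "benign") 0L else spec$n_per_class
    for (i in seq_len(spec$n_per_class)) {
      pat <- render_patch(params, spec$image_size,
                          seed = spec$seed + offset + i)
      fn <- file.path(out_dir, sprintf("%s_%04d.png", cls, i))
      png::writePNG(pat$image / 255, target = fn)
      case <- sprintf("case_%s_%03d", cls,
                      (i - 1L) %/% spec$patches_per_case + 1L)
      k <- k + 1L
      rows[[k]] <- data.frame(path = fn, case_id = case, label = cls,
                              split = "none", stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Fraction of dark pixels in a patch
#'
#' Simple proxy for nuclear area: the fraction of pixels whose mean RGB
#' intensity falls below `threshold`. Used as a class-separation diagnostic
#' for synthetic data.
#'
#' @param img an H x W x 3 array in 0-255.
#' @param threshold intensity cut-off (default 110).
#' @return A fraction in \[0, 1\].
#' @export
dark_pixel_fraction <- function(img, threshold = 110) {
  stopifnot_img8(img)
  lum <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  mean(lum < threshold)
}
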