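#' Read an RGB microscopy image
#'
#' Decodes PNG (via \pkg{png}) or JPEG (via \pkg{EBImage}, if installed) into
#' an 8-bit H x W x 3 array with values in 0-255. Grayscale input is
#' replicated to three channels; an alpha channel is dropped.
#'
#' @param path image file path.
#' @return An H x W x 3 numeric array in 0-255.
#' @export
load_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG decoding requires the EBImage package", call. = FALSE)
    }
    e <- EBImage::readImage(path)
    img <- aperm(EBImage::imageData(e), c(2L, 1L, 3L)[seq_along(dim(e))])
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Tile an image into non-overlapping patches
#'
#' Divides a W x H image into non-overlapping `patch_size` squares on a
#' regular grid anchored at the top-left corner; leftover right/bottom
#' margins that cannot hold a full patch are discarded. A 1280 x 960 field
#' at patch size 256 yields 5 x 3 = 15 patches.
#'
#' @param image an H x W x 3 RGB array (0-255).
#' @param patch_size patch side length in pixels (>= 1).
#' @return A data.frame of patch records in row-major order with 0-based
#'   `row`, `col` grid indices and 0-based top-left pixel origins `x0`, `y0`
#'   (`x0 = col * patch_size`, `y0 = row * patch_size`).
#' @export
tile_image <- function(image, patch_size = 256L) {
  stopifnot_img8(image, "source image")
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L) stop("patch_size must be >= 1", call. = FALSE)
  H <- dim(image)[1L]
  W <- dim(image)[2L]
  nr <- H %/% patch_size
  nc <- W %/% patch_size
  if (nr == 0L || nc == 0L) {
    return(data.frame(row = integer(0), col = integer(0),
                      x0 = integer(0), y0 = integer(0)))
  }
  grid <- expand.grid(col = 0:(nc - 1L), row = 0:(nr - 1L))
  data.frame(row = grid$row, col = grid$col,
             x0 = grid$col * patch_size, y0 = grid$row * patch_size)
}

#' Extract the pixels of one patch record
#'
#' @param image source H x W x 3 array.
#' @param record one row of [tile_image()] output (fields `x0`, `y0`).
#' @param patch_size patch side length.
#' @return A `patch_size` x `patch_size` x 3 array.
#' @export
extract_patch <- function(image, record, patch_size = 256L) {
  ys <- record$y0 + seq_len(patch_size)
  xs <- record$x0 + seq_len(patch_size)
  image[ys, xs, , drop = FALSE]
}

#' Label tiled patches using the case diagnosis and the expert selection table
#'
#' Patches from benign cases are labeled `benign` without review. Patches
#' from malignant cases require a row in the cytopathologists' selection
#' table: those flagged as containing malignant cells are labeled
#' `malignant`, the rest are kept with label `excluded` (flagged, not
#' dropped, for auditability). A malignant-case patch missing from the table
#' is an error — the selection step must be complete, not defaulted.
#'
#' @param patches data.frame from [tile_image()].
#' @param source source image identifier (matches `selection$source`).
#' @param case_id case identifier.
#' @param case_diagnosis `"benign"` or `"malignant"`.
#' @param selection data.frame with columns
#'   `source, row, col, contains_malignant`; may be `NULL` for benign cases.
#' @return A manifest data.frame with columns
#'   `path, case_id, label, split, source, row, col` (`path` empty until
#'   patches are written).
#' @export
label_patches <- function(patches, source, case_id, case_diagnosis,
                          selection = NULL) {
  case_diagnosis <- match.arg(case_diagnosis, c("benign", "malignant"))
  n <- nrow(patches)
  if (case_diagnosis == "benign") {
    label <- rep("benign", n)
  } else {
    if (is.null(selection)) {
      stop("malignant-case patches require a selection table", call. = FALSE)
    }
    sel <- selection[selection$source == source, , drop = FALSE]
    key <- paste(patches$row, patches$col)
    skey <- paste(sel$row, sel$col)
    idx <- match(key, skey)
    if (anyNA(idx)) {
      missing <- key[is.na(idx)][1L]
      stop("missing selection annotation for malignant-case patch (row col) ",
           missing, " of ", source, call. = FALSE)
    }
    label <- ifelse(sel$contains_malignant[idx], "malignant", "excluded")
  }
  data.frame(path = rep("", n), case_id = rep(case_id, n), label = label,
             split = rep("none", n), source = rep(source, n),
             row = patches$row, col = patches$col, stringsAsFactors = FALSE)
}

manifest_core_cols <- c("path", "case_id", "label", "split")

#' Write / read a patch manifest CSV
#'
#' The manifest is the table that flows between all pipeline stages. Core
#' columns are `path, case_id, label, split`; extra columns (tiling
#' coordinates, augmentation descriptors) are preserved. Round-trips are
#' exact, including row order.
#'
#' @param manifest a manifest data.frame.
#' @param path CSV file path.
#' @return `read_manifest` returns the manifest data.frame;
#'   `write_manifest` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(manifest_core_cols %in% names(manifest)))
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  if (!all(manifest_core_cols %in% names(m))) {
    stop("malformed manifest: header must contain ",
         paste(manifest_core_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in manifest_core_cols) m[[cc]] <- as.character(m[[cc]])
  for (cc in intersect(c("row", "col"), names(m))) m[[cc]] <- as.integer(m[[cc]])
  m
}

#' Tile a directory of source images into a labeled patch manifest
#'
#' Convenience wrapper: loads each source image, tiles it with
#' [tile_image()], labels patches via [label_patches()], optionally writes
#' the patch PNG files, and concatenates the per-image manifests.
#'
#' @param sources data.frame with columns `path, case_id, case_diagnosis`.
#' @param patch_size patch side length.
#' @param selection selection table (see [label_patches()]).
#' @param out_dir if non-`NULL`, patch PNGs are written here and `path` is
#'   filled in.
#' @return A manifest data.frame.
#' @export
tile_sources <- function(sources, patch_size = 256L, selection = NULL,
                         out_dir = NULL) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(sources))) {
    img <- load_image(sources$path[i])
    recs <- tile_image(img, patch_size)
    if (nrow(recs) == 0L) next
    man <- label_patches(recs, source = sources$path[i],
                         case_id = sources$case_id[i],
                         case_diagnosis = sources$case_diagnosis[i],
                         selection = selection)
    if (!is.null(out_dir)) {
      base <- tools::file_path_sans_ext(basename(sources$path[i]))
      for (j in seq_len(nrow(recs))) {
        fn <- file.path(out_dir, sprintf("%s_r%dc%d.png", base,
                                         recs$row[j], recs$col[j]))
        png::writePNG(extract_patch(img, recs[j, ], patch_size) / 255,
                      target = fn)
        man$path[j] <- fn
      }
    }
    out[[length(out) + 1L]] <- man
  }
  if (length(out) == 0L) {
    return(data.frame(path = character(0), case_id = character(0),
                      label = character(0), split = character(0),
                      source = character(0), row = integer(0),
                      col = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
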