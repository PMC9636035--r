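#' Construct a slide record
#'
#' Wraps an RGB image (8-bit 0..255 array or path to a PNG) together with
#' its identifiers and magnification metadata.
#'
#' @param pixels RGB array (height x width x 3, 0..255) or path to a PNG.
#' @param slide_id,patient_id identifiers.
#' @param magnification native objective power (e.g. 40).
#' @param microns_per_pixel optional physical pixel size.
#' @return a `slide_record`.
#' @export
slide_record <- function(pixels, slide_id, patient_id = NA_character_,
                         magnification = 40, microns_per_pixel = NULL) {
  if (is.character(pixels)) pixels <- read_png255(pixels)
  stopifnot_rgb(pixels, "slide pixels")
  if (magnification <= 0) stop("magnification must be > 0", call. = FALSE)
  structure(list(pixels = pixels, slide_id = slide_id,
                 patient_id = patient_id, magnification = magnification,
                 microns_per_pixel = microns_per_pixel),
            class = "slide_record")
}

#' Compute a tissue (foreground) mask by HSV saturation thresholding
#'
#' Stained tissue is saturated (pink/purple) while glass background is
#' near-white and unsaturated. The saturation channel is smoothed with a
#' 3x3 box blur before thresholding to suppress speckle.
#'
#' @param slide a [slide_record()] or RGB array.
#' @param saturation_threshold saturation above which a pixel counts as
#'   tissue (default 0.07).
#' @param blur_radius box-blur radius in pixels (default 1, i.e. 3x3).
#' @return a `tissue_mask`: list with logical `mask`, `tissue_fraction`,
#'   and the `magnification` it was computed at.
#' @export
compute_tissue_mask <- function(slide, saturation_threshold = 0.07,
                                blur_radius = 1L) {
  img <- if (inherits(slide, "slide_record")) slide$pixels else slide
  stopifnot_rgb(img, "slide")
  d <- dim(img)
  rgbm <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                as.vector(img[, , 3]))
  s <- grDevices::rgb2hsv(rgbm, maxColorValue = 255)["s", ]
  smat <- matrix(s, d[1], d[2])
  smat <- box_blur(smat, blur_radius)
  mask <- smat > saturation_threshold
  structure(list(mask = mask, tissue_fraction = mean(mask),
                 magnification = if (inherits(slide, "slide_record"))
                   slide$magnification else NA_real_),
            class = "tissue_mask")
}

#' Resample a slide to a lower working magnification
#'
#' Linear dimensions scale by `target / native`. Integer shrink factors use
#' area (block) averaging; non-integer factors fall back to bilinear
#' interpolation. Upsampling is refused.
#'
#' @param slide a [slide_record()].
#' @param target_magnification working power (default 10).
#' @return a [slide_record()] at the target magnification,
#'   `microns_per_pixel` scaled accordingly.
#' @export
resample_to_magnification <- function(slide, target_magnification = 10) {
  stopifnot(inherits(slide, "slide_record"))
  if (target_magnification > slide$magnification)
    stop("target magnification exceeds native magnification (no upsampling)",
         call. = FALSE)
  f <- slide$magnification / target_magnification
  if (f == 1) return(slide)
  d <- dim(slide$pixels)
  hh <- floor(d[1] / f); ww <- floor(d[2] / f)
  px <- round(clip255(resize_rgb(slide$pixels[seq_len(floor(hh * f)),
                                              seq_len(floor(ww * f)), ,
                                              drop = FALSE], hh, ww)))
  slide_record(px, slide$slide_id, slide$patient_id,
               magnification = target_magnification,
               microns_per_pixel = if (is.null(slide$microns_per_pixel)) NULL
                                   else slide$microns_per_pixel * f)
}

#' Tile a slide into tissue patches
#'
#' Lays a row-major grid of `patch_px` tiles with top-left corners at
#' multiples of `stride`, drops tiles extending past the image, and keeps a
#' tile iff its mean mask coverage is at least `min_tissue_fraction`.
#' Coordinates are 0-based `(x, y) = (column, row)` pixel offsets at the
#' slide's current magnification.
#'
#' @param slide a [slide_record()] at the working magnification.
#' @param mask a [compute_tissue_mask()] result aligned to `slide` (or
#'   `NULL` to keep every tile).
#' @param patch_px tile edge length (default 512).
#' @param stride grid stride; defaults to `patch_px` (non-overlapping).
#' @param min_tissue_fraction minimum mask coverage to keep a tile
#'   (default 0.5).
#' @return list of `piter_patch` objects (fields: slide_id, patient_id, x,
#'   y, size_px, magnification, tissue_fraction, pixels).
#' @export
tile_slide <- function(slide, mask = NULL, patch_px = 512L,
                       stride = patch_px, min_tissue_fraction = 0.5) {
  stopifnot(inherits(slide, "slide_record"), stride >= 1L)
  d <- dim(slide$pixels)
  if (patch_px > d[1] || patch_px > d[2]) {
    warning("patch_px exceeds image dimensions; no tiles produced")
    return(list())
  }
  m <- if (is.null(mask)) NULL else mask$mask
  if (!is.null(m) && !all(dim(m) == d[1:2]))
    stop("mask dimensions do not match slide", call. = FALSE)
  xs <- seq(0L, d[2] - patch_px, by = stride)
  ys <- seq(0L, d[1] - patch_px, by = stride)
  out <- list()
  for (y in ys) {       # row-major: rows outer, columns inner
    for (x in xs) {
      rows <- (y + 1L):(y + patch_px); cols <- (x + 1L):(x + patch_px)
      tf <- if (is.null(m)) 1 else mean(m[rows, cols])
      if (tf >= min_tissue_fraction) {
        out[[length(out) + 1L]] <- structure(
          list(slide_id = slide$slide_id, patient_id = slide$patient_id,
               x = x, y = y, size_px = patch_px,
               magnification = slide$magnification, tissue_fraction = tf,
               pixels = slide$pixels[rows, cols, , drop = FALSE]),
          class = "piter_patch")
      }
    }
  }
  out
}

#' Write tiled patches and their index CSV
#'
#' Files are named `<slide_id>_<x>_<y>.png`; the index CSV has columns
#' slide_id, patient_id, x, y, magnification, tissue_fraction.
#'
#' @param patches list of `piter_patch` from [tile_slide()].
#' @param out_dir output directory (created if needed).
#' @return path of the index CSV.
#' @export
write_patches <- function(patches, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- NULL
  for (p in patches) {
    fn <- sprintf("%s_%d_%d.png", p$slide_id, p$x, p$y)
    write_png255(p$pixels, file.path(out_dir, fn))
    rows <- rbind(rows, data.frame(slide_id = p$slide_id,
                                   patient_id = p$patient_id, x = p$x,
                                   y = p$y, magnification = p$magnification,
                                   tissue_fraction = p$tissue_fraction,
                                   stringsAsFactors = FALSE))
  }
  idx <- file.path(out_dir, "patches.csv")
  utils::write.csv(rows, idx, row.names = FALSE)
  idx
}
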