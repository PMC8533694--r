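#' Calibrated image stack
#'
#' The unit of raw input: a single-channel 3D intensity volume with pixel
#' calibration. Voxels are stored as a numeric array with dimensions
#' \code{(z, y, x)}; slice \code{k} is \code{voxels[k, , ]}.
#'
#' @param voxels numeric 3D array \code{(z, y, x)} of non-negative
#'   intensities (a 2D matrix is promoted to a single-slice stack).
#' @param pixel_size_um lateral calibration, micrometres per pixel
#'   (x = y assumed); must be a single positive number.
#' @param z_step_um axial step in micrometres (informational, may be `NA`).
#' @param bit_depth 8, 16 or `"float"`; integer depths bound intensities by
#'   `2^bit_depth - 1`.
#' @param image_id,channel,group identifiers carried through the pipeline.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(voxels, pixel_size_um, z_step_um = NA_real_,
                        bit_depth = 16, image_id = "img", channel = "ch1",
                        group = "") {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("'voxels' must be a (z, y, x) array or a 2D matrix")
  }
  if (dim(voxels)[1] < 1L) stop("stack must have at least one slice")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("'pixel_size_um' must be a single positive number")
  }
  if (anyNA(voxels) || any(voxels < 0)) {
    stop("intensities must be non-negative and non-missing")
  }
  if (!identical(bit_depth, "float")) {
    bit_depth <- as.integer(bit_depth)
    if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8, 16 or \"float\"")
    if (any(voxels > 2^bit_depth - 1)) {
      stop("intensities exceed 2^bit_depth - 1")
    }
  }
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, bit_depth = bit_depth,
                 image_id = as.character(image_id),
                 channel = as.character(channel),
                 group = as.character(group)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ImageStack '%s' [%s/%s]: %d slice(s) of %d x %d px, %.4g um/px, depth %s\n",
              x$image_id, x$channel,
              if (nzchar(x$group)) x$group else "-",
              d[1], d[2], d[3], x$pixel_size_um, as.character(x$bit_depth)))
  invisible(x)
}

#' Calibrated 2D image
#'
#' A projected (or single-slice) floating-point image carrying its
#' calibration and a provenance trail of the operations applied so far.
#'
#' @param pixels numeric matrix (y, x).
#' @param pixel_size_um micrometres per pixel.
#' @param image_id,channel,group identifiers.
#' @param provenance character vector of applied operations (append-only).
#' @return An object of class `CalibratedImage`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, image_id = "img",
                             channel = "ch1", group = "",
                             provenance = character()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) stop("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels))) stop("pixel values must be finite")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("'pixel_size_um' must be positive")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 image_id = as.character(image_id),
                 channel = as.character(channel),
                 group = as.character(group),
                 provenance = as.character(provenance)),
            class = "CalibratedImage")
}

#' @export
print.CalibratedImage <- function(x, ...) {
  cat(sprintf("CalibratedImage '%s' [%s/%s]: %d x %d px, %.4g um/px\n",
              x$image_id, x$channel,
              if (nzchar(x$group)) x$group else "-",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Binary foreground mask
#'
#' @param pixels logical matrix (y, x); `TRUE` = foreground.
#' @param pixel_size_um micrometres per pixel.
#' @param image_id identifier.
#' @param threshold_used the intensity cutoff that produced the mask
#'   (`NA` for masks not produced by thresholding, e.g. rasterized ROIs).
#' @return An object of class `BinaryMask`.
#' @export
binary_mask <- function(pixels, pixel_size_um, image_id = "img",
                        threshold_used = NA_real_) {
  if (!is.matrix(pixels) || !is.logical(pixels)) stop("'pixels' must be a logical matrix")
  if (anyNA(pixels)) stop("mask must not contain NA")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 image_id = as.character(image_id),
                 threshold_used = threshold_used),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("BinaryMask '%s': %d x %d px, %d foreground px (threshold %s)\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              format(x$threshold_used)))
  invisible(x)
}

# internal: accept CalibratedImage or bare matrix, return matrix
.as_pixels <- function(img) {
  if (inherits(img, "CalibratedImage")) return(img$pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a CalibratedImage or a numeric matrix")
}
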