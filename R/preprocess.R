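#' Square-neighbourhood mean filter
#'
#' Replaces every pixel by the arithmetic mean of the \eqn{(2r+1)^2} square
#' (Chebyshev) neighbourhood centred on it, slice by slice for stacks.
#' Edges are replicate-padded, so the output is defined everywhere and has
#' the same shape as the input. Because an extreme value contributes to
#' every window containing it, an isolated hot pixel is attenuated but
#' smeared over its whole neighbourhood -- the reason the median filter is
#' the preferred default for artifact removal.
#'
#' @param img an `ImageStack`, `CalibratedImage` or numeric matrix.
#' @param radius integer neighbourhood radius, >= 1. Radius 1 is the
#'   classical 3x3 "pixel and its direct neighbours" filter.
#' @return Same type as the input, floating point, with provenance updated.
#' @seealso [median_filter()], [z_project()]
#' @export
mean_filter <- function(img, radius = 1L) {
  .apply_filter(img, radius, box_mean_cpp, "mean_filter")
}

#' Square-neighbourhood median filter
#'
#' Replaces every pixel by the median of the \eqn{(2r+1)^2} square
#' neighbourhood centred on it, slice by slice for stacks, with
#' replicate-edge padding. With radius 1, any pixel whose 8 neighbours all
#' lie at or below a level `T` is mapped to a value at or below `T`: isolated
#' aberrant-high pixels are removed outright rather than smeared, and object
#' edges are preserved.
#'
#' @inheritParams mean_filter
#' @return Same type as the input, floating point, with provenance updated.
#' @export
median_filter <- function(img, radius = 1L) {
  .apply_filter(img, radius, box_median_cpp, "median_filter")
}

.apply_filter <- function(img, radius, kernel, opname) {
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 1L) {
    stop("'radius' must be a single integer >= 1")
  }
  tag <- sprintf("%s(radius=%d)", opname, radius)
  if (inherits(img, "ImageStack")) {
    v <- img$voxels
    out <- array(0, dim = dim(v))
    for (k in seq_len(dim(v)[1])) {
      out[k, , ] <- kernel(v[k, , , drop = TRUE], radius)
    }
    res <- img
    res$voxels <- out
    res$bit_depth <- "float"
    attr(res, "provenance") <- c(attr(img, "provenance"), tag)
    return(res)
  }
  if (inherits(img, "CalibratedImage")) {
    res <- img
    res$pixels <- kernel(img$pixels, radius)
    res$provenance <- c(img$provenance, tag)
    return(res)
  }
  if (is.matrix(img) && is.numeric(img)) return(kernel(img, radius))
  stop("expected an ImageStack, CalibratedImage or numeric matrix")
}

#' Z-projection of a stack to a 2D image
#'
#' Collapses the z axis by one of three per-pixel reductions: `"average"`
#' (mean over slices), `"max"` (maximum intensity, the default protocol
#' choice -- it enhances contrast between punctate signal and background),
#' or `"sum"` (sum of slices; equals `n_slices` times the average).
#'
#' @param stack an `ImageStack` with at least one slice.
#' @param method `"max"`, `"average"` or `"sum"`.
#' @return A `CalibratedImage` with the stack's calibration and identifiers.
#' @export
z_project <- function(stack, method = c("max", "average", "sum")) {
  if (!inherits(stack, "ImageStack")) stop("expected an ImageStack")
  method <- match.arg(method)
  v <- stack$voxels
  nz <- dim(v)[1]
  px <- switch(method,
    max     = Reduce(pmax, lapply(seq_len(nz), function(k) v[k, , , drop = TRUE])),
    average = colMeans(v, dims = 1),
    sum     = colSums(v, dims = 1)
  )
  if (!is.matrix(px)) px <- matrix(px, dim(v)[2], dim(v)[3])
  calibrated_image(px, stack$pixel_size_um, image_id = stack$image_id,
                   channel = stack$channel, group = stack$group,
                   provenance = c(attr(stack, "provenance"),
                                  sprintf("z_project(method=%s, n_slices=%d)",
                                          method, nz)))
}
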