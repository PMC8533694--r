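#' Polygonal region of interest
#'
#' An ordered, implicitly closed polygon in pixel coordinates. The
#' convention throughout the package is 0-based coordinates with `x` along
#' columns and `y` along rows; pixel `(row r, col c)` occupies the unit
#' square `[c, c+1) x [r, r+1)` and its centre sits at `(c + 0.5, r + 0.5)`.
#'
#' @param vertices two-column numeric matrix (or data.frame) of `(x, y)`
#'   vertices, at least 3, enclosing a non-zero area.
#' @return An object of class `RegionOfInterest`.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L || anyNA(v)) {
    stop("a region of interest needs at least 3 finite (x, y) vertices")
  }
  x <- v[, 1]; y <- v[, 2]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)  # shoelace
  if (abs(area2) < .Machine$double.eps * 4) stop("polygon has zero area")
  structure(list(vertices = unname(v)), class = "RegionOfInterest")
}

#' Read a region of interest from a vertex file
#'
#' Accepts a CSV with `x,y` header or plain whitespace-separated `x y`
#' lines (the common export of interactive polygon tools).
#'
#' @param path file of polygon vertices.
#' @return A `RegionOfInterest`.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  first <- readLines(path, n = 1L)
  v <- if (grepl("[A-Za-z]", first)) {
    read.csv(path)[, 1:2]
  } else {
    read.table(path, header = FALSE)[, 1:2]
  }
  roi_polygon(as.matrix(v))
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its centre lies inside the polygon under
#' the even-odd rule; centres exactly on the boundary are included.
#'
#' @param roi a `RegionOfInterest`.
#' @param shape image shape `c(h, w)` in pixels.
#' @param pixel_size_um calibration to record on the mask.
#' @return A `BinaryMask`.
#' @export
rasterize_roi <- function(roi, shape, pixel_size_um = 1) {
  if (!inherits(roi, "RegionOfInterest")) stop("expected a RegionOfInterest")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stop("'shape' must be positive c(h, w)")
  h <- shape[1]; w <- shape[2]
  cx <- rep(seq_len(w) - 0.5, each = h)   # pixel-centre x, column-major
  cy <- rep(seq_len(h) - 0.5, times = w)  # pixel-centre y
  inside <- .point_in_polygon(cx, cy, roi$vertices)
  binary_mask(matrix(inside, h, w), pixel_size_um = pixel_size_um,
              image_id = "roi", threshold_used = NA_real_)
}

# Even-odd ray casting, vectorized over points; boundary points included.
.point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    cross <- (px - xi) * dy - (py - yi) * dx
    dot <- (px - xi) * dx + (py - yi) * dy
    len2 <- dx * dx + dy * dy
    on_edge <- on_edge | (abs(cross) < 1e-9 * max(1, sqrt(len2)) & dot >= 0 & dot <= len2)
    # crossing test (half-open in y to count shared vertices once)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Label connected foreground components
#'
#' Maximal connected components of the foreground under 4- or 8-adjacency
#' (8 by default, matching the behaviour classical particle analyzers rely
#' on). Labels run 1..N in scan order; background is 0.
#'
#' @param mask a `BinaryMask` or logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer label matrix with attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  m <- if (inherits(mask, "BinaryMask")) mask$pixels else mask
  if (!is.logical(m) || !is.matrix(m)) stop("expected a BinaryMask or logical matrix")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  label_components_cpp(m, connectivity)
}

#' Measure labeled particles
#'
#' One record per label: pixel and physical-unit area, centroid (pixel-
#' centre convention, so a 2x2 square at the image origin has centroid
#' `(1, 1)`), half-open bounding box, chain-code perimeter (straight steps
#' 1, diagonal steps `sqrt(2)`; single pixels use the unit-square outline
#' length 4), circularity `min(1, 4*pi*A/P^2)` and equivalent-circle
#' diameter `2*sqrt(A/pi)`. The chain-code perimeter of a digital disc
#' slightly underestimates the true circumference, so digital discs can
#' reach the circularity cap of 1.
#'
#' @param labels integer label matrix from [label_components()].
#' @param pixel_size_um micrometres per pixel.
#' @return data.frame of class `ParticleRecord` columns: `label`,
#'   `area_px`, `area_um2`, `centroid_x`, `centroid_y`, `bbox_x0`,
#'   `bbox_y0`, `bbox_x1`, `bbox_y1`, `perimeter_um`, `circularity`,
#'   `equiv_diameter_um`.
#' @export
measure_particles <- function(labels, pixel_size_um) {
  n <- attr(labels, "n_components")
  if (is.null(n)) n <- max(0L, max(labels))
  if (n == 0L) return(.empty_particles())
  idx <- which(labels > 0)
  lab <- labels[idx]
  rc <- arrayInd(idx, dim(labels))
  r0 <- rc[, 1] - 1L  # 0-based row (y)
  c0 <- rc[, 2] - 1L  # 0-based col (x)
  area_px <- tabulate(lab, nbins = n)
  cx <- rowsum(c0 + 0.5, lab)[, 1] / area_px
  cy <- rowsum(r0 + 0.5, lab)[, 1] / area_px
  x0 <- tapply(c0, lab, min); x1 <- tapply(c0, lab, max) + 1L
  y0 <- tapply(r0, lab, min); y1 <- tapply(r0, lab, max) + 1L
  per_px <- perimeter_cpp(labels, as.integer(n))
  area_um2 <- area_px * pixel_size_um^2
  perimeter_um <- per_px * pixel_size_um
  circ <- pmin(1, 4 * pi * area_um2 / perimeter_um^2)
  out <- data.frame(
    label = seq_len(n), area_px = area_px, area_um2 = area_um2,
    centroid_x = as.numeric(cx), centroid_y = as.numeric(cy),
    bbox_x0 = as.numeric(x0), bbox_y0 = as.numeric(y0),
    bbox_x1 = as.numeric(x1), bbox_y1 = as.numeric(y1),
    perimeter_um = perimeter_um, circularity = circ,
    equiv_diameter_um = 2 * sqrt(area_um2 / pi)
  )
  class(out) <- c("ParticleRecord", "data.frame")
  out
}

.empty_particles <- function() {
  out <- data.frame(label = integer(), area_px = integer(), area_um2 = numeric(),
                    centroid_x = numeric(), centroid_y = numeric(),
                    bbox_x0 = numeric(), bbox_y0 = numeric(),
                    bbox_x1 = numeric(), bbox_y1 = numeric(),
                    perimeter_um = numeric(), circularity = numeric(),
                    equiv_diameter_um = numeric())
  class(out) <- c("ParticleRecord", "data.frame")
  out
}

#' Filter particles by physical size and circularity
#'
#' Applied after measurement, so filtering never has to be redone from the
#' image. The default size criterion is the equivalent-circle diameter (a
#' length, directly comparable to a nucleus diameter such as the common
#' "> 2 um" rule); an area criterion in um^2 is also available since some
#' particle analyzers filter on area. The minimum is strict (`>`), the
#' maximum inclusive (`<=`); circularity bounds are inclusive.
#'
#' @param particles a `ParticleRecord` data.frame.
#' @param min_diameter_um,max_diameter_um equivalent-diameter bounds (um),
#'   `NULL` to skip.
#' @param circ_range inclusive circularity range, default `c(0, 1)`.
#' @param min_area_um2,max_area_um2 optional area bounds (um^2).
#' @return The surviving subset, same class.
#' @export
filter_particles <- function(particles, min_diameter_um = NULL,
                             max_diameter_um = NULL, circ_range = c(0, 1),
                             min_area_um2 = NULL, max_area_um2 = NULL) {
  if (!is.null(min_diameter_um) && !is.null(max_diameter_um) &&
      !(min_diameter_um >= 0 && min_diameter_um < max_diameter_um)) {
    stop("need 0 <= min_diameter_um < max_diameter_um")
  }
  if (!is.null(min_area_um2) && !is.null(max_area_um2) &&
      !(min_area_um2 >= 0 && min_area_um2 < max_area_um2)) {
    stop("need 0 <= min_area_um2 < max_area_um2")
  }
  keep <- rep(TRUE, nrow(particles))
  if (!is.null(min_diameter_um)) keep <- keep & particles$equiv_diameter_um > min_diameter_um
  if (!is.null(max_diameter_um)) keep <- keep & particles$equiv_diameter_um <= max_diameter_um
  if (!is.null(min_area_um2)) keep <- keep & particles$area_um2 > min_area_um2
  if (!is.null(max_area_um2)) keep <- keep & particles$area_um2 <= max_area_um2
  keep <- keep & particles$circularity >= circ_range[1] &
    particles$circularity <= circ_range[2]
  particles[keep, , drop = FALSE]
}

#' Quantify one image: binarize, restrict, label, measure, filter
#'
#' The "particle analysis" stage: threshold the projected image, intersect
#' with the region of interest (if any), label 8-connected components,
#' measure them, apply the size/circularity filters, and report the two
#' readouts -- object count and total stained area. Adjacent stained cells
#' that touch merge into a single object, so under heavy clustering the
#' count readout underestimates the number of events while the area readout
#' does not.
#'
#' @param img a `CalibratedImage` (typically filtered and z-projected).
#' @param T threshold intensity (foreground strictly above `T`).
#' @param roi optional `RegionOfInterest` restricting quantification.
#' @param min_diameter_um,max_diameter_um,circ_range particle filters, see
#'   [filter_particles()]. The protocol default is `min_diameter_um = 2`.
#' @param connectivity 4 or 8 (default).
#' @param threshold_mode binarization comparison, `">"` or `">="`.
#' @return A `QuantResult`: list with `image_id`, `group`, `count`,
#'   `total_area_um2`, `particles` (surviving), `removed` (filtered-out
#'   particles, for conservation checks), `filters_applied`,
#'   `threshold_used`.
#' @export
quantify_image <- function(img, T, roi = NULL, min_diameter_um = NULL,
                           max_diameter_um = NULL, circ_range = c(0, 1),
                           connectivity = 8L, threshold_mode = ">") {
  if (!inherits(img, "CalibratedImage")) stop("expected a CalibratedImage")
  mask <- binarize(img, T, mode = threshold_mode)
  if (!is.null(roi)) {
    rmask <- rasterize_roi(roi, dim(img$pixels), img$pixel_size_um)
    mask$pixels <- mask$pixels & rmask$pixels
  }
  labels <- label_components(mask, connectivity)
  particles <- measure_particles(labels, img$pixel_size_um)
  kept <- filter_particles(particles, min_diameter_um, max_diameter_um, circ_range)
  removed <- particles[!particles$label %in% kept$label, , drop = FALSE]
  structure(list(
    image_id = img$image_id, group = img$group,
    count = nrow(kept), total_area_um2 = sum(kept$area_um2),
    particles = kept, removed = removed,
    filters_applied = list(min_diameter_um = min_diameter_um,
                           max_diameter_um = max_diameter_um,
                           circ_range = circ_range,
                           connectivity = connectivity),
    threshold_used = T
  ), class = "QuantResult")
}

#' @export
print.QuantResult <- function(x, ...) {
  cat(sprintf("QuantResult '%s' [%s]: %d particle(s), total stained area %.3f um^2 (T = %s)\n",
              x$image_id, if (nzchar(x$group)) x$group else "-",
              x$count, x$total_area_um2, format(x$threshold_used)))
  invisible(x)
}
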