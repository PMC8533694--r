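#' Intensity histogram of a calibrated image
#'
#' Bins the (optionally masked) pixel intensities into `n_bins` equal-width
#' bins spanning the observed min..max range. Values equal to the maximum
#' fall in the last bin. The histogram is the sole input to the automatic
#' threshold algorithms, mirroring how histogram-based thresholding is
#' defined.
#'
#' A constant image yields a degenerate single-value range; the histogram is
#' still returned (with a synthetic unit-width bin) but flagged
#' `degenerate = TRUE`, and [auto_threshold()] refuses it.
#'
#' @param img `CalibratedImage` or numeric matrix.
#' @param n_bins number of bins, >= 2 (default 256, the 8-bit convention
#'   that the classical algorithms assume).
#' @param mask optional `BinaryMask` (or logical matrix) restricting the
#'   histogram to a region of interest; must match the image shape and
#'   cover at least one pixel.
#' @return An object of class `IntensityHistogram`: list with `bin_edges`
#'   (`n_bins + 1` ascending values), `counts`, `total`, `source_range`,
#'   `degenerate`.
#' @export
compute_histogram <- function(img, n_bins = 256L, mask = NULL) {
  px <- .as_pixels(img)
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 2L) {
    stop("'n_bins' must be a single integer >= 2")
  }
  if (!is.null(mask)) {
    m <- if (inherits(mask, "BinaryMask")) mask$pixels else mask
    if (!is.logical(m) || !identical(dim(m), dim(px))) {
      stop("mask must be a logical array of the same shape as the image")
    }
    if (!any(m)) stop("mask covers no pixels")
    px <- px[m]
  }
  v <- as.numeric(px)
  lo <- min(v); hi <- max(v)
  degenerate <- (hi <= lo)
  if (degenerate) hi <- lo + 1  # synthetic unit range so edges stay strictly increasing
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  w <- (hi - lo) / n_bins
  idx <- pmin(floor((v - lo) / w), n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts, total = length(v),
                 source_range = c(lo, if (degenerate) lo else hi),
                 degenerate = degenerate),
            class = "IntensityHistogram")
}

#' @export
print.IntensityHistogram <- function(x, ...) {
  cat(sprintf("IntensityHistogram: %d bins over [%.4g, %.4g], %d pixels%s\n",
              length(x$counts), x$source_range[1], x$source_range[2],
              x$total, if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Automatic histogram thresholding
#'
#' Computes a binarization cutoff from an intensity histogram by one of
#' four classical algorithms. Foreground is defined downstream as pixels
#' strictly greater than the returned value (see [binarize()]). The
#' returned threshold is the lower edge of the selected bin; ties between
#' equally optimal bins are broken to the lowest bin, deterministically.
#'
#' \describe{
#'   \item{otsu}{maximizes the between-class variance
#'     \eqn{\omega_0\omega_1(\mu_0-\mu_1)^2} over all splits.}
#'   \item{moments}{moment-preserving selection: the first three histogram
#'     moments determine a two-level image with the same moments; the
#'     threshold is placed where the cumulative pixel fraction first
#'     reaches the background fraction \eqn{p_0}.}
#'   \item{isodata}{iterates \eqn{T \leftarrow (\mu_{\le T} + \mu_{>T})/2}
#'     to a fixed point, starting from the overall mean.}
#'   \item{intermode}{smooths the histogram with a 3-bin moving average
#'     until exactly two local maxima remain (iteration cap 10000), and
#'     returns the midpoint of the two modes.}
#' }
#'
#' @param hist an `IntensityHistogram` with at least two occupied bins.
#' @param method `"otsu"`, `"moments"`, `"isodata"` or `"intermode"`.
#' @return A single threshold intensity, in the units of the source image.
#' @export
auto_threshold <- function(hist, method = c("otsu", "moments", "isodata", "intermode")) {
  method <- match.arg(method)
  if (!inherits(hist, "IntensityHistogram")) stop("expected an IntensityHistogram")
  if (isTRUE(hist$degenerate) || sum(hist$counts > 0) < 2L) {
    stop("degenerate histogram: need at least two occupied bins to split")
  }
  switch(method,
    otsu      = .thr_otsu(hist),
    moments   = .thr_moments(hist),
    isodata   = .thr_isodata(hist),
    intermode = .thr_intermode(hist)
  )
}

# lower edges = representative value of each bin
.bin_values <- function(hist) hist$bin_edges[-(length(hist$counts) + 1L)]

.thr_otsu <- function(hist) {
  p <- hist$counts / hist$total
  v <- .bin_values(hist)
  n <- length(p)
  w0 <- cumsum(p)
  mu <- cumsum(p * v)
  mu_tot <- mu[n]
  # split after bin t: class0 = bins 1..t, class1 = rest
  t_cand <- seq_len(n - 1L)
  w0t <- w0[t_cand]
  w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  bcv <- rep(-Inf, n - 1L)
  mu0 <- mu[t_cand] / w0t
  mu1 <- (mu_tot - mu[t_cand]) / w1t
  bcv[valid] <- (w0t * w1t * (mu0 - mu1)^2)[valid]
  best <- which(bcv >= max(bcv) - 0)[1L]  # lowest optimizing bin
  v[best]
}

.thr_moments <- function(hist) {
  p <- hist$counts / hist$total
  n <- length(p)
  z <- seq_len(n) - 1  # bin indices; p0 is invariant to the affine bin->intensity map
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1 * m1
  if (cd <= 0) stop("moment-preserving threshold undefined: zero variance histogram")
  c0 <- (-m2 * m2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1 * c1 - 4 * c0
  if (disc < 0) stop("moment-preserving threshold undefined: complex representative levels")
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- cumsum(p)
  best <- which(cum >= p0 - 1e-12)[1L]  # lowest bin reaching the background fraction
  if (is.na(best)) best <- n
  .bin_values(hist)[best]
}

.thr_isodata <- function(hist) {
  p <- hist$counts
  v <- .bin_values(hist)
  occ <- p > 0
  T <- sum(p * v) / sum(p)  # start at the overall mean
  for (i in seq_len(1000L)) {
    below <- occ & v <= T
    above <- occ & v > T
    if (!any(below) || !any(above)) break
    Tn <- (sum(p[below] * v[below]) / sum(p[below]) +
           sum(p[above] * v[above]) / sum(p[above])) / 2
    if (abs(Tn - T) < 1e-9) { T <- Tn; break }
    T <- Tn
  }
  # snap to the lower edge of the containing bin
  edges <- hist$bin_edges
  bin <- findInterval(T, edges, rightmost.closed = TRUE)
  bin <- min(max(bin, 1L), length(v))
  v[bin]
}

.thr_intermode <- function(hist) {
  h <- as.numeric(hist$counts)
  n <- length(h)
  if (n < 3L) stop("intermode needs at least 3 bins")
  v <- .bin_values(hist)
  n_modes <- function(y) {
    i <- 2:(length(y) - 1L)
    sum(y[i] > y[i - 1L] & y[i] > y[i + 1L])
  }
  it <- 0L
  while (n_modes(h) != 2L) {
    it <- it + 1L
    if (it > 10000L) stop("intermode: histogram failed to become bimodal within 10000 smoothing passes")
    h <- (c(h[1], h[-n]) + h + c(h[-1], h[n])) / 3  # 3-bin moving average, replicated ends
  }
  i <- 2:(n - 1L)
  modes <- i[h[i] > h[i - 1L] & h[i] > h[i + 1L]]
  Tv <- (v[modes[1L]] + v[modes[2L]]) / 2
  edges <- hist$bin_edges
  bin <- min(max(findInterval(Tv, edges, rightmost.closed = TRUE), 1L), n)
  v[bin]
}

#' Consensus (median-of-medians) threshold
#'
#' Computes a single threshold to apply uniformly across an experiment:
#' the median of the per-image threshold values is taken within each
#' experimental group, then the median of those group medians is returned.
#' Group-first aggregation avoids giving more weight to a group that simply
#' has more images. Even-length medians are the mean of the two central
#' values, as usual.
#'
#' @param records data.frame with columns `group`, `value` and (optionally)
#'   `channel`; typically a threshold table read by
#'   [read_threshold_table()]. All records must share one channel, and every
#'   group must contribute at least one finite value.
#' @return The consensus threshold intensity.
#' @export
consensus_threshold <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("group", "value") %in% names(records)) || nrow(records) == 0L) {
    stop("records must be a non-empty data.frame with 'group' and 'value' columns")
  }
  if ("channel" %in% names(records) && length(unique(records$channel)) > 1L) {
    stop("consensus threshold must be computed within a single channel")
  }
  if (anyNA(records$value) || !is.numeric(records$value)) {
    stop("every record must carry a finite threshold value")
  }
  if (any(!nzchar(as.character(records$group)))) stop("every group label must be non-empty")
  med <- tapply(records$value, as.character(records$group), median)
  median(as.numeric(med))
}

#' Binarize an image at a threshold
#'
#' Foreground ("white") is every pixel whose intensity is strictly greater
#' than `T`; everything at or below `T` becomes background ("black"). The
#' comparison can be switched to `>=` for cross-checking against tools that
#' use the inclusive convention.
#'
#' @param img `CalibratedImage` or numeric matrix.
#' @param T finite threshold intensity.
#' @param mode `">"` (default) or `">="`.
#' @return A `BinaryMask` recording the threshold used.
#' @export
binarize <- function(img, T, mode = c(">", ">=")) {
  mode <- match.arg(mode)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T)) stop("'T' must be a single finite number")
  px <- .as_pixels(img)
  fg <- if (mode == ">") px > T else px >= T
  binary_mask(fg,
              pixel_size_um = if (inherits(img, "CalibratedImage")) img$pixel_size_um else 1,
              image_id = if (inherits(img, "CalibratedImage")) img$image_id else "img",
              threshold_used = T)
}
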