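#' Synthetic scene specification
#'
#' Describes a calibrated ground-truth z-stack emulating a monolayer
#' epithelium with apoptotic staining. Two staining geometries are
#' supported: `"nuclear"` (punctate, TUNEL-like: small well-separated
#' spots) and `"cytosolic"` (cleaved-caspase-like: larger filled discs
#' whose clusters merge into single objects). Three defect classes can be
#' layered on top: diffuse Gaussian background noise (`noise_sd`), isolated
#' aberrant-high pixels (`hot_pixel_rate`), and grouped aberrant-high
#' pixels below the particle size limit (`hot_cluster_rate`).
#'
#' Objects are soft-edged discs: a flat top with a 1-pixel raised-cosine
#' shoulder whose half-maximum sits exactly at the nominal radius, so the
#' ground-truth mask (disc of the nominal radius) is what a mid-range
#' threshold recovers. Ground truth is defined on the noiseless,
#' defect-free signal.
#'
#' @param shape `c(n_z, h, w)` in pixels.
#' @param pixel_size_um micrometres per pixel (default 0.5).
#' @param staining `"nuclear"` or `"cytosolic"`.
#' @param n_cells number of stained cells for nuclear scenes.
#' @param event_rate apoptotic events per 1000 um^2 for cytosolic scenes.
#' @param cluster_strength 0..1; 0 = uniform placement (with enforced
#'   separation for nuclear scenes), 1 = strongly aggregated
#'   parent-offspring clustering.
#' @param object_diameter_um stained-object diameter; defaults 3.5 um
#'   (nucleus-like) for nuclear, 7 um (cell-sized) for cytosolic.
#' @param signal_level,background_level object and background intensities.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param hot_pixel_rate isolated aberrant-high pixels per 1000 image
#'   pixels.
#' @param hot_cluster_rate aberrant-high pixel groups per image (each with
#'   equivalent diameter below the particle size limit).
#' @param bit_depth 8 or 16.
#' @param seed integer; fixes all randomness of the scene.
#' @return An object of class `SceneSpec`.
#' @export
scene_spec <- function(shape = c(8L, 512L, 512L), pixel_size_um = 0.5,
                       staining = c("nuclear", "cytosolic"), n_cells = 25L,
                       event_rate = 2, cluster_strength = 0,
                       object_diameter_um = NULL, signal_level = 3000,
                       background_level = 300, noise_sd = 30,
                       hot_pixel_rate = 0, hot_cluster_rate = 0,
                       bit_depth = 16L, seed = 1L) {
  staining <- match.arg(staining)
  if (is.null(object_diameter_um)) {
    object_diameter_um <- if (staining == "nuclear") 3.5 else 7.0
  }
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("'shape' must be c(n_z, h, w)")
  if (object_diameter_um <= 2 * pixel_size_um) {
    stop("object diameter must exceed 2 pixels")
  }
  for (nm in c("event_rate", "cluster_strength", "noise_sd", "hot_pixel_rate",
               "hot_cluster_rate", "signal_level", "background_level")) {
    if (get(nm) < 0) stop("'", nm, "' must be >= 0")
  }
  if (cluster_strength > 1) stop("'cluster_strength' must be in [0, 1]")
  structure(list(shape = shape, pixel_size_um = pixel_size_um,
                 staining = staining, n_cells = as.integer(n_cells),
                 event_rate = event_rate, cluster_strength = cluster_strength,
                 object_diameter_um = object_diameter_um,
                 signal_level = signal_level,
                 background_level = background_level, noise_sd = noise_sd,
                 hot_pixel_rate = hot_pixel_rate,
                 hot_cluster_rate = hot_cluster_rate,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "SceneSpec")
}

#' Simulate a calibrated scene with exact ground truth
#'
#' Generates the stack described by a [scene_spec()]: objects placed in a
#' contiguous z-band (the middle half of the stack, emulating a monolayer),
#' additive Gaussian background everywhere, optional injected hot pixels
#' and sub-size hot clusters, intensities clipped to the bit depth. Ground
#' truth (object count, per-object masks, union stained area) is computed
#' from the noiseless object masks before noise and defects are added.
#'
#' With `cluster_strength = 0`, nuclear scenes enforce a minimum
#' centre-to-centre distance so every object is separated from its
#' neighbours by background; cytosolic placements may always overlap.
#'
#' @param spec a `SceneSpec`.
#' @param image_id,group identifiers stamped on the stack.
#' @param size_limit_um particle size limit that injected hot clusters must
#'   stay strictly below (default 2 um).
#' @return list with `stack` (an `ImageStack`), `truth` (a `GroundTruth`:
#'   `true_count`, `true_area_um2`, `object_masks` as pixel-index vectors,
#'   `union` logical matrix, `defects` inventory data.frame).
#' @export
simulate_scene <- function(spec, image_id = "scene", group = "",
                           size_limit_um = 2) {
  stopifnot(inherits(spec, "SceneSpec"))
  set.seed(spec$seed)
  nz <- spec$shape[1]; h <- spec$shape[2]; w <- spec$shape[3]
  px <- spec$pixel_size_um
  r_px <- spec$object_diameter_um / 2 / px
  n_obj <- if (spec$staining == "nuclear") spec$n_cells else
    round(spec$event_rate * h * w * px^2 / 1000)

  centers <- .place_centers(n_obj, h, w, r_px, spec$staining, spec$cluster_strength)

  # noiseless 2D signal and per-object truth masks
  signal <- matrix(0, h, w)
  object_masks <- vector("list", nrow(centers))
  union <- matrix(FALSE, h, w)
  edge_w <- 1  # px, raised-cosine shoulder half-width
  for (k in seq_len(nrow(centers))) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    i0 <- max(1, floor(cy - r_px - edge_w - 1)); i1 <- min(h, ceiling(cy + r_px + edge_w + 1))
    j0 <- max(1, floor(cx - r_px - edge_w - 1)); j1 <- min(w, ceiling(cx + r_px + edge_w + 1))
    ii <- i0:i1; jj <- j0:j1
    d <- sqrt(outer((ii - 0.5 - cy)^2, (jj - 0.5 - cx)^2, `+`))
    prof <- ifelse(d <= r_px - edge_w, 1,
                   ifelse(d >= r_px + edge_w, 0,
                          0.5 * (1 + cos(pi * (d - (r_px - edge_w)) / (2 * edge_w)))))
    signal[ii, jj] <- pmax(signal[ii, jj], prof * spec$signal_level)
    m <- matrix(FALSE, h, w)
    m[ii, jj] <- d <= r_px
    object_masks[[k]] <- which(m)
    union <- union | m
  }

  band <- .z_band(nz)
  vox <- array(0, dim = c(nz, h, w))
  for (z in band) vox[z, , ] <- signal
  vox <- vox + spec$background_level
  if (spec$noise_sd > 0) vox <- vox + rnorm(length(vox), 0, spec$noise_sd)
  maxv <- 2^spec$bit_depth - 1
  vox <- pmin(pmax(vox, 0), maxv)
  vox <- round(vox)

  stack <- image_stack(vox, pixel_size_um = px, bit_depth = spec$bit_depth,
                       image_id = image_id,
                       channel = if (spec$staining == "nuclear") "nuclear" else "cytosolic",
                       group = group)

  defects <- .empty_defects()
  if (spec$hot_pixel_rate > 0 || spec$hot_cluster_rate > 0) {
    avoid <- box_mean_cpp(union + 0, 2L) > 0  # keep artifacts off (and away from) objects
    inj <- inject_artifacts(stack, spec, avoid = avoid, size_limit_um = size_limit_um)
    stack <- inj$stack
    defects <- inj$inventory
  }

  truth <- structure(list(
    true_count = nrow(centers),
    true_area_um2 = sum(union) * px^2,
    object_masks = object_masks,
    union = union,
    defects = defects
  ), class = "GroundTruth")
  list(stack = stack, truth = truth)
}

.z_band <- function(nz) {
  if (nz == 1L) return(1L)
  lo <- floor(nz / 4) + 1L
  hi <- max(lo, min(nz, floor(3 * nz / 4)))
  lo:hi
}

.place_centers <- function(n, h, w, r_px, staining, cluster_strength) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  margin <- r_px + 2
  if (h - 2 * margin <= 1 || w - 2 * margin <= 1) {
    stop("objects cannot fit in the field: image too small for the object diameter")
  }
  runif_in <- function(m) cbind(runif(m, margin, h - margin),
                                runif(m, margin, w - margin))
  if (staining == "nuclear" && cluster_strength == 0) {
    # rejection-sample with guaranteed >= 1 px background separation
    min_d <- 2 * r_px + 3
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n) {
      tries <- tries + 1L
      if (tries > 2000L * n) stop("objects cannot fit in the field with the required separation")
      cand <- runif_in(1L)
      if (nrow(centers) == 0L ||
          min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) >= min_d) {
        centers <- rbind(centers, cand)
      }
    }
    return(centers)
  }
  if (cluster_strength == 0) return(runif_in(n))
  # Thomas-like parent-offspring clustering: one knob controls adjacency
  mean_per_parent <- 1 + 3 * cluster_strength
  n_parents <- max(1L, ceiling(n / mean_per_parent))
  parents <- runif_in(n_parents)
  assign <- sample.int(n_parents, n, replace = TRUE)
  sd_px <- 2 * r_px * (2.5 * (1 - cluster_strength) + 0.35 * cluster_strength)
  centers <- parents[assign, , drop = FALSE] +
    matrix(rnorm(2 * n, 0, sd_px), n, 2)
  centers[, 1] <- pmin(pmax(centers[, 1], margin), h - margin)
  centers[, 2] <- pmin(pmax(centers[, 2], margin), w - margin)
  centers
}

.empty_defects <- function() {
  data.frame(type = character(), id = integer(), z = integer(),
             y = integer(), x = integer())
}

#' Inject aberrant-high artifact pixels into a stack
#'
#' Adds the two discrete defect classes: isolated hot pixels (single pixels
#' raised to 98% of the dynamic range with all 8 neighbours left untouched)
#' and hot clusters (compact connected groups -- 3x3 blocks or 5-pixel
#' plus shapes -- whose equivalent diameter is strictly below the particle
#' size limit). Each artifact lands on one random z slice. The inventory
#' lists every injected coordinate, so removal efficacy is measurable.
#'
#' Placement uses the current RNG state; [simulate_scene()] seeds it from
#' the spec.
#'
#' @param stack an `ImageStack`.
#' @param spec a `SceneSpec` supplying `hot_pixel_rate`,
#'   `hot_cluster_rate` and `bit_depth`.
#' @param avoid optional logical (h, w) matrix of pixels to keep clear of
#'   (e.g. real objects and their surroundings).
#' @param size_limit_um the particle size limit clusters must stay under.
#' @return list with the modified `stack` and the `inventory` data.frame
#'   (`type`, `id`, `z`, `y`, `x`).
#' @export
inject_artifacts <- function(stack, spec, avoid = NULL, size_limit_um = 2) {
  stopifnot(inherits(stack, "ImageStack"), inherits(spec, "SceneSpec"))
  nz <- dim(stack$voxels)[1]; h <- dim(stack$voxels)[2]; w <- dim(stack$voxels)[3]
  px <- stack$pixel_size_um
  n_hot <- round(spec$hot_pixel_rate * h * w / 1000)
  n_clu <- round(spec$hot_cluster_rate)
  if (n_hot == 0 && n_clu == 0) {
    return(list(stack = stack, inventory = .empty_defects()))
  }
  cluster_shapes <- list(
    block3 = cbind(rep(0:2, 3), rep(0:2, each = 3)),
    plus5  = cbind(c(1, 0, 1, 2, 1), c(0, 1, 1, 1, 2))
  )
  for (s in cluster_shapes) {
    d_eq <- 2 * sqrt(nrow(s) * px^2 / pi)
    if (n_clu > 0 && d_eq >= size_limit_um) {
      stop("injected cluster equivalent diameter (", signif(d_eq, 3),
           " um) is not below the size limit; decrease pixel size or raise the limit")
    }
  }
  occupied <- if (is.null(avoid)) matrix(FALSE, h, w) else avoid
  hot_val <- 0.98 * (2^(if (identical(stack$bit_depth, "float")) 16 else stack$bit_depth) - 1)
  inv <- list()
  free_around <- function(ys, xs, m) {
    i0 <- max(1, min(ys) - m); i1 <- min(h, max(ys) + m)
    j0 <- max(1, min(xs) - m); j1 <- min(w, max(xs) + m)
    !any(occupied[i0:i1, j0:j1])
  }
  mark <- function(ys, xs, m) {
    i0 <- max(1, min(ys) - m); i1 <- min(h, max(ys) + m)
    j0 <- max(1, min(xs) - m); j1 <- min(w, max(xs) + m)
    occupied[i0:i1, j0:j1] <<- TRUE
  }
  place <- function(n, kind) {
    placed <- 0L; tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 2000L * n) {
        stop("cannot place ", kind, " satisfying the isolation constraint: field too crowded")
      }
      if (kind == "hot_pixel") {
        y <- sample.int(h - 2L, 1L) + 1L
        x <- sample.int(w - 2L, 1L) + 1L
        if (!free_around(y, x, 1L)) next
        z <- sample.int(nz, 1L)
        stack$voxels[z, y, x] <<- hot_val
        mark(y, x, 1L)
        placed <- placed + 1L
        inv[[length(inv) + 1L]] <<- data.frame(type = "hot_pixel", id = placed,
                                               z = z, y = y, x = x)
      } else {
        shape <- cluster_shapes[[sample.int(length(cluster_shapes), 1L)]]
        y0 <- sample.int(h - 4L, 1L) + 1L
        x0 <- sample.int(w - 4L, 1L) + 1L
        ys <- y0 + shape[, 1]; xs <- x0 + shape[, 2]
        if (max(ys) > h - 1L || max(xs) > w - 1L || !free_around(ys, xs, 1L)) next
        z <- sample.int(nz, 1L)
        for (q in seq_along(ys)) stack$voxels[z, ys[q], xs[q]] <<- hot_val
        mark(ys, xs, 1L)
        placed <- placed + 1L
        inv[[length(inv) + 1L]] <<- data.frame(type = "hot_cluster", id = placed,
                                               z = z, y = ys, x = xs)
      }
    }
  }
  place(n_hot, "hot_pixel")
  place(n_clu, "hot_cluster")
  inventory <- if (length(inv)) do.call(rbind, inv) else .empty_defects()
  list(stack = stack, inventory = inventory)
}

#' Fraction of true objects lost to cluster merging
#'
#' Labels the ground-truth union mask and compares the component count with
#' the true object count: `1 - n_components / true_count`. This is the
#' mechanism by which the count readout underestimates densely clustered
#' cytosolic staining while the area readout does not.
#'
#' @param truth a `GroundTruth`.
#' @param connectivity 4 or 8 (default).
#' @return Merged fraction in `[0, 1]` (0 when `true_count` is 0).
#' @export
merged_object_fraction <- function(truth, connectivity = 8L) {
  if (truth$true_count == 0L) return(0)
  lab <- label_components(truth$union, connectivity)
  1 - attr(lab, "n_components") / truth$true_count
}

#' Simulate a two-group experiment to disk
#'
#' Generates `n_per_group` scenes per group (e.g. two genotypes with
#' different apoptotic event rates), writes each stack as a multi-page
#' TIFF, and writes a manifest CSV plus a ground-truth CSV. Per-image seeds
#' are derived deterministically from the master seed, so the directory
#' contents are reproducible byte for byte.
#'
#' @param spec_a,spec_b `SceneSpec`s for the two groups (their `seed`
#'   fields are overridden per image).
#' @param n_per_group images per group, >= 1.
#' @param seed master seed.
#' @param out_dir output directory (created; must be empty unless
#'   `overwrite`).
#' @param groups group labels, default `c("A", "B")`.
#' @param overwrite allow writing into a non-empty directory.
#' @return The manifest data.frame, invisibly, with attributes
#'   `manifest_path` and `truth_path`.
#' @export
simulate_experiment <- function(spec_a, spec_b, n_per_group = 3L, seed = 1L,
                                out_dir, groups = c("A", "B"),
                                overwrite = FALSE) {
  stopifnot(inherits(spec_a, "SceneSpec"), inherits(spec_b, "SceneSpec"))
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 1L) stop("'n_per_group' must be >= 1")
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite) {
    stop("output directory exists and is not empty: ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(spec_a, spec_b)
  manifest <- NULL
  truth_rows <- NULL
  for (g in 1:2) {
    for (i in seq_len(n_per_group)) {
      sp <- specs[[g]]
      sp$seed <- as.integer((as.numeric(seed) * 1000 + g * 100 + i) %% 2147483647)
      id <- sprintf("%s_%02d", groups[g], i)
      sc <- simulate_scene(sp, image_id = id, group = groups[g])
      f <- paste0(id, ".tif")
      write_stack(sc$stack, file.path(out_dir, f))
      manifest <- rbind(manifest, data.frame(
        file = f, series = 1L, channel = sc$stack$channel, image_id = id,
        group = groups[g], pixel_size_um = sp$pixel_size_um))
      truth_rows <- rbind(truth_rows, data.frame(
        image_id = id, group = groups[g], true_count = sc$truth$true_count,
        true_area_um2 = sc$truth$true_area_um2,
        n_hot_pixels = sum(sc$truth$defects$type == "hot_pixel"),
        n_hot_cluster_px = sum(sc$truth$defects$type == "hot_cluster")))
    }
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  truth_path <- file.path(out_dir, "ground_truth.csv")
  write_manifest(manifest, manifest_path)
  write.csv(truth_rows, truth_path, row.names = FALSE)
  attr(manifest, "manifest_path") <- manifest_path
  attr(manifest, "truth_path") <- truth_path
  invisible(manifest)
}
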