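small_nuclear <- function(seed, n_cells = 12, noise_sd = 0, ...) {
  scene_spec(shape = c(4, 160, 160), staining = "nuclear", n_cells = n_cells,
             noise_sd = noise_sd, seed = seed, ...)
}

test_that("empty scenes and determinism contracts hold", {
  sp0 <- scene_spec(shape = c(2, 64, 64), staining = "nuclear", n_cells = 0,
                    noise_sd = 0, seed = 3)
  sc0 <- simulate_scene(sp0)
  expect_equal(sc0$truth$true_count, 0L)
  expect_equal(sc0$truth$true_area_um2, 0)
  expect_true(all(sc0$stack$voxels == sp0$background_level))

  sp <- small_nuclear(5, noise_sd = 25, hot_pixel_rate = 0.5, hot_cluster_rate = 2)
  a <- simulate_scene(sp); b <- simulate_scene(sp)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$defects, b$truth$defects)
})

test_that("ground-truth area is the union of the object masks", {
  sp <- scene_spec(shape = c(2, 128, 128), staining = "cytosolic", event_rate = 6,
                   cluster_strength = 0.8, noise_sd = 0, seed = 9)
  sc <- simulate_scene(sp)
  u <- matrix(FALSE, 128, 128)
  for (ix in sc$truth$object_masks) u[ix] <- TRUE
  expect_equal(sc$truth$true_area_um2, sum(u) * sp$pixel_size_um^2)
  expect_identical(u, sc$truth$union)
  expect_equal(sc$truth$true_count, length(sc$truth$object_masks))
})

test_that("noiseless separated nuclear scenes are recovered exactly by the pipeline", {
  for (seed in 1:4) {
    sp <- small_nuclear(seed)
    sc <- simulate_scene(sp)
    img <- z_project(median_filter(sc$stack, 1), "max")
    q <- quantify_image(img, sp$background_level + sp$signal_level / 2,
                        min_diameter_um = 2)
    expect_equal(q$count, sc$truth$true_count)
    expect_lt(abs(q$total_area_um2 - sc$truth$true_area_um2) / sc$truth$true_area_um2,
              0.05)
    # any threshold strictly between background and signal recovers the count
    for (T in sp$background_level + sp$signal_level * c(0.25, 0.75)) {
      expect_equal(quantify_image(img, T, min_diameter_um = 2)$count,
                   sc$truth$true_count)
    }
  }
})

test_that("injected artifacts respect isolation, size and inventory contracts", {
  sp <- small_nuclear(31, noise_sd = 20, hot_pixel_rate = 1, hot_cluster_rate = 3)
  sc <- simulate_scene(sp)
  inv <- sc$truth$defects
  n_hot <- round(sp$hot_pixel_rate * 160 * 160 / 1000)
  expect_equal(sum(inv$type == "hot_pixel"), n_hot)
  expect_equal(length(unique(inv$id[inv$type == "hot_cluster"])), 3L)

  # isolated hot pixels: all 8 neighbours untouched (still at background scale)
  hp <- inv[inv$type == "hot_pixel", ]
  for (k in seq_len(nrow(hp))) {
    nb <- sc$stack$voxels[hp$z[k], hp$y[k] + (-1:1), hp$x[k] + (-1:1)]
    expect_equal(sum(nb > 0.9 * 65535), 1L) # only the pixel itself
  }

  # injected clusters sit strictly below the 2 um size limit
  for (cid in unique(inv$id[inv$type == "hot_cluster"])) {
    n_px <- sum(inv$type == "hot_cluster" & inv$id == cid)
    expect_lt(2 * sqrt(n_px * sp$pixel_size_um^2 / pi), 2)
  }

  # zero rates: unchanged stack, empty inventory
  sp0 <- small_nuclear(31, noise_sd = 20)
  inj <- inject_artifacts(simulate_scene(sp0)$stack, sp0)
  expect_equal(nrow(inj$inventory), 0L)
  expect_identical(inj$stack$voxels, simulate_scene(sp0)$stack$voxels)
})

test_that("median filtering erases injected isolated hot pixels below the scene threshold", {
  for (seed in c(2, 13)) {
    sp <- small_nuclear(seed, noise_sd = 25, hot_pixel_rate = 2)
    sc <- simulate_scene(sp)
    T <- sp$background_level + sp$signal_level / 2
    hp <- sc$truth$defects[sc$truth$defects$type == "hot_pixel", ]
    med <- z_project(median_filter(sc$stack, 1), "max")
    mn <- z_project(mean_filter(sc$stack, 1), "max")
    expect_equal(sum(med$pixels[cbind(hp$y, hp$x)] > T), 0L)
    expect_gt(sum(mn$pixels[cbind(hp$y, hp$x)] > T), 0L) # mean spreads, not erases
  }
})

test_that("cytosolic merging grows with event density", {
  rates <- c(1, 2, 4, 8)
  mf <- sapply(rates, function(r) {
    mean(sapply(1:5, function(s) {
      sp <- scene_spec(shape = c(1, 192, 192), staining = "cytosolic",
                       event_rate = r, cluster_strength = 0.7, noise_sd = 0,
                       seed = 500 + 13 * s + round(10 * r))
      merged_object_fraction(simulate_scene(sp)$truth)
    }))
  })
  expect_gt(cor(rates, mf, method = "spearman"), 0)
  # count through the union can only undercount
  sp <- scene_spec(shape = c(1, 192, 192), staining = "cytosolic", event_rate = 6,
                   cluster_strength = 0.9, noise_sd = 0, seed = 77)
  sc <- simulate_scene(sp)
  lab <- label_components(sc$truth$union)
  expect_lte(attr(lab, "n_components"), sc$truth$true_count)
})

test_that("simulate_experiment writes a reproducible directory of stacks and tables", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  spA <- scene_spec(shape = c(2, 96, 96), staining = "nuclear", n_cells = 6,
                    noise_sd = 15)
  spB <- scene_spec(shape = c(2, 96, 96), staining = "nuclear", n_cells = 3,
                    noise_sd = 15)
  m1 <- simulate_experiment(spA, spB, n_per_group = 3, seed = 4, out_dir = td1)
  expect_equal(nrow(m1), 6L)
  expect_equal(sort(unique(m1$group)), c("A", "B"))
  expect_equal(sum(grepl("\\.tif$", dir(td1))), 6L)
  truth <- read.csv(attr(m1, "truth_path"))
  expect_equal(nrow(truth), 6L)

  m2 <- simulate_experiment(spA, spB, n_per_group = 3, seed = 4, out_dir = td2)
  for (f in grep("\\.tif$", dir(td1), value = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(td1, f))),
                     unname(tools::md5sum(file.path(td2, f))), info = f)
  }
  expect_error(simulate_experiment(spA, spB, n_per_group = 3, seed = 4,
                                   out_dir = td1), "not empty")
})
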