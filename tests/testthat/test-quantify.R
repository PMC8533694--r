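test_that("ROI rasterization matches a point-in-polygon oracle at every pixel centre", {
  # full-frame rectangle -> full mask
  full <- roi_polygon(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_true(all(rasterize_roi(full, c(10, 10))$pixels))

  expect_error(roi_polygon(rbind(c(0, 0), c(5, 5))), "3")
  expect_error(roi_polygon(rbind(c(0, 0), c(5, 5), c(10, 10))), "zero area")

  tri <- roi_polygon(rbind(c(0.3, 0.2), c(9.1, 2.4), c(4.2, 9.6)))
  m <- rasterize_roi(tri, c(10, 10))$pixels
  for (r in 1:10) for (c in 1:10) {
    expect_identical(m[r, c],
                     oracle_point_in_polygon(c - 0.5, r - 0.5, tri$vertices),
                     info = sprintf("pixel (%d,%d)", r, c))
  }
})

test_that("connectivity semantics: diagonal pixels touch under 8 but not 4", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(attr(label_components(m, 8), "n_components"), 1L)
  expect_equal(attr(label_components(m, 4), "n_components"), 2L)
  expect_equal(attr(label_components(matrix(FALSE, 5, 5)), "n_components"), 0L)
})

test_that("component counts equal a BFS flood-fill oracle on random masks", {
  set.seed(14)
  for (i in 1:25) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    conn <- sample(c(4L, 8L), 1)
    expect_equal(attr(label_components(m, conn), "n_components"),
                 oracle_component_count(m, conn))
  }
})

test_that("particle measurements follow the stated conventions", {
  # 2x2 square, pixel 0.5 um
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE
  p <- measure_particles(label_components(m), 0.5)
  expect_equal(p$area_px, 4L)
  expect_equal(p$area_um2, 1.0)
  expect_equal(c(p$centroid_x, p$centroid_y), c(2, 2)) # centre of the square
  expect_equal(c(p$bbox_x0, p$bbox_y0, p$bbox_x1, p$bbox_y1), c(1, 1, 3, 3))
  expect_equal(p$equiv_diameter_um, 2 * sqrt(1 / pi))

  # single pixel
  s <- matrix(FALSE, 3, 3); s[2, 2] <- TRUE
  ps <- measure_particles(label_components(s), 0.5)
  expect_equal(ps$area_px, 1L)
  expect_equal(ps$equiv_diameter_um, 2 * sqrt(0.25 / pi))

  # rasterized disc of radius 20 px: near-circular, estimator bias documented
  n <- 51; d <- sqrt(outer((1:n - 26)^2, (1:n - 26)^2, `+`))
  pd <- measure_particles(label_components(d <= 20), 1)
  expect_gte(pd$circularity, 0.9)
  expect_lte(pd$circularity, 1.0)
  expect_equal(pd$area_px, sum(d <= 20))
})

test_that("area invariants hold for every measured particle", {
  set.seed(21)
  m <- matrix(runif(40 * 40) < 0.3, 40, 40)
  p <- measure_particles(label_components(m), 0.7)
  expect_equal(p$area_um2, p$area_px * 0.7^2)
  expect_equal(p$equiv_diameter_um, 2 * sqrt(p$area_um2 / pi))
  expect_true(all(p$circularity >= 0 & p$circularity <= 1))
  expect_equal(sum(p$area_px), sum(m))
})

test_that("size filtering is strict on the minimum equivalent diameter", {
  # pixel 0.5 um: 12 px -> 3.0 um2 -> d ~ 1.954 um (removed at 2 um);
  # 13 px -> 3.25 um2 -> d ~ 2.034 um (kept)
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:5] <- TRUE            # 12-pixel block
  m[10:12, 10:13] <- TRUE; m[10, 14] <- TRUE # 13-pixel object
  p <- measure_particles(label_components(m), 0.5)
  kept <- filter_particles(p, min_diameter_um = 2)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$area_px, 13L)

  expect_identical(filter_particles(p), p) # no limits: identity
  # increasing the minimum never increases survivors
  counts <- sapply(c(0, 1, 2, 3), function(d) nrow(filter_particles(p, min_diameter_um = d)))
  expect_true(all(diff(counts) <= 0))
  expect_error(filter_particles(p, min_diameter_um = 3, max_diameter_um = 2), "min")

  # area-mode filtering provided as the alternative convention
  expect_equal(nrow(filter_particles(p, min_area_um2 = 3.0)), 1L)
  expect_equal(nrow(filter_particles(p, min_area_um2 = 3.25)), 0L)
})

test_that("quantify_image counts separated discs and merges touching ones", {
  img <- matrix(0, 40, 40)
  d1 <- sqrt(outer((1:40 - 12)^2, (1:40 - 12)^2, `+`))
  d2 <- sqrt(outer((1:40 - 12)^2, (1:40 - 30)^2, `+`))
  img[d1 <= 6 | d2 <= 6] <- 200
  q2 <- quantify_image(ci(img, px = 1), 100, min_diameter_um = 2)
  expect_equal(q2$count, 2L)
  a_separate <- q2$total_area_um2

  # same discs overlapping: one object, union area below the sum
  d2b <- sqrt(outer((1:40 - 12)^2, (1:40 - 20)^2, `+`))
  img2 <- matrix(0, 40, 40); img2[d1 <= 6 | d2b <= 6] <- 200
  q1 <- quantify_image(ci(img2, px = 1), 100, min_diameter_um = 2)
  expect_equal(q1$count, 1L)
  expect_lt(q1$total_area_um2, a_separate)
})

test_that("foreground area is conserved between kept and filtered-out particles", {
  set.seed(33)
  img <- matrix(runif(50 * 50, 0, 255), 50, 50)
  roi <- roi_polygon(rbind(c(5, 5), c(45, 8), c(40, 45), c(8, 40)))
  q <- quantify_image(ci(img, px = 0.5), 180, roi = roi, min_diameter_um = 1.2)
  mask <- binarize(ci(img, px = 0.5), 180)$pixels & rasterize_roi(roi, c(50, 50))$pixels
  expect_equal(sum(q$particles$area_um2) + sum(q$removed$area_um2),
               sum(mask) * 0.25)
  expect_equal(q$count, nrow(q$particles))
  expect_equal(q$total_area_um2, sum(q$particles$area_um2))
})

test_that("ROI restriction equals quantifying the pre-masked image", {
  set.seed(44)
  img <- matrix(runif(30 * 30, 0, 255), 30, 30)
  roi <- roi_polygon(rbind(c(3, 3), c(27, 5), c(25, 27), c(5, 25)))
  q_roi <- quantify_image(ci(img, px = 1), 150, roi = roi)
  masked <- img
  masked[!rasterize_roi(roi, c(30, 30))$pixels] <- 0
  q_pre <- quantify_image(ci(masked, px = 1), 150)
  expect_equal(q_roi$count, q_pre$count)
  expect_equal(q_roi$total_area_um2, q_pre$total_area_um2)
})
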