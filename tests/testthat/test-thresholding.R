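test_that("histogram bins the (masked) intensity range as specified", {
  img <- ci(matrix(c(0, 0, 255, 255), 2, 2, byrow = TRUE), px = 1)
  h <- compute_histogram(img, 256)
  expect_equal(h$counts[1], 2)
  expect_equal(h$counts[256], 2)
  expect_equal(h$total, 4)
  expect_equal(sum(h$counts), h$total)
  expect_true(all(diff(h$bin_edges) > 0))

  mask <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2, byrow = TRUE), 1)
  hm <- compute_histogram(img, 256, mask)
  expect_equal(hm$total, 2)
  expect_equal(hm$counts[1], 2)
  expect_true(isTRUE(hm$degenerate)) # masked region is constant

  # 16-bit style range: extremes land in first/last equal-width bins
  img16 <- ci(matrix(c(0, 4095, 2000, 2000), 2, 2), px = 1)
  h16 <- compute_histogram(img16, 256)
  w <- 4095 / 256
  expect_equal(h16$bin_edges[2] - h16$bin_edges[1], w)
  expect_equal(h16$counts[1], 1)
  expect_equal(h16$counts[256], 1)
  expect_equal(h16$counts[floor(2000 / w) + 1], 2)

  expect_error(compute_histogram(img, 256, binary_mask(matrix(FALSE, 2, 2), 1)), "mask")
  expect_error(compute_histogram(img, 1), "n_bins")
})

test_that("the four auto-threshold algorithms match their oracles on the two-spike case", {
  cnt <- integer(256); cnt[51] <- 100; cnt[201] <- 100
  h <- structure(list(bin_edges = as.numeric(0:256), counts = cnt, total = 200L,
                      source_range = c(0, 256), degenerate = FALSE),
                 class = "IntensityHistogram")
  expect_equal(auto_threshold(h, "otsu"), 50)     # lowest of the tied optima
  expect_equal(auto_threshold(h, "isodata"), 125) # fixed point of (50+200)/2
  expect_equal(auto_threshold(h, "moments"), 50)  # p0 = 0.5 reached at the first spike
  expect_equal(auto_threshold(h, "intermode"), 125)
  expect_equal(oracle_otsu_scan(h), 50)
  expect_equal(oracle_isodata(h), 125)
  expect_equal(oracle_moments(h), 50)

  # degenerate: single occupied bin
  cnt1 <- integer(256); cnt1[51] <- 100
  h1 <- structure(list(bin_edges = as.numeric(0:256), counts = cnt1, total = 100L,
                       source_range = c(0, 256), degenerate = FALSE),
                  class = "IntensityHistogram")
  for (meth in c("otsu", "moments", "isodata", "intermode")) {
    expect_error(auto_threshold(h1, meth), "degenerate")
  }
})

test_that("Otsu equals the exhaustive between-class-variance scan on random histograms", {
  set.seed(123)
  for (i in 1:60) {
    h <- random_histogram()
    expect_identical(auto_threshold(h, "otsu"), oracle_otsu_scan(h))
  }
})

test_that("IsoData and Moments match independent oracles on random histograms", {
  set.seed(321)
  for (i in 1:40) {
    h <- random_histogram()
    expect_equal(auto_threshold(h, "isodata"), oracle_isodata(h))
    expect_equal(auto_threshold(h, "moments"), oracle_moments(h))
  }
})

test_that("auto-thresholds are invariant under uniform scaling of the counts", {
  set.seed(9)
  for (i in 1:10) {
    h <- random_histogram()
    h2 <- h; h2$counts <- h$counts * 5L; h2$total <- h$total * 5L
    for (meth in c("otsu", "moments", "isodata")) {
      expect_equal(auto_threshold(h2, meth), auto_threshold(h, meth), info = meth)
    }
    # intermode on a reliably bimodal mixture
    v <- pmin(pmax(c(rnorm(2000, 60, 8), rnorm(2000, 190, 8)), 0), 255)
    hb <- compute_histogram(ci(matrix(v, 40, 100), px = 1), 256)
    hb2 <- hb; hb2$counts <- hb$counts * 3L; hb2$total <- hb$total * 3L
    expect_equal(auto_threshold(hb2, "intermode"), auto_threshold(hb, "intermode"))
  }
})

test_that("all four methods split well-separated Gaussian mixtures between the means", {
  set.seed(99)
  v <- c(rnorm(4000, 80, 10), rnorm(4000, 200, 10))
  v <- pmin(pmax(v, 0), 255)
  h <- compute_histogram(ci(matrix(v, 80, 100), px = 1), 256)
  for (meth in c("otsu", "moments", "isodata", "intermode")) {
    T <- auto_threshold(h, meth)
    expect_gt(T, 80); expect_lt(T, 200)
  }
})

test_that("consensus threshold is the median of per-group medians", {
  rec <- data.frame(group = c("A", "A", "A", "B"),
                    value = c(100, 110, 120, 200), channel = "c1")
  expect_equal(consensus_threshold(rec), 155) # medians 110 and 200
  expect_equal(consensus_threshold(rec[1:3, ]), 110) # single group

  # duplicating every record within one group leaves the result unchanged
  rec2 <- rbind(rec, rec[rec$group == "A", ])
  expect_equal(consensus_threshold(rec2), 155)

  # group relabeling leaves the result unchanged
  rec3 <- rec; rec3$group <- c("X", "X", "X", "Y")
  expect_equal(consensus_threshold(rec3), 155)

  # resampling an odd-length group around its own median
  rec4 <- rec; rec4$value[c(1, 3)] <- c(105, 118)
  expect_equal(consensus_threshold(rec4), 155)

  expect_error(consensus_threshold(data.frame(group = character(), value = numeric())))
  expect_error(consensus_threshold(data.frame(group = c("A", "B"), value = 1:2,
                                              channel = c("c1", "c2"))), "channel")
})

test_that("binarize uses the strict-above convention and is antitone in T", {
  img <- ci(matrix(c(99, 100, 101, 50), 2, 2), px = 1)
  m <- binarize(img, 100)
  expect_identical(as.vector(m$pixels), c(FALSE, FALSE, TRUE, FALSE))
  expect_false(any(binarize(img, 101)$pixels))  # T >= max: empty
  expect_true(all(binarize(img, 49)$pixels))    # T < min: full
  expect_true(any(binarize(img, 100, mode = ">=")$pixels != m$pixels))

  set.seed(5)
  r <- ci(matrix(runif(100, 0, 255), 10, 10), px = 1)
  t1 <- sort(runif(2, 0, 255))
  m1 <- binarize(r, t1[1])$pixels; m2 <- binarize(r, t1[2])$pixels
  expect_true(all(m1[m2])) # mask(T2) subset of mask(T1)
})
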