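# Independent brute-force oracles used to pin down the pinned semantics of
# the fast implementations. These deliberately share no code with R/.

# replicate-padded sliding-window filter, direct loops
oracle_box_filter <- function(m, r, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else median
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- pmin(pmax(i + (-r:r), 1), nr)
      jj <- pmin(pmax(j + (-r:r), 1), nc)
      out[i, j] <- f(as.numeric(m[ii, jj]))
    }
  }
  out
}

# BFS flood-fill component count
oracle_component_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  }
  n <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        q <- p + nbr[k, ]
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  n
}

# exhaustive between-class-variance scan over all candidate split bins,
# lowest-tie rule; returns the lower edge of the winning bin
oracle_otsu_scan <- function(hist) {
  p <- hist$counts / hist$total
  v <- hist$bin_edges[-length(hist$bin_edges)]
  n <- length(p)
  best_bcv <- -Inf; best_t <- NA
  for (t in seq_len(n - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:t] * v[1:t]) / w0
    mu1 <- sum(p[(t + 1):n] * v[(t + 1):n]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best_bcv) { best_bcv <- bcv; best_t <- t }
  }
  v[best_t]
}

# class-mean fixed-point iteration oracle
oracle_isodata <- function(hist, tol = 1e-9) {
  v <- hist$bin_edges[-length(hist$bin_edges)]
  p <- hist$counts
  T <- sum(p * v) / sum(p)
  repeat {
    lo <- p > 0 & v <= T; hi <- p > 0 & v > T
    if (!any(lo) || !any(hi)) break
    Tn <- (weighted.mean(v[lo], p[lo]) + weighted.mean(v[hi], p[hi])) / 2
    if (abs(Tn - T) < tol) { T <- Tn; break }
    T <- Tn
  }
  v[min(max(findInterval(T, hist$bin_edges, rightmost.closed = TRUE), 1), length(v))]
}

# Tsai moment-preserving selection, written out via polyroot
oracle_moments <- function(hist) {
  p <- hist$counts / hist$total
  z <- seq_along(p) - 1
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  # z0, z1 solve z^2 + c1 z + c0 = 0 with the Tsai coefficients
  cd <- m2 - m1^2
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  roots <- sort(Re(polyroot(c(c0, c1, 1))))
  p0 <- (roots[2] - m1) / (roots[2] - roots[1])
  bin <- which(cumsum(p) >= p0 - 1e-12)[1]
  if (is.na(bin)) bin <- length(p)
  hist$bin_edges[bin]
}

# even-odd point-in-polygon by counting parametrized edge crossings of a
# rightward ray, with explicit boundary inclusion
oracle_point_in_polygon <- function(x, y, verts) {
  n <- nrow(verts)
  crossings <- 0L
  for (i in seq_len(n)) {
    a <- verts[i, ]; b <- verts[if (i == n) 1 else i + 1, ]
    # boundary?
    ab <- b - a; ap <- c(x, y) - a
    if (abs(ab[1] * ap[2] - ab[2] * ap[1]) < 1e-9 &&
        sum(ap * ab) >= 0 && sum(ap * ab) <= sum(ab * ab)) return(TRUE)
    if ((a[2] > y) != (b[2] > y)) {
      t <- (y - a[2]) / (b[2] - a[2])
      if (a[1] + t * (b[1] - a[1]) > x) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# exact two-sided rank-sum p by full enumeration (small n, no ties)
oracle_ranksum_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  all_u <- combn(na + nb, na, u_of)
  mu <- na * nb / 2
  # two-sided by doubling the smaller tail (capped at 1)
  p <- 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs))
  min(1, p)
}

# exact rank-sum tail by dynamic programming over rank sums (no ties):
# number of na-subsets of 1..N with each possible rank sum
oracle_ranksum_dp <- function(na, nb, u_obs) {
  N <- na + nb
  maxs <- sum((N - na + 1):N)
  # f[k+1, s+1] = number of k-subsets with rank sum s
  f <- matrix(0, na + 1, maxs + 1)
  f[1, 1] <- 1
  for (r in seq_len(N)) {
    for (k in min(na, r):1) {
      nz <- which(f[k, ] > 0)
      f[k + 1, nz + r] <- f[k + 1, nz + r] + f[k, nz]
    }
  }
  counts <- f[na + 1, ]
  s <- which(counts > 0) - 1
  u <- s - na * (na + 1) / 2
  tot <- sum(counts[s + 1])
  p_le <- sum(counts[s + 1][u <= u_obs]) / tot
  p_ge <- sum(counts[s + 1][u >= u_obs]) / tot
  min(1, 2 * min(p_le, p_ge))
}

# closed-form OLS by the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  p <- 2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r_squared = r2, p = p)
}

# random non-degenerate 256-bin histogram
random_histogram <- function(n_bins = 256, max_range = 255) {
  counts <- rpois(n_bins, lambda = sample(c(0.2, 2, 20), n_bins, replace = TRUE,
                                          prob = c(0.6, 0.3, 0.1)))
  if (sum(counts > 0) < 2) counts[c(10, 200)] <- counts[c(10, 200)] + 1
  structure(list(bin_edges = seq(0, max_range, length.out = n_bins + 1),
                 counts = counts, total = sum(counts),
                 source_range = c(0, max_range), degenerate = FALSE),
            class = "IntensityHistogram")
}

# small calibrated test image from a matrix
ci <- function(m, px = 0.5, id = "test") {
  calibrated_image(m, pixel_size_um = px, image_id = id)
}
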