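#' Two-sample rank-sum (Mann-Whitney/Wilcoxon) test
#'
#' Two-sided comparison of two independent groups of per-image readouts.
#' The exact null distribution is enumerated when both groups have at most
#' 10 observations and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used (both via
#' [stats::wilcox.test()]).
#'
#' @param a,b numeric vectors of readout values, both non-empty.
#' @return list with `U` (the Mann-Whitney statistic of `a` vs `b`), `p`
#'   (two-sided), and `method` (`"exact"` or `"approximate"`).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 10L && length(b) <= 10L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "approximate")
}

#' Summarize one group's readout values
#'
#' @param values non-empty numeric vector (per-image counts or areas).
#' @param group optional group label to attach.
#' @return A one-row data.frame of class `GroupResult`: `group`, `n`,
#'   `mean`, `sd` (n-1 denominator; 0 with `sd_defined = FALSE` for a
#'   single value), `min`, `max`, `median`.
#' @export
summarize_group <- function(values, group = NA_character_) {
  if (length(values) == 0L || anyNA(values)) stop("values must be non-empty and non-missing")
  s <- if (length(values) > 1L) sd(values) else 0
  out <- data.frame(group = group, n = length(values), mean = mean(values),
                    sd = s, min = min(values), max = max(values),
                    median = median(values),
                    sd_defined = length(values) > 1L)
  class(out) <- c("GroupResult", "data.frame")
  out
}

#' Concordance between two threshold series
#'
#' Ordinary least squares of `y` on `x` (e.g. two experimenters' manual
#' thresholds for the same images): used to ask whether two raters are
#' systematically consistent. Returns the slope, intercept, squared Pearson
#' correlation and the two-sided p-value of the slope t-test.
#'
#' @param x,y paired numeric vectors, equal length >= 3, `x` non-constant.
#' @return list with `slope`, `intercept`, `r_squared`, `p`.
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (sd(x) == 0) stop("x is constant: concordance slope undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p = unname(sm$coefficients[2, 4]))
}

#' Histogram figure of threshold values
#'
#' Writes a PNG bar chart of the distribution of determined threshold
#' values (as the workflow recapitulates at the end of the threshold
#' phase), plus a CSV of the bin counts so the figure's content is
#' testable. Identical values all land in one bin.
#'
#' @param records non-empty data.frame with a `value` column (a threshold
#'   table).
#' @param path output PNG path; the CSV is written next to it with the
#'   extension swapped to `.csv`.
#' @param n_bins number of bins (default 16).
#' @return Named paths of the two files, invisibly.
#' @export
threshold_histogram_figure <- function(records, path, n_bins = 16L) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L || !"value" %in% names(records)) {
    stop("records must be non-empty and carry a 'value' column")
  }
  v <- records$value
  lo <- min(v); hi <- max(v)
  if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5; n_bins <- 1L }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  csv_path <- sub("\\.[Pp][Nn][Gg]$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  write.csv(data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       count = counts),
            csv_path, row.names = FALSE)
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::barplot(counts, names.arg = signif((edges[-length(edges)] + edges[-1]) / 2, 4),
                    xlab = "threshold value", ylab = "images",
                    main = "Distribution of determined thresholds",
                    col = "grey70", border = "grey30", las = 2)
  invisible(c(png = path, csv = csv_path))
}
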