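#' Pipeline configuration
#'
#' Collects every parameter of the two-phase workflow. Threshold modes:
#' \describe{
#'   \item{`"algorithm:<name>"`}{Part 1 computes a threshold per image with
#'     the named histogram algorithm (`otsu`, `moments`, `isodata`,
#'     `intermode`).}
#'   \item{`"manual_table"`}{Part 1 exports preview images and a template
#'     CSV; an operator fills in the `value` column off-line; Part 2
#'     applies one threshold per image.}
#'   \item{`"consensus_from_table"`}{Part 2 reduces the (manual) table to a
#'     single median-of-medians threshold -- computed from the first
#'     `consensus_fraction` of images, ordered by `image_id` -- and applies
#'     it uniformly.}
#' }
#'
#' @param manifest path to the manifest CSV (see [read_manifest()]).
#' @param out_dir output directory for all phase products.
#' @param channel optional channel to restrict the manifest to.
#' @param filter_method `"median"` (default), `"mean"` or `"none"`.
#' @param filter_radius filter radius in pixels (default 1).
#' @param projection `"max"` (default), `"average"` or `"sum"`.
#' @param threshold_mode see above.
#' @param threshold_table optional path to an existing threshold table
#'   (defaults to the one Part 1 writes into `out_dir`).
#' @param consensus_fraction fraction (0, 1] of images (by sorted
#'   `image_id`) used for the consensus threshold; default 1.
#' @param roi_dir optional directory of per-image ROI vertex files named
#'   `<image_id>.csv`; when set, every image must have one.
#' @param min_diameter_um,max_diameter_um,circ_min,circ_max particle
#'   filters (protocol default: objects strictly larger than 2 um
#'   equivalent diameter).
#' @param connectivity 4 or 8.
#' @param n_bins histogram bins for algorithm thresholds.
#' @param seed recorded in the run log (the processing itself is
#'   deterministic).
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(manifest, out_dir, channel = NULL,
                            filter_method = c("median", "mean", "none"),
                            filter_radius = 1L,
                            projection = c("max", "average", "sum"),
                            threshold_mode = "algorithm:otsu",
                            threshold_table = NULL, consensus_fraction = 1,
                            roi_dir = NULL, min_diameter_um = 2,
                            max_diameter_um = NULL, circ_min = 0,
                            circ_max = 1, connectivity = 8L, n_bins = 256L,
                            seed = 1L) {
  filter_method <- match.arg(filter_method)
  projection <- match.arg(projection)
  if (!(identical(threshold_mode, "manual_table") ||
        identical(threshold_mode, "consensus_from_table") ||
        grepl("^algorithm:(otsu|moments|isodata|intermode)$", threshold_mode))) {
    stop("unknown threshold_mode: ", threshold_mode)
  }
  if (consensus_fraction <= 0 || consensus_fraction > 1) {
    stop("'consensus_fraction' must be in (0, 1]")
  }
  structure(list(manifest = manifest, out_dir = out_dir, channel = channel,
                 filter_method = filter_method,
                 filter_radius = as.integer(filter_radius),
                 projection = projection, threshold_mode = threshold_mode,
                 threshold_table = threshold_table,
                 consensus_fraction = consensus_fraction, roi_dir = roi_dir,
                 min_diameter_um = min_diameter_um,
                 max_diameter_um = max_diameter_um,
                 circ_min = circ_min, circ_max = circ_max,
                 connectivity = as.integer(connectivity),
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative `manifest`,
#' `threshold_table` and `roi_dir` paths are resolved against the config
#' file's directory.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("manifest", "threshold_table", "roi_dir", "out_dir")) {
    if (!is.null(y[[k]]) && !grepl("^(/|[A-Za-z]:)", y[[k]])) {
      y[[k]] <- file.path(base, y[[k]])
    }
  }
  do.call(pipeline_config, y)
}

# read + filter + project one manifest row
.process_image <- function(row, config) {
  f <- row$file
  if (!file.exists(f)) {
    f2 <- file.path(dirname(config$manifest), row$file)
    if (file.exists(f2)) f <- f2 else stop("image file not found: ", row$file)
  }
  cal <- if ("pixel_size_um" %in% names(row) && is.finite(row$pixel_size_um)) {
    row$pixel_size_um
  } else NULL
  stack <- read_stack(f, series = row$series, channel = row$channel,
                      calibration = cal, group = row$group,
                      image_id = row$image_id)
  if (config$filter_method == "median") {
    stack <- median_filter(stack, config$filter_radius)
  } else if (config$filter_method == "mean") {
    stack <- mean_filter(stack, config$filter_radius)
  }
  z_project(stack, config$projection)
}

.config_params <- function(config, phase) {
  list(phase = phase, manifest = config$manifest,
       channel = config$channel %||% "all",
       filter_method = config$filter_method,
       filter_radius = config$filter_radius,
       projection = config$projection,
       threshold_mode = config$threshold_mode,
       consensus_fraction = config$consensus_fraction,
       roi_dir = config$roi_dir %||% "none",
       min_diameter_um = config$min_diameter_um %||% "none",
       max_diameter_um = config$max_diameter_um %||% "none",
       circ_min = config$circ_min, circ_max = config$circ_max,
       connectivity = config$connectivity, n_bins = config$n_bins,
       seed = config$seed)
}

.manifest_rows <- function(config) {
  m <- read_manifest(config$manifest)
  if (!is.null(config$channel)) m <- m[m$channel == config$channel, , drop = FALSE]
  if (nrow(m) == 0L) stop("manifest has no rows for the requested channel")
  m[order(m$image_id), , drop = FALSE]
}

#' Part 1: process images and determine thresholds
#'
#' Every manifest image is filtered and z-projected. In algorithm mode the
#' configured histogram algorithm produces one threshold per image, written
#' to `thresholds.csv` together with a distribution histogram (PNG + CSV).
#' In manual/consensus mode, 16-bit preview PNGs are exported and a
#' template `thresholds_template.csv` with empty value cells is emitted for
#' off-line operator completion. All parameters go to the run log.
#'
#' @param config a `PipelineConfig`.
#' @return Named list of output paths, invisibly.
#' @export
run_threshold_phase <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  m <- .manifest_rows(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(run_log = file.path(config$out_dir, "run_log_part1.txt"))
  algo <- sub("^algorithm:", "", config$threshold_mode)
  if (grepl("^algorithm:", config$threshold_mode)) {
    recs <- NULL
    for (k in seq_len(nrow(m))) {
      img <- .process_image(m[k, ], config)
      Tk <- auto_threshold(compute_histogram(img, config$n_bins), algo)
      recs <- rbind(recs, data.frame(image_id = img$image_id,
                                     channel = img$channel, group = img$group,
                                     method = algo, value = Tk,
                                     operator_id = NA_character_))
    }
    out$thresholds <- file.path(config$out_dir, "thresholds.csv")
    write_threshold_table(recs, out$thresholds)
    fig <- threshold_histogram_figure(recs, file.path(config$out_dir, "thresholds_hist.png"))
    out$histogram_png <- unname(fig["png"]); out$histogram_csv <- unname(fig["csv"])
  } else {
    recs <- NULL
    previews <- character()
    for (k in seq_len(nrow(m))) {
      img <- .process_image(m[k, ], config)
      p <- file.path(config$out_dir, paste0("preview_", img$image_id, ".png"))
      rng <- range(img$pixels)
      scaled <- if (diff(rng) > 0) (img$pixels - rng[1]) / diff(rng) else img$pixels * 0
      png::writePNG(scaled, p)
      previews <- c(previews, p)
      recs <- rbind(recs, data.frame(image_id = img$image_id,
                                     channel = img$channel, group = img$group,
                                     method = "manual", value = NA_real_,
                                     operator_id = NA_character_))
    }
    out$template <- file.path(config$out_dir, "thresholds_template.csv")
    write.csv(recs, out$template, row.names = FALSE)
    out$previews <- previews
  }
  write_run_record(run_record(.config_params(config, "threshold")), out$run_log)
  invisible(out)
}

# resolve the per-image (or unique) thresholds for Part 2
.resolve_thresholds <- function(config, thresholds, manifest_rows) {
  if (is.null(thresholds)) {
    thresholds <- config$threshold_table %||% file.path(config$out_dir, "thresholds.csv")
  }
  if (is.character(thresholds)) thresholds <- read_threshold_table(thresholds)
  thresholds <- as.data.frame(thresholds)
  if (identical(config$threshold_mode, "consensus_from_table")) {
    tt <- thresholds[order(thresholds$image_id), , drop = FALSE]
    n_use <- max(1L, ceiling(config$consensus_fraction * nrow(tt)))
    Tuniq <- consensus_threshold(tt[seq_len(n_use), , drop = FALSE])
    return(list(unique_value = Tuniq,
                lookup = function(id) Tuniq))
  }
  lookup <- function(id) {
    i <- match(id, thresholds$image_id)
    if (is.na(i) || is.na(thresholds$value[i])) {
      stop("no threshold available for image '", id, "'")
    }
    thresholds$value[i]
  }
  list(unique_value = NULL, lookup = lookup)
}

#' Part 2: apply thresholds, select zones, quantify, summarize
#'
#' Consumes only files (raw images, the threshold table, optional ROI
#' files): images are re-processed exactly as in Part 1, the resolved
#' threshold is applied, quantification is restricted to the per-image ROI
#' when configured, and the per-image results, per-group summaries
#' (count and area readouts) and pairwise rank-sum comparisons are written
#' as CSVs, plus a run log recording every parameter (including the
#' applied unique threshold in consensus mode).
#'
#' @param config a `PipelineConfig`.
#' @param thresholds optional threshold table (data.frame or path);
#'   defaults to `config$threshold_table`, then `out_dir/thresholds.csv`.
#' @return Invisibly, a list with `results` (list of `QuantResult`),
#'   `summary` data.frame, `comparisons` data.frame and the output paths.
#' @export
run_quantify_phase <- function(config, thresholds = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  m <- .manifest_rows(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- .resolve_thresholds(config, thresholds, m)
  results <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    img <- .process_image(m[k, ], config)
    roi <- NULL
    if (!is.null(config$roi_dir)) {
      rf <- file.path(config$roi_dir, paste0(img$image_id, ".csv"))
      if (!file.exists(rf)) stop("ROI file missing for image '", img$image_id, "': ", rf)
      roi <- read_roi(rf)
    }
    results[[k]] <- quantify_image(
      img, thr$lookup(img$image_id), roi = roi,
      min_diameter_um = config$min_diameter_um,
      max_diameter_um = config$max_diameter_um,
      circ_range = c(config$circ_min, config$circ_max),
      connectivity = config$connectivity)
  }
  paths <- write_results_table(results, file.path(config$out_dir, "results"))
  summary_df <- read_results_table(paths["summary"])

  groups <- sort(unique(summary_df$group))
  g_sum <- NULL
  for (g in groups) {
    for (readout in c("count", "total_area_um2")) {
      s <- summarize_group(summary_df[[readout]][summary_df$group == g], g)
      s$readout <- if (readout == "count") "count" else "area"
      g_sum <- rbind(g_sum, s)
    }
  }
  sum_path <- file.path(config$out_dir, "group_summary.csv")
  write.csv(g_sum[c("group", "readout", "n", "mean", "sd", "min", "max", "median")],
            sum_path, row.names = FALSE)

  comps <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2)
    for (j in seq_len(ncol(pairs))) {
      for (readout in c("count", "total_area_um2")) {
        a <- summary_df[[readout]][summary_df$group == pairs[1, j]]
        b <- summary_df[[readout]][summary_df$group == pairs[2, j]]
        rt <- rank_sum_test(a, b)
        comps <- rbind(comps, data.frame(
          group_a = pairs[1, j], group_b = pairs[2, j],
          readout = if (readout == "count") "count" else "area",
          threshold_mode = config$threshold_mode, U = rt$U, p = rt$p))
      }
    }
  }
  comp_path <- file.path(config$out_dir, "comparisons.csv")
  write.csv(comps %||% data.frame(group_a = character(), group_b = character(),
                                  readout = character(),
                                  threshold_mode = character(),
                                  U = numeric(), p = numeric()),
            comp_path, row.names = FALSE)

  params <- .config_params(config, "quantify")
  if (!is.null(thr$unique_value)) params$applied_unique_threshold <- thr$unique_value
  log_path <- file.path(config$out_dir, "run_log_part2.txt")
  write_run_record(run_record(params), log_path)

  invisible(list(results = results, summary = summary_df,
                 group_summary = g_sum, comparisons = comps,
                 paths = c(paths, group_summary = sum_path,
                           comparisons = comp_path, run_log = log_path)))
}
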