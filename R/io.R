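#' Read a calibrated image stack from a (multi-page) TIFF
#'
#' Reads a single-channel z-stack. Calibration (micrometres per pixel) is
#' taken from the file's resolution metadata when present, and can always
#' be overridden with `calibration`; it is an error to have neither, since
#' every physical-unit step downstream (notably the size filter) needs it.
#' Multi-channel acquisitions are handled by storing one channel per file
#' and recording the channel in the manifest.
#'
#' @param path TIFF file (multi-page = z slices).
#' @param series series index recorded in the default `image_id`
#'   (`"<filestem>:s<series>"`); one file holds one series.
#' @param channel channel identifier to record.
#' @param calibration optional micrometres-per-pixel override.
#' @param group experimental group (e.g. genotype) to record.
#' @param image_id optional explicit identifier.
#' @return An `ImageStack` with integer intensities restored to their
#'   original scale (lossless for 8/16-bit files).
#' @export
read_stack <- function(path, series = 1L, channel = "ch1", calibration = NULL,
                       group = "", image_id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1]])
  px_um <- calibration
  if (is.null(px_um)) {
    xr <- info$x.resolution
    yr <- info$y.resolution
    if (!is.null(xr) && !is.null(yr) && abs(xr - yr) > 1e-6 * xr) {
      stop("non-uniform x/y pixel size in ", path)
    }
    if (!is.null(xr) && is.finite(xr) && xr > 0) {
      unit <- info$resolution.unit
      per_um <- switch(as.character(unit %||% "inch"),
                       inch = xr / 25400, cm = xr / 1e4, xr / 1e4)
      px_um <- 1 / per_um
    }
  }
  if (is.null(px_um)) {
    stop("no pixel-size metadata in ", path,
         " and no 'calibration' override given")
  }
  depth <- info$bits.per.sample %||% 16L
  scale <- if (depth %in% c(8L, 16L)) 2^depth - 1 else 1
  nz <- length(pages)
  d <- dim(pages[[1]])
  vox <- array(0, dim = c(nz, d[1], d[2]))
  for (k in seq_len(nz)) {
    pk <- pages[[k]]
    if (length(dim(pk)) == 3L) pk <- pk[, , 1]  # first sample of multi-sample pages
    vox[k, , ] <- round(pk * scale)
  }
  if (is.null(image_id)) {
    image_id <- sprintf("%s:s%d", tools::file_path_sans_ext(basename(path)), series)
  }
  image_stack(vox, pixel_size_um = px_um,
              bit_depth = if (depth %in% c(8L, 16L)) depth else "float",
              image_id = image_id, channel = channel, group = group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image stack to a multi-page TIFF
#'
#' Integer depths are written losslessly at their native bit depth;
#' float stacks are written as 32-bit float. Note that the TIFF writer
#' does not embed resolution tags, so calibration travels in the manifest.
#'
#' @param stack an `ImageStack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "ImageStack")) stop("expected an ImageStack")
  v <- stack$voxels
  if (identical(stack$bit_depth, "float")) {
    pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , , drop = TRUE])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  } else {
    scale <- 2^stack$bit_depth - 1
    pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , , drop = TRUE] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(stack$bit_depth),
                    compression = "none")
  }
  invisible(path)
}

#' Read / write an experiment manifest
#'
#' The manifest maps image files to series, channels, identifiers, groups
#' and pixel calibration: columns `file`, `series`, `channel`, `image_id`,
#' `group`, `pixel_size_um`. Every downstream table carries `image_id` and
#' `group`, so all statistics are recomputable from files alone.
#'
#' @param path CSV file.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "channel", "image_id", "group")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (!"series" %in% names(m)) m$series <- 1L
  dup <- duplicated(m[c("image_id", "channel")])
  if (any(dup)) stop("duplicate image_id + channel in manifest: ",
                     paste(m$image_id[dup], collapse = ", "))
  if (any(!nzchar(m$group))) stop("every manifest row needs a non-empty group")
  m
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a threshold table
#'
#' One row per image x channel: `image_id`, `channel`, `group`, `method`,
#' `value`, `operator_id`. The table is the hand-off between the threshold
#' phase and the quantify phase, and the input to consensus thresholding.
#' Write-then-read is the identity on all columns; duplicated
#' `image_id + channel` rows are rejected.
#'
#' @param records data.frame of threshold records (non-empty for write).
#' @param path CSV file.
#' @return `path` invisibly (write); data.frame (read).
#' @export
write_threshold_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("refusing to write an empty threshold table")
  need <- c("image_id", "channel", "group", "method", "value")
  if (!all(need %in% names(records))) {
    stop("threshold records need columns: ", paste(need, collapse = ", "))
  }
  if (!"operator_id" %in% names(records)) records$operator_id <- NA_character_
  if (anyDuplicated(records[c("image_id", "channel")])) {
    stop("duplicate image_id + channel rows in threshold table")
  }
  write.csv(records[c(need, "operator_id")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  if (!file.exists(path)) stop("threshold table not found: ", path)
  t <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "channel", "group", "method", "value")
  if (!all(need %in% names(t))) {
    stop("malformed threshold table, need columns: ", paste(need, collapse = ", "))
  }
  dup <- duplicated(t[c("image_id", "channel")])
  if (any(dup)) stop("duplicate image_id + channel rows in threshold table: ",
                     paste(t$image_id[dup], collapse = ", "))
  t
}

#' Write quantification results tables
#'
#' Two CSVs: a summary with one row per image (`image_id`, `group`,
#' `threshold_used`, `count`, `total_area_um2`, filter settings) and a
#' detail table with one row per particle. `path` is used as a stem:
#' `<stem>_summary.csv` and `<stem>_particles.csv`.
#'
#' @param results list of `QuantResult` objects sharing a schema.
#' @param path output stem (may include a directory).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (!is.list(results)) stop("'results' must be a list of QuantResult")
  summary_path <- paste0(path, "_summary.csv")
  detail_path <- paste0(path, "_particles.csv")
  rows <- lapply(results, function(r) {
    data.frame(image_id = r$image_id, group = r$group,
               threshold_used = r$threshold_used, count = r$count,
               total_area_um2 = r$total_area_um2,
               min_diameter_um = r$filters_applied$min_diameter_um %||% NA_real_,
               max_diameter_um = r$filters_applied$max_diameter_um %||% NA_real_,
               circ_min = r$filters_applied$circ_range[1],
               circ_max = r$filters_applied$circ_range[2])
  })
  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), group = character(),
               threshold_used = numeric(), count = integer(),
               total_area_um2 = numeric(), min_diameter_um = numeric(),
               max_diameter_um = numeric(), circ_min = numeric(),
               circ_max = numeric())
  det <- lapply(results, function(r) {
    p <- as.data.frame(r$particles)
    if (nrow(p) == 0L) return(NULL)
    cbind(data.frame(image_id = r$image_id, group = r$group), p)
  })
  det <- det[!vapply(det, is.null, logical(1))]
  detail_df <- if (length(det)) do.call(rbind, det) else
    cbind(data.frame(image_id = character(), group = character()),
          as.data.frame(.empty_particles()))
  write.csv(summary_df, summary_path, row.names = FALSE)
  write.csv(detail_df, detail_path, row.names = FALSE)
  invisible(c(summary = summary_path, particles = detail_path))
}

#' Read back a results summary table
#' @param path the `<stem>_summary.csv` file written by [write_results_table()].
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results table not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Run record: every parameter needed to reproduce a run
#'
#' A flat named list of parameters (filter method and radius, projection,
#' threshold mode, size/circularity limits, seed, ...) plus a timestamp,
#' serialized as human-readable `key: value` lines and parseable back.
#'
#' @param parameters non-empty named list of parameters.
#' @param notes optional character vector of per-image processing notes.
#' @return An object of class `RunRecord`.
#' @export
run_record <- function(parameters, notes = character()) {
  if (!is.list(parameters) || length(parameters) == 0L ||
      is.null(names(parameters)) || any(!nzchar(names(parameters)))) {
    stop("a run always has parameters: supply a non-empty named list")
  }
  structure(list(parameters = parameters,
                 timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
                 notes = notes),
            class = "RunRecord")
}

#' @rdname run_record
#' @param record a `RunRecord`.
#' @param path output text file.
#' @export
write_run_record <- function(record, path) {
  if (!inherits(record, "RunRecord")) stop("expected a RunRecord")
  vals <- vapply(record$parameters, function(v) paste(format(v), collapse = ","),
                 character(1))
  lines <- c(paste0("timestamp: ", record$timestamp),
             paste0(names(record$parameters), ": ", vals))
  if (length(record$notes)) lines <- c(lines, paste0("note: ", record$notes))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname run_record
#' @export
read_run_record <- function(path) {
  if (!file.exists(path)) stop("run record not found: ", path)
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([^:]+): ?(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_, character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, character(1))
  ok <- !is.na(keys)
  keys <- keys[ok]; vals <- vals[ok]
  notes <- vals[keys == "note"]
  params <- as.list(vals[!(keys %in% c("note", "timestamp"))])
  names(params) <- keys[!(keys %in% c("note", "timestamp"))]
  # restore numerics where possible
  params <- lapply(params, function(v) {
    suppressWarnings(num <- as.numeric(strsplit(v, ",")[[1]]))
    if (!anyNA(num)) num else v
  })
  structure(list(parameters = params,
                 timestamp = vals[keys == "timestamp"][1],
                 notes = notes),
            class = "RunRecord")
}
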