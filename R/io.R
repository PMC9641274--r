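# Plain-text containers for cubes, traces, feature tables and reports.
# Numeric payloads are written with 17 significant digits, which round-trips
# IEEE doubles exactly, so write-then-read is lossless.

fmt_full <- function(x) sprintf("%.17g", x)

#' Write / read a THz image cube
#'
#' The cube container is a single text file: a JSON header line holding the
#' grid geometry, time axis, pixel pitch, stored field-of-view and site
#' label, followed by the validity mask and one full-precision trace per
#' pixel.  The round-trip is lossless (bit-identical samples and mask).
#'
#' @param cube a [thz_cube()].
#' @param path file path.
#' @return `read_cube()` returns the [thz_cube()]; `write_cube()` returns
#'   `path` invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "thz_cube"))
  d <- dim(cube$traces)
  header <- list(container = "thzburn-cube", version = 1L,
                 nx = d[1], ny = d[2], n_samples = d[3],
                 dt = cube$dt, t0 = cube$t0, pixel_pitch = cube$pixel_pitch,
                 fov_mm = c(d[1] * cube$pixel_pitch, d[2] * cube$pixel_pitch),
                 label = if (is.null(cube$label)) NULL else unclass(cube$label),
                 class_name = attr(cube, "class_name"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  writeLines(paste(as.integer(cube$valid_mask), collapse = " "), con)
  mat <- matrix(cube$traces, nrow = d[1] * d[2], ncol = d[3])
  writeLines(apply(mat, 1, function(r) paste(fmt_full(r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such cube file: %s", path))
  con <- file(path, "r"); on.exit(close(con))
  header <- tryCatch(jsonlite::fromJSON(readLines(con, n = 1L)),
                     error = function(e)
                       format_error("cube header is not valid JSON"))
  for (fld in c("nx", "ny", "n_samples", "dt", "pixel_pitch"))
    if (is.null(header[[fld]]))
      format_error(sprintf("cube file is missing required field '%s'", fld))
  nx <- header$nx; ny <- header$ny; n <- header$n_samples
  mask_vals <- scan(con, what = integer(), n = nx * ny, quiet = TRUE)
  samp <- scan(con, what = double(), n = nx * ny * n, quiet = TRUE)
  if (length(samp) != nx * ny * n)
    format_error("cube file is truncated: sample block is incomplete")
  label <- if (!is.null(header$label))
    site_label(header$label$site_id, header$label$etiology,
               header$label$dermal_burn_pct, header$label$reepi_pct_day28)
  cube <- thz_cube(array(matrix(samp, nrow = nx * ny, ncol = n, byrow = TRUE),
                         dim = c(nx, ny, n)),
                   dt = header$dt, t0 = header$t0 %||% 0,
                   pixel_pitch = header$pixel_pitch,
                   valid_mask = matrix(as.logical(mask_vals), nx, ny),
                   label = label)
  attr(cube, "class_name") <- header$class_name
  cube
}

#' Write / read a waveform trace
#'
#' JSON header line (`dt`, `t0`, `n_samples`) plus one line of
#' full-precision samples.
#'
#' @param trace a [waveform_trace()].
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "waveform_trace"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(jsonlite::toJSON(list(container = "thzburn-trace", version = 1L,
                                   dt = trace$dt, t0 = trace$t0,
                                   n_samples = length(trace$samples)),
                              auto_unbox = TRUE, digits = NA), con)
  writeLines(paste(fmt_full(trace$samples), collapse = " "), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such trace file: %s", path))
  con <- file(path, "r"); on.exit(close(con))
  header <- tryCatch(jsonlite::fromJSON(readLines(con, n = 1L)),
                     error = function(e)
                       format_error("trace header is not valid JSON"))
  if (is.null(header$dt)) format_error("trace file is missing required field 'dt'")
  samp <- scan(con, what = double(), n = header$n_samples, quiet = TRUE)
  waveform_trace(samp, dt = header$dt, t0 = header$t0 %||% 0)
}

#' Write / read an ESER feature table
#'
#' The feature table is a CSV holding one row per ROI observation — its
#' identifiers, labels and the deconvolved ESER values at full precision —
#' plus a JSON sidecar (`<path>.json`) recording the wavelet, level and
#' sub-band configuration that produced it.
#'
#' @param features a feature matrix from [eser_features()] (with its `meta`
#'   attribute), or a data frame already combining metadata and features.
#' @param path CSV file path.
#' @param run_config optional list stored in the JSON sidecar.
#' @export
write_features <- function(features, path, run_config = NULL) {
  if (is.matrix(features)) {
    meta <- attr(features, "meta")
    if (is.null(meta)) config_error("feature matrix lacks its 'meta' attribute")
    df <- cbind(meta, as.data.frame(features))
    side <- list(wavelet = attr(features, "wavelet"),
                 level = attr(features, "level"),
                 subbands = attr(features, "subbands"))
  } else {
    df <- as.data.frame(features)
    side <- list()
  }
  if (anyDuplicated(df$roi_id))
    integrity_error("duplicated observation ids in the feature table")
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_full)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  side$run_config <- run_config
  if (length(side))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}

feature_meta_cols <- c("roi_id", "site_id", "etiology", "dermal_burn_pct",
                       "reepi_pct_day28", "severity", "healing")

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such feature table: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(feature_meta_cols, names(df))
  if (length(missing_cols))
    integrity_error(sprintf("feature table is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$roi_id))
    integrity_error("duplicated observation ids in the feature table")
  df$severity <- factor(df$severity, levels = c("H", "SPT", "DPT", "FT"))
  df$healing <- factor(df$healing, levels = c("FR", "NPR"))
  feat_cols <- grep("^n[0-9]+$", names(df), value = TRUE)
  mat <- as.matrix(df[feat_cols])
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::fromJSON(side_path)
    attr(mat, "wavelet") <- side$wavelet
    attr(mat, "level") <- side$level
    attr(mat, "subbands") <- side$subbands
  }
  attr(mat, "meta") <- df[intersect(feature_meta_cols, names(df))]
  mat
}

#' Write / read an evaluation report
#'
#' JSON serialization of a [burn_experiment()] report: per-iteration
#' metrics, aggregates, winning configurations and partition sizes.
#'
#' @param report a `burn_eval` object.
#' @param path JSON file path.
#' @param run_config optional configuration list embedded in the report.
#' @export
write_report <- function(report, path, run_config = NULL) {
  stopifnot(inherits(report, "burn_eval"))
  payload <- list(task = report$task, n_iterations = report$n_iterations,
                  positive = report$positive,
                  metrics = report$metrics, aggregate = report$aggregate,
                  configs = report$configs,
                  sizes = as.data.frame(report$sizes),
                  run_config = run_config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such report: %s", path))
  jsonlite::fromJSON(path)
}
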