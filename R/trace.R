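#' Time-domain waveform trace
#'
#' A `waveform_trace` is one time-domain electric-field record: a numeric
#' vector of field amplitudes (arbitrary units) together with its time axis,
#' described by the time of the first sample `t0` and the sampling step `dt`,
#' both in picoseconds.
#'
#' @param samples numeric vector of electric-field amplitudes (a.u.); all
#'   values must be finite.
#' @param dt sampling step in picoseconds; must be positive.
#' @param t0 time of the first sample in picoseconds.
#' @return An object of class `waveform_trace`: a list with elements
#'   `samples`, `dt`, `t0`.
#' @examples
#' tr <- waveform_trace(sin(2 * pi * 0.5 * seq(0, 40, by = 0.05)), dt = 0.05)
#' length(time_axis(tr))
#' @export
waveform_trace <- function(samples, dt, t0 = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    config_error("'dt' must be a single positive number (ps)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    config_error("'t0' must be a single finite number (ps)")
  samples <- as.numeric(samples)
  if (length(samples) < 1L || !all(is.finite(samples)))
    config_error("'samples' must be a non-empty vector of finite values")
  structure(list(samples = samples, dt = dt, t0 = t0),
            class = "waveform_trace")
}

#' @rdname waveform_trace
#' @param x a `waveform_trace`.
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "waveform_trace"))
  x$t0 + x$dt * (seq_along(x$samples) - 1)
}

#' @export
print.waveform_trace <- function(x, ...) {
  cat(sprintf("<waveform_trace> %d samples, dt = %g ps, t0 = %g ps, span %.2f ps\n",
              length(x$samples), x$dt, x$t0,
              x$dt * (length(x$samples) - 1)))
  invisible(x)
}

#' @export
length.waveform_trace <- function(x) length(x$samples)

as_trace_samples <- function(x) {
  if (inherits(x, "waveform_trace")) x$samples else as.numeric(x)
}

#' THz-TDS image cube
#'
#' Container for one measurement site: an `nx` by `ny` grid of time-domain
#' traces sharing a common time axis, a per-pixel validity mask, the pixel
#' pitch and the site label.  Traces are stored as a numeric array with
#' dimensions `c(nx, ny, n_samples)`.
#'
#' @param traces numeric array `nx x ny x n_samples` of field amplitudes.
#' @param dt sampling step (ps).
#' @param t0 time of the first sample (ps).
#' @param pixel_pitch pixel spacing in mm (default 1, a 1-mm^2 pixel).
#' @param valid_mask logical `nx x ny` matrix; `FALSE` marks pixels excluded
#'   from analysis (biopsy or corner pixels).  Defaults to all valid.
#' @param label a [site_label()] or `NULL`.
#' @return An object of class `thz_cube`.
#' @export
thz_cube <- function(traces, dt, t0 = 0, pixel_pitch = 1,
                     valid_mask = NULL, label = NULL) {
  if (!is.array(traces) || length(dim(traces)) != 3L)
    config_error("'traces' must be a 3-d array (nx, ny, n_samples)")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    config_error("'dt' must be a single positive number (ps)")
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    config_error("'pixel_pitch' must be positive (mm)")
  d <- dim(traces)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[1], d[2])
  if (!is.matrix(valid_mask) || !identical(dim(valid_mask), d[1:2]))
    config_error("'valid_mask' must be a logical matrix matching the grid")
  storage.mode(valid_mask) <- "logical"
  structure(list(traces = traces, dt = dt, t0 = t0,
                 pixel_pitch = pixel_pitch, valid_mask = valid_mask,
                 label = label),
            class = "thz_cube")
}

#' @export
print.thz_cube <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf("<thz_cube> %d x %d pixels (%g mm pitch), %d samples at dt = %g ps\n",
              d[1], d[2], x$pixel_pitch, d[3], x$dt))
  cat(sprintf("  field-of-view %g x %g mm^2; %d/%d pixels valid\n",
              d[1] * x$pixel_pitch, d[2] * x$pixel_pitch,
              sum(x$valid_mask), length(x$valid_mask)))
  if (!is.null(x$label))
    cat(sprintf("  site %s (%s): dermal burn %.1f%%, day-28 re-epi %.1f%%\n",
                x$label$site_id, x$label$etiology,
                x$label$dermal_burn_pct, x$label$reepi_pct_day28))
  invisible(x)
}

cube_dims <- function(cube) dim(cube$traces)

# One pixel of a cube as a waveform_trace.
cube_trace <- function(cube, i, j) {
  waveform_trace(cube$traces[i, j, ], dt = cube$dt, t0 = cube$t0)
}

# Flatten the cube's traces to an (n_samples x n_pixels) matrix, pixels in
# column-major (i fastest) order; used by the vectorised conditioning steps.
cube_matrix <- function(cube) {
  d <- dim(cube$traces)
  t(matrix(cube$traces, nrow = d[1] * d[2], ncol = d[3]))
}

matrix_to_cube <- function(mat, cube) {
  d <- dim(cube$traces)
  cube$traces <- array(t(mat), dim = d)
  cube
}

#' Site label
#'
#' Ground-truth description of one measurement site: the burn etiology, the
#' histological dermal burn percentage on day 0, and the day-28
#' re-epithelialization percentage that defines the healing outcome.
#'
#' @param site_id identifier string.
#' @param etiology one of `"scald"`, `"contact"`, `"healthy"`.
#' @param dermal_burn_pct dermal burn depth percentage in \[0, 100\].
#' @param reepi_pct_day28 day-28 re-epithelialization percentage in \[0, 100\].
#' @return An object of class `site_label`.
#' @export
site_label <- function(site_id, etiology = c("scald", "contact", "healthy"),
                       dermal_burn_pct, reepi_pct_day28) {
  etiology <- match.arg(etiology)
  for (v in c(dermal_burn_pct = dermal_burn_pct,
              reepi_pct_day28 = reepi_pct_day28)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 100)
      label_error("percentages must be single values in [0, 100]")
  }
  structure(list(site_id = as.character(site_id), etiology = etiology,
                 dermal_burn_pct = dermal_burn_pct,
                 reepi_pct_day28 = reepi_pct_day28),
            class = "site_label")
}
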