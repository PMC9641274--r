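#' Zero-phase band-pass filter
#'
#' Filters a trace with a zero-phase frequency-domain mask: unit gain over
#' `[f_lo, f_hi]`, raised-cosine tapers of width 10% of each band edge just
#' outside the passband, zero beyond.  Zero-phase filtering leaves the
#' reflection-peak positions untouched, which the alignment and gating
#' stages rely on.
#'
#' @param trace a [waveform_trace()].
#' @param f_lo,f_hi passband edges in THz; `f_hi` must lie below Nyquist.
#' @return The filtered [waveform_trace()].
#' @export
bandpass <- function(trace, f_lo = 0.1, f_hi = 1.0) {
  stopifnot(inherits(trace, "waveform_trace"))
  m <- bandpass_mask(length(trace$samples), trace$dt, f_lo, f_hi)
  out <- trace
  out$samples <- Re(fft(fft(trace$samples) * m, inverse = TRUE)) /
    length(trace$samples)
  out
}

bandpass_mask <- function(n, dt, f_lo, f_hi) {
  nyq <- 1 / (2 * dt)
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < nyq))
    config_error("need 0 < f_lo < f_hi < Nyquist for the band-pass filter")
  f <- abs(c(0:(n %/% 2), -((n - n %/% 2 - 1):1))) / (n * dt)
  w_lo <- 0.1 * f_lo; w_hi <- 0.1 * f_hi
  m <- numeric(n)
  m[f >= f_lo & f <= f_hi] <- 1
  lo <- f < f_lo & f > f_lo - w_lo
  m[lo] <- 0.5 * (1 + cos(pi * (f_lo - f[lo]) / w_lo))
  hi <- f > f_hi & f < f_hi + w_hi
  m[hi] <- 0.5 * (1 + cos(pi * (f[hi] - f_hi) / w_hi))
  m
}

#' @rdname bandpass
#' @param cube a [thz_cube()]; all pixel traces are filtered with one mask.
#' @export
bandpass_cube <- function(cube, f_lo = 0.1, f_hi = 1.0) {
  stopifnot(inherits(cube, "thz_cube"))
  d <- dim(cube$traces)
  m <- bandpass_mask(d[3], cube$dt, f_lo, f_hi)
  X <- cube_matrix(cube)                       # n_samples x n_pixels
  Y <- Re(stats::mvfft(stats::mvfft(X) * m, inverse = TRUE)) / d[3]
  matrix_to_cube(Y, cube)
}

#' Align a cube on its first reflection
#'
#' Circularly shifts every pixel trace by the integer lag that maximizes the
#' cross-correlation of its gated first reflection against a template.  The
#' template is the site-median trace by default; passing the air reference
#' instead aligns the site onto the reference time base, recovering global
#' per-site drifts (a site planted with a +7-sample shift yields recovered
#' shifts of -7).
#'
#' Pixels whose gated segment is identically zero cannot be aligned and are
#' marked invalid.
#'
#' @param cube a [thz_cube()].
#' @param reference_gate time interval `c(t_lo, t_hi)` (ps) bracketing the
#'   first reflection.
#' @param template optional [waveform_trace()] (or numeric vector on the same
#'   axis) used as the alignment target; default: site-median trace.
#' @param max_lag largest |lag| searched (samples).
#' @return A list with `cube` (aligned) and `shifts` (`nx x ny` integer
#'   matrix of applied shifts; a trace delayed by `s` samples gets shift
#'   `-s`).
#' @export
align_cube <- function(cube, reference_gate, template = NULL, max_lag = 25L) {
  stopifnot(inherits(cube, "thz_cube"))
  d <- dim(cube$traces); n <- d[3]
  idx <- gate_indices(cube, reference_gate)
  if (length(idx) < 2L) config_error("'reference_gate' is too narrow or outside the trace")
  lags <- -max_lag:max_lag
  if (min(idx) + min(lags) < 1L || max(idx) + max(lags) > n)
    config_error("'reference_gate' +/- max_lag must stay inside the trace")
  X <- cube_matrix(cube)                       # n_samples x n_pixels
  if (is.null(template)) {
    tmpl <- apply(X[, as.vector(cube$valid_mask), drop = FALSE], 1, stats::median)
  } else {
    tmpl <- as_trace_samples(template)
    if (length(tmpl) != n)
      config_error("'template' length does not match the cube's traces")
  }
  tg <- tmpl[idx]
  # corr[lag, pixel] = sum_t template(t) * trace(t + lag)
  corr <- vapply(lags, function(l) as.vector(tg %*% X[idx + l, , drop = FALSE]),
                 numeric(ncol(X)))
  best <- lags[max.col(corr, ties.method = "first")]
  seg_energy <- colSums(X[idx, , drop = FALSE]^2)
  dead <- seg_energy == 0
  best[dead] <- 0L
  shifts <- matrix(-as.integer(best), d[1], d[2])
  mask <- cube$valid_mask & !matrix(dead, d[1], d[2])
  for (p in which(best != 0L)) {
    l <- best[p]
    X[, p] <- X[c((l %% n + 1L):n, seq_len(l %% n))[1:n], p]
  }
  out <- matrix_to_cube(X, cube)
  out$valid_mask <- mask
  list(cube = out, shifts = shifts)
}

gate_indices <- function(cube_or_trace, interval) {
  dt <- cube_or_trace$dt; t0 <- cube_or_trace$t0
  n <- if (inherits(cube_or_trace, "thz_cube")) dim(cube_or_trace$traces)[3]
       else length(cube_or_trace$samples)
  if (length(interval) != 2L || interval[1] >= interval[2])
    config_error("gate interval must be c(t_lo, t_hi) with t_lo < t_hi")
  i0 <- max(1L, ceiling((interval[1] - t0) / dt) + 1L)
  i1 <- min(n, floor((interval[2] - t0) / dt) + 1L)
  if (i0 > i1) config_error("gate interval lies outside the trace")
  i0:i1
}

#' Flag biopsy pixels from post-pulse Fabry-Perot energy
#'
#' Biopsy punches leave an air gap that produces an extra Fabry-Perot echo
#' after the tissue reflection.  Pixels whose energy inside `post_pulse_gate`
#' exceeds the site median by more than `k_mad` robust standard deviations
#' (median absolute deviation) are marked invalid.  The corner pixels stay
#' invalid regardless (the scanner housing clips the beam there).
#'
#' @param cube a [thz_cube()] (aligned).
#' @param post_pulse_gate time interval `c(t_lo, t_hi)` (ps) after the tissue
#'   reflection.
#' @param k_mad threshold factor (default 5).
#' @return The cube with an updated `valid_mask`; the newly flagged pixels
#'   are attached as attribute `flagged` (logical matrix).
#' @export
detect_invalid_pixels <- function(cube, post_pulse_gate, k_mad = 5) {
  stopifnot(inherits(cube, "thz_cube"))
  d <- dim(cube$traces)
  idx <- gate_indices(cube, post_pulse_gate)
  X <- cube_matrix(cube)
  energy <- colSums(X[idx, , drop = FALSE]^2)
  ok <- as.vector(cube$valid_mask)
  med <- stats::median(energy[ok])
  s <- stats::mad(energy[ok])
  flagged <- matrix(energy > med + k_mad * s, d[1], d[2]) & cube$valid_mask
  cube$valid_mask <- cube$valid_mask & !flagged
  cube$valid_mask[c(1, d[1]), c(1, d[2])] <- FALSE
  attr(cube, "flagged") <- flagged
  cube
}

#' Blackman gate specification
#'
#' @param width gate duration in ps (default 25, spanning the tissue
#'   reflection).
#' @param window_shape only `"blackman"` is supported.
#' @param center_policy how the gate center is found: the absolute-amplitude
#'   peak of the second reflection.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(width = 25, window_shape = "blackman",
                      center_policy = "peak-of-second-reflection") {
  if (!identical(window_shape, "blackman"))
    config_error("only the Blackman window shape is supported")
  if (!is.numeric(width) || width <= 0) config_error("'width' must be positive (ps)")
  structure(list(width = width, window_shape = window_shape,
                 center_policy = center_policy),
            class = "gate_spec")
}

#' Isolate the tissue reflection with a Blackman time gate
#'
#' Multiplies the trace by a Blackman window of duration `spec$width`
#' centered on the absolute-amplitude peak of the tissue (second) reflection
#' and crops the result to the window support, so the output length is fixed
#' at `round(width / dt)` samples for a given run.  Gating an already gated
#' trace with the same spec is a no-op: the trace records the gate applied
#' to it, making the operation idempotent.
#'
#' @param trace a [waveform_trace()].
#' @param spec a [gate_spec()].
#' @param search optional `c(t_lo, t_hi)` (ps) restricting the peak search to
#'   the second reflection (otherwise the whole trace is searched — only
#'   appropriate for single-pulse traces such as the air reference).
#' @param center optional sample index overriding the peak search; used to
#'   gate every pixel of a site at one common center.
#' @return The gated [waveform_trace()], cropped to the window support.
#' @export
gate_tissue_reflection <- function(trace, spec = gate_spec(), search = NULL,
                                   center = NULL) {
  stopifnot(inherits(trace, "waveform_trace"), inherits(spec, "gate_spec"))
  if (!is.null(trace$gate) && isTRUE(all.equal(trace$gate, unclass(spec))))
    return(trace)
  n <- length(trace$samples)
  W <- as.integer(round(spec$width / trace$dt))
  if (W < 4L) config_error("gate width is shorter than 4 samples")
  if (is.null(center)) {
    sidx <- if (is.null(search)) seq_len(n) else gate_indices(trace, search)
    center <- sidx[which.max(abs(trace$samples[sidx]))]
  }
  start <- center - (W %/% 2L) + 1L
  stop_ <- start + W - 1L
  if (start < 1L || stop_ > n)
    gating_error("gate window would be truncated at the trace boundary")
  win <- blackman_window(W)
  out <- waveform_trace(trace$samples[start:stop_] * win, dt = trace$dt,
                        t0 = trace$t0 + (start - 1L) * trace$dt)
  out$gate <- unclass(spec)
  out
}

blackman_window <- function(n) as.numeric(signal::blackman(n))

#' @rdname gate_tissue_reflection
#' @param cube a [thz_cube()] (aligned); the gate center is located once on
#'   the mean trace over valid pixels and applied to every pixel, so all
#'   gated traces share a time base.
#' @export
gate_cube <- function(cube, spec = gate_spec(), search = NULL) {
  stopifnot(inherits(cube, "thz_cube"))
  d <- dim(cube$traces)
  X <- cube_matrix(cube)
  mean_tr <- rowMeans(X[, as.vector(cube$valid_mask), drop = FALSE])
  ref <- waveform_trace(mean_tr, dt = cube$dt, t0 = cube$t0)
  sidx <- if (is.null(search)) seq_len(d[3]) else gate_indices(ref, search)
  center <- sidx[which.max(abs(mean_tr[sidx]))]
  W <- as.integer(round(spec$width / cube$dt))
  start <- center - (W %/% 2L) + 1L
  if (start < 1L || start + W - 1L > d[3])
    gating_error("gate window would be truncated at the trace boundary")
  win <- blackman_window(W)
  Y <- X[start:(start + W - 1L), , drop = FALSE] * win
  out <- cube
  out$traces <- array(t(Y), dim = c(d[1], d[2], W))
  out$t0 <- cube$t0 + (start - 1L) * cube$dt
  attr(out, "gate") <- unclass(spec)
  out
}

#' Extract averaged region-of-interest observations
#'
#' Tiles the grid into non-overlapping `roi_side x roi_side` blocks starting
#' at pixel (1, 1); blocks containing any invalid pixel are dropped; each
#' surviving block yields one observation whose trace is the pixel-wise mean
#' of its member traces.  Spatial averaging suppresses rough-surface
#' scattering artifacts.
#'
#' @param cube a [thz_cube()], conditioned (aligned and gated) with its mask
#'   final.
#' @param roi_side ROI edge length in pixels (default 5, i.e. 25 pixels per
#'   observation).
#' @return A list of `roi_observation` objects, each with `roi_id`,
#'   `site_id`, `mean_trace` (a [waveform_trace()]), `label`, and the block
#'   position.
#' @export
extract_roi_observations <- function(cube, roi_side = 5L) {
  stopifnot(inherits(cube, "thz_cube"))
  d <- dim(cube$traces)
  if (roi_side > d[1] || roi_side > d[2])
    config_error("'roi_side' exceeds the grid size")
  site <- if (!is.null(cube$label)) cube$label$site_id else "site"
  out <- list()
  for (bi in seq_len(d[1] %/% roi_side)) {
    for (bj in seq_len(d[2] %/% roi_side)) {
      rows <- ((bi - 1L) * roi_side + 1L):(bi * roi_side)
      cols <- ((bj - 1L) * roi_side + 1L):(bj * roi_side)
      if (!all(cube$valid_mask[rows, cols])) next
      block <- cube$traces[rows, cols, , drop = FALSE]
      mean_samp <- colMeans(matrix(block, nrow = roi_side^2, ncol = d[3]))
      tr <- waveform_trace(mean_samp, dt = cube$dt, t0 = cube$t0)
      tr$gate <- attr(cube, "gate")
      out[[length(out) + 1L]] <- structure(
        list(roi_id = sprintf("%s_r%02d_c%02d", site, bi, bj),
             site_id = site, mean_trace = tr, label = cube$label,
             block = c(bi, bj),
             class_name = attr(cube, "class_name")),
        class = "roi_observation")
    }
  }
  out
}

#' One-call signal conditioning for a site
#'
#' Chains the conditioning stages: band-pass filter, first-reflection
#' alignment (against the air reference when given), biopsy-pixel rejection,
#' Blackman gating of the tissue reflection, and ROI averaging.
#'
#' @param cube a raw [thz_cube()].
#' @param air optional air-reference [waveform_trace()] used as the
#'   alignment template.
#' @param band passband `c(f_lo, f_hi)` in THz.
#' @param first_gate time interval around the first reflection (ps).
#' @param post_pulse_gate interval after the tissue pulse used for biopsy
#'   detection (ps).
#' @param tissue_search interval bracketing the tissue reflection peak (ps).
#' @param spec a [gate_spec()].
#' @param k_mad biopsy detection threshold factor.
#' @param roi_side ROI edge length (pixels).
#' @param max_lag alignment search bound (samples).
#' @return A list with `observations` (see [extract_roi_observations()]),
#'   `cube` (the conditioned, gated cube) and `shifts`.
#' @export
condition_cube <- function(cube, air = NULL, band = c(0.1, 1.0),
                           first_gate, post_pulse_gate, tissue_search,
                           spec = gate_spec(), k_mad = 5, roi_side = 5L,
                           max_lag = 25L) {
  # Alignment runs on the raw traces, where both reflections are compact;
  # the band-pass can ring a strongly tilted tissue reflection into the
  # first-reflection gate and bias the lag estimate.  Integer circular
  # shifts commute with the circular zero-phase filter, so aligning first
  # is equivalent.
  al <- align_cube(cube, first_gate, template = air, max_lag = max_lag)
  cb <- bandpass_cube(al$cube, band[1], band[2])
  cb <- detect_invalid_pixels(cb, post_pulse_gate, k_mad = k_mad)
  gated <- gate_cube(cb, spec, search = tissue_search)
  list(observations = extract_roi_observations(gated, roi_side),
       cube = gated, shifts = al$shifts)
}

#' @rdname condition_cube
#' @param trace the raw air-reference trace; conditioned identically to the
#'   tissue traces (band-pass plus Blackman gate on its principal
#'   reflection) so the ESER deconvolution cancels the system response
#'   coherently.
#' @export
condition_air <- function(trace, band = c(0.1, 1.0), spec = gate_spec()) {
  gate_tissue_reflection(bandpass(trace, band[1], band[2]), spec)
}
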