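#' Scene configuration for the synthetic THz-TDS simulator
#'
#' Describes the simulated measurement: a single-cycle THz pulse reflected
#' once at the air/imaging-window interface (arrival `tau1`, amplitude `a1`)
#' and once at the window/tissue interface (arrival `tau2`), the latter
#' shaped by a severity-dependent tissue spectral response.  Biopsy pixels
#' additionally carry a delayed Fabry-Perot echo from the air gap left by the
#' punch.  All pixels of one site share a single global integer timing drift;
#' white Gaussian noise is added per pixel.
#'
#' The tissue response of class `c` is `rho_c * exp(-beta_c * f)` applied in
#' the frequency domain (`f` in THz): a broadband reflectivity scale and an
#' exponential spectral tilt.  The default severity ladder orders `rho`
#' upward (more severe burns reflect more strongly, as observed for edematous
#' tissue) and `beta` upward (severe burns attenuate the high-frequency
#' content more), which drives the mean in-band ESER down with severity.
#'
#' @param dt sampling step (ps); the 0.01-ps default puts Nyquist at 50 THz so
#'   level-12 sub-bands 10-80 span about 0.12-0.99 THz.
#' @param n_samples trace length (>= 64 samples).
#' @param pulse_width intensity FWHM of the THz pulse (ps).
#' @param tau1,tau2 arrival times (ps) of the air-window and window-tissue
#'   reflections.
#' @param a1 air-window reflection amplitude (a.u.).
#' @param reflectivity_by_class named list; each element `c(rho =, beta =)`
#'   (`beta` in 1/THz).  Order defines the severity ladder.
#' @param fp_delay Fabry-Perot echo delay at biopsy pixels (ps).
#' @param fp_amp echo amplitude as a fraction of the tissue reflection.
#' @param snr_db additive-noise SNR in dB relative to the clean trace RMS;
#'   `Inf` disables noise.
#' @param drift_max bound on the per-site global timing drift (samples).
#' @param nx,ny grid size (pixels).
#' @param seed default RNG seed used by the generators when no explicit seed
#'   is passed.
#' @return An object of class `scene_config` (validated list).
#' @export
scene_config <- function(dt = 0.01, n_samples = 8192, pulse_width = 2,
                         tau1 = 14, tau2 = 28, a1 = 1,
                         reflectivity_by_class = list(
                           H   = c(rho = 0.45, beta = 0.3),
                           SPT = c(rho = 0.50, beta = 1.2),
                           DPT = c(rho = 0.55, beta = 2.5),
                           FT  = c(rho = 0.60, beta = 4.5)),
                         fp_delay = 9, fp_amp = 0.5, snr_db = 30,
                         drift_max = 5, nx = 27, ny = 27, seed = 1L) {
  if (dt <= 0) config_error("'dt' must be positive")
  if (n_samples < 64) config_error("'n_samples' must be at least 64")
  if (pulse_width <= 0) config_error("'pulse_width' must be positive")
  span <- n_samples * dt
  if (!(tau1 < tau2 && tau2 + fp_delay < span))
    config_error("need tau1 < tau2 < tau2 + fp_delay < n_samples * dt")
  if (fp_delay <= 0 || fp_amp < 0) config_error("invalid Fabry-Perot echo parameters")
  if (drift_max < 0 || drift_max != round(drift_max))
    config_error("'drift_max' must be a non-negative integer (samples)")
  if (nx < 1 || ny < 1) config_error("grid size must be positive")
  if (!is.list(reflectivity_by_class) || is.null(names(reflectivity_by_class)))
    config_error("'reflectivity_by_class' must be a named list")
  for (cl in names(reflectivity_by_class)) {
    v <- unlist(reflectivity_by_class[[cl]])
    if (is.null(names(v)) && length(v) == 2L) names(v) <- c("rho", "beta")
    if (!all(c("rho", "beta") %in% names(v)) || v[["rho"]] <= 0 || v[["beta"]] < 0)
      config_error(sprintf("class '%s' needs positive rho and non-negative beta", cl))
    reflectivity_by_class[[cl]] <- v[c("rho", "beta")]
  }
  rhos <- vapply(reflectivity_by_class, function(v) v[["rho"]], numeric(1))
  if (length(rhos) > 1 && any(diff(rhos) == 0))
    warning("reflectivity 'rho' values are not strictly ordered across classes")
  structure(list(dt = dt, n_samples = as.integer(n_samples),
                 pulse_width = pulse_width, tau1 = tau1, tau2 = tau2, a1 = a1,
                 reflectivity_by_class = reflectivity_by_class,
                 fp_delay = fp_delay, fp_amp = fp_amp, snr_db = snr_db,
                 drift_max = as.integer(drift_max),
                 nx = as.integer(nx), ny = as.integer(ny),
                 seed = seed),
            class = "scene_config")
}

# Ratio t/sigma at which the Ricker intensity falls to half its peak;
# solves (1 - x) * exp(-x/2) = 1/sqrt(2) for x = (t/sigma)^2.
ricker_half_intensity_x <- function() {
  uniroot(function(x) (1 - x) * exp(-x / 2) - 1 / sqrt(2),
          c(1e-9, 0.9), tol = 1e-14)$root
}

ricker_sigma <- function(pulse_width) {
  pulse_width / (2 * sqrt(ricker_half_intensity_x()))
}

# Single-cycle pulse: second derivative of a Gaussian (Ricker wavelet),
# peak-normalized to 1 at t = 0.
ricker <- function(t, sigma) {
  x <- (t / sigma)^2
  (1 - x) * exp(-x / 2)
}

#' Generate the simulator's THz pulse
#'
#' The single-cycle pulse model: the second derivative of a Gaussian (Ricker
#' wavelet), peak-normalized to 1 and centered at `t = 0`, with the intensity
#' FWHM set by `config$pulse_width`.  Its amplitude spectrum is band-limited
#' and DC-free, with a spectral peak inside the 0.1-1 THz measurement band
#' for the 2-ps default width.
#'
#' @param config a [scene_config()].
#' @return A [waveform_trace()] of length `config$n_samples` centered at
#'   `t = 0` (so `t0 = -n_samples/2 * dt`).
#' @export
generate_pulse <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  sigma <- ricker_sigma(config$pulse_width)
  t0 <- -config$n_samples / 2 * config$dt
  t <- t0 + config$dt * (0:(config$n_samples - 1))
  waveform_trace(ricker(t, sigma), dt = config$dt, t0 = t0)
}

# Tissue-reflected pulse arriving at tau: Ricker shaped in the frequency
# domain by the class response rho * exp(-beta * |f|) (f in THz; real, even
# in f, hence zero-phase).
tilted_pulse <- function(config, tau, rho, beta) {
  n <- config$n_samples
  sigma <- ricker_sigma(config$pulse_width)
  t <- config$dt * (0:(n - 1))
  base <- ricker(t - tau, sigma)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * config$dt)
  resp <- rho * exp(-beta * abs(f))
  Re(fft(fft(base) * resp, inverse = TRUE)) / n
}

severity_class_of <- function(label, scheme = label_scheme()) {
  if (label$etiology == "healthy") "H"
  else assign_labels(label, scheme)$severity
}

#' Generate one synthetic measurement site
#'
#' Builds the image cube of one site: every pixel trace is
#' `a1 * pulse(t - tau1) + tilted_pulse(t - tau2)` plus, at biopsy pixels
#' only, a Fabry-Perot echo `fp_amp * tilted_pulse(t - tau2 - fp_delay)`,
#' plus white Gaussian noise at `snr_db`.  All pixels share one random
#' integer timing shift bounded by `drift_max`.  The four corner pixels are
#' flagged invalid in the mask (the scanner housing clips the beam there);
#' biopsy pixels stay valid in the returned mask — finding them is the
#' preprocessing stage's job.
#'
#' @param config a [scene_config()].
#' @param label a [site_label()].
#' @param biopsy_region `NULL`, or `list(rows =, cols =)` of pixel index
#'   vectors inside the grid.
#' @param class reflectivity class name; defaults to the severity class
#'   implied by the label.
#' @param seed optional RNG seed (defaults to the ambient RNG stream).
#' @return A [thz_cube()] with attributes `class` (reflectivity class),
#'   `drift` (the planted shift, samples) and `biopsy_mask` (logical matrix,
#'   the planted ground truth).
#' @export
generate_site_cube <- function(config, label, biopsy_region = NULL,
                               class = NULL, seed = NULL) {
  stopifnot(inherits(config, "scene_config"), inherits(label, "site_label"))
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  class <- class %||% severity_class_of(label)
  if (!class %in% names(config$reflectivity_by_class))
    config_error(sprintf("no reflectivity entry for class '%s'", class))
  rb <- config$reflectivity_by_class[[class]]
  n <- config$n_samples; nx <- config$nx; ny <- config$ny
  npix <- nx * ny
  sigma <- ricker_sigma(config$pulse_width)
  t <- config$dt * (0:(n - 1))

  clean <- config$a1 * ricker(t - config$tau1, sigma) +
    tilted_pulse(config, config$tau2, rb[["rho"]], rb[["beta"]])
  biopsy_mask <- matrix(FALSE, nx, ny)
  if (!is.null(biopsy_region)) {
    rows <- biopsy_region$rows; cols <- biopsy_region$cols
    if (is.null(rows) || is.null(cols) ||
        any(rows < 1 | rows > nx) || any(cols < 1 | cols > ny))
      config_error("'biopsy_region' must be list(rows =, cols =) inside the grid")
    biopsy_mask[rows, cols] <- TRUE
  }
  echo <- if (any(biopsy_mask)) {
    config$fp_amp * tilted_pulse(config, config$tau2 + config$fp_delay,
                                 rb[["rho"]], rb[["beta"]])
  } else NULL

  drift <- if (config$drift_max > 0)
    sample.int(2L * config$drift_max + 1L, 1L) - config$drift_max - 1L
  else 0L

  mat <- matrix(clean, nrow = npix, ncol = n, byrow = TRUE)
  if (!is.null(echo)) {
    bidx <- which(as.vector(biopsy_mask))
    mat[bidx, ] <- mat[bidx, , drop = FALSE] +
      matrix(echo, nrow = length(bidx), ncol = n, byrow = TRUE)
  }
  if (drift != 0L) {
    idx <- ((0:(n - 1)) - drift) %% n + 1L   # shift right by `drift` samples
    mat <- mat[, idx, drop = FALSE]
  }
  if (is.finite(config$snr_db)) {
    sd_n <- sqrt(mean(clean^2)) * 10^(-config$snr_db / 20)
    mat <- mat + matrix(stats::rnorm(npix * n, sd = sd_n), npix, n)
  }
  mask <- matrix(TRUE, nx, ny)
  mask[c(1, nx), c(1, ny)] <- FALSE          # corner pixels
  cube <- thz_cube(array(mat, dim = c(nx, ny, n)), dt = config$dt, t0 = 0,
                   pixel_pitch = 1, valid_mask = mask, label = label)
  attr(cube, "class_name") <- class
  attr(cube, "drift") <- drift
  attr(cube, "biopsy_mask") <- biopsy_mask
  cube
}

#' Generate a labelled synthetic dataset
#'
#' Draws `class_counts[c]` sites per reflectivity class, with dermal-burn
#' percentages inside the class's histological threshold interval and day-28
#' re-epithelialization percentages negatively correlated with severity
#' (probability of full closure set by `fr_prob`).  Burn sites get a randomly
#' placed biopsy block; healthy sites do not.  Also returns the air/mirror
#' reference trace: the first reflection alone, measured at 20 dB lower
#' noise.
#'
#' The default site counts, combined with the default 27 x 27 grid and
#' non-overlapping 5 x 5 regions of interest, are sized so the per-class
#' observation yields land near 300/332/224/569 for H/SPT/DPT/FT.
#'
#' @param config a [scene_config()].
#' @param class_counts named integer vector of sites per class; names must
#'   index `config$reflectivity_by_class`.
#' @param seed RNG seed (default `config$seed`); the run is bit-reproducible
#'   given the seed.
#' @param fr_prob named probability of a site being fully re-epithelialized,
#'   per class.
#' @param biopsy_size edge length (pixels) of the square biopsy block planted
#'   in burn sites; 0 disables.
#' @return A list with `cubes` (list of [thz_cube()]), `air`
#'   (a [waveform_trace()]), and `config`.
#' @export
generate_dataset <- function(config,
                             class_counts = c(H = 13, SPT = 16, DPT = 11, FT = 27),
                             seed = config$seed,
                             fr_prob = c(H = 1, SPT = 0.8, DPT = 0.3, FT = 0),
                             biopsy_size = 4) {
  stopifnot(inherits(config, "scene_config"))
  if (any(class_counts < 1)) config_error("need at least one site per requested class")
  unknown <- setdiff(names(class_counts), names(config$reflectivity_by_class))
  if (length(unknown))
    config_error(sprintf("class(es) %s have no reflectivity entry",
                         paste(unknown, collapse = ", ")))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)

  dermal_range <- list(H = c(0, 0), SPT = c(10, 59), DPT = c(61, 89),
                       FT = c(91, 100))
  reepi_range  <- list(H = c(100, 100), SPT = c(75, 98), DPT = c(45, 90),
                       FT = c(5, 50))
  cubes <- list(); k <- 0L
  for (cl in names(class_counts)) {
    dr <- dermal_range[[cl]] %||% c(0, 0)
    rr <- reepi_range[[cl]] %||% c(0, 100)
    pfr <- if (cl %in% names(fr_prob)) fr_prob[[cl]] else 0
    for (s in seq_len(class_counts[[cl]])) {
      k <- k + 1L
      dermal <- if (dr[1] == dr[2]) dr[1] else stats::runif(1, dr[1], dr[2])
      reepi <- if (stats::runif(1) < pfr) 100 else stats::runif(1, rr[1], rr[2])
      etio <- if (cl == "H") "healthy" else sample(c("scald", "contact"), 1)
      lab <- site_label(sprintf("%s%02d", cl, s), etio, dermal, reepi)
      biopsy <- NULL
      if (cl != "H" && biopsy_size > 0 &&
          config$nx > biopsy_size && config$ny > biopsy_size) {
        r0 <- sample.int(config$nx - biopsy_size + 1L, 1L)
        c0 <- sample.int(config$ny - biopsy_size + 1L, 1L)
        biopsy <- list(rows = r0:(r0 + biopsy_size - 1L),
                       cols = c0:(c0 + biopsy_size - 1L))
      }
      cubes[[k]] <- generate_site_cube(config, lab, biopsy, class = cl)
    }
  }
  air <- generate_air_reference(config)
  list(cubes = cubes, air = air, config = config)
}

#' @rdname generate_dataset
#' @export
generate_air_reference <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  sigma <- ricker_sigma(config$pulse_width)
  t <- config$dt * (0:(config$n_samples - 1))
  samp <- config$a1 * ricker(t - config$tau1, sigma)
  if (is.finite(config$snr_db)) {
    sd_n <- sqrt(mean(samp^2)) * 10^(-(config$snr_db + 20) / 20)
    samp <- samp + stats::rnorm(length(samp), sd = sd_n)
  }
  waveform_trace(samp, dt = config$dt, t0 = 0)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
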