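# Signal conditioning: band-pass, alignment, biopsy rejection, gating, ROIs.

# n * dt = 100 ps, so tones at multiples of 0.01 THz occupy a single DFT bin
tone_trace <- function(f_thz, dt = 0.05, n = 2000) {
  waveform_trace(sin(2 * pi * f_thz * dt * (0:(n - 1))), dt = dt)
}

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  tr <- tone_trace(0.5)
  out <- bandpass(tr, 0.1, 1.0)
  expect_equal(max(abs(out$samples)), max(abs(tr$samples)), tolerance = 0.01)
  hi <- bandpass(tone_trace(2.0), 0.1, 1.0)
  expect_lt(max(abs(hi$samples)), 0.01 * max(abs(tone_trace(2)$samples)))
  expect_error(bandpass(tr, 0.1, 11), class = "thzburn_config_error")
  expect_error(bandpass(tr, -1, 0.5), class = "thzburn_config_error")
})

test_that("alignment recovers a planted global shift against a reference template", {
  sc <- demo_scene(snr_db = Inf, drift_max = 0, nx = 5, ny = 5)
  air <- generate_air_reference(sc)
  cube <- generate_site_cube(sc, site_label("s", "scald", 95, 0),
                             class = "FT", seed = 1)
  n <- dim(cube$traces)[3]
  shift_by <- function(cb, s) {                 # delay every trace by s samples
    idx <- ((0:(n - 1)) - s) %% n + 1
    cb$traces <- cb$traces[, , idx, drop = FALSE]
    cb
  }
  al <- align_cube(shift_by(cube, 7), sc$tau1 + c(-6, 6), template = air)
  expect_true(all(al$shifts == -7))
  # already aligned: all shifts zero
  al0 <- align_cube(cube, sc$tau1 + c(-6, 6), template = air)
  expect_true(all(al0$shifts == 0))
  # aligned output equals the unshifted cube
  expect_equal(al$cube$traces, cube$traces)
})

test_that("alignment inverts the generator's drift exactly at 30 dB SNR", {
  sc <- demo_scene()   # snr_db = 30, drift_max = 5
  air <- generate_air_reference(sc)
  for (s in 1:3) {
    cube <- generate_site_cube(sc, site_label("s", "contact", 70, 50),
                               class = "DPT", seed = s)
    al <- align_cube(cube, sc$tau1 + c(-6, 6), template = air)
    expect_true(all(al$shifts == -attr(cube, "drift")))
    expect_lte(max(abs(al$shifts)), sc$drift_max)
  }
})

test_that("a flat first-reflection gate marks the pixel invalid", {
  sc <- demo_scene(snr_db = Inf, drift_max = 0, nx = 4, ny = 4)
  cube <- generate_site_cube(sc, site_label("s", "healthy", 0, 100),
                             class = "H", seed = 1)
  cube$traces[2, 3, ] <- 0
  al <- align_cube(cube, sc$tau1 + c(-6, 6),
                   template = generate_air_reference(sc))
  expect_false(al$cube$valid_mask[2, 3])
})

test_that("biopsy detection recovers the planted block exactly and is threshold-stable", {
  lab <- site_label("s", "scald", 95, 10)
  region <- list(rows = 10:13, cols = 15:18)
  gate <- NULL
  flagged_at <- function(fp_amp, seed = 4) {
    sc <- demo_scene(fp_amp = fp_amp)
    cube <- generate_site_cube(sc, lab, biopsy_region = region,
                               class = "FT", seed = seed)
    al <- align_cube(cube, sc$tau1 + c(-6, 6),
                     template = generate_air_reference(sc))
    out <- detect_invalid_pixels(bandpass_cube(al$cube, 0.1, 1),
                                 sc$tau2 + sc$fp_delay + c(-2.5, 2.5),
                                 k_mad = 5)
    attr(out, "flagged")
  }
  truth <- matrix(FALSE, 27, 27); truth[region$rows, region$cols] <- TRUE
  expect_identical(flagged_at(0.5), truth)
  # stronger echoes flag the same set once above threshold
  expect_identical(flagged_at(1.0), truth)
  expect_identical(flagged_at(2.0), truth)
})

test_that("noise-free cube with no biopsy keeps only corner pixels invalid", {
  sc <- demo_scene(snr_db = Inf, drift_max = 0, nx = 8, ny = 8)
  cube <- generate_site_cube(sc, site_label("s", "healthy", 0, 100),
                             class = "H", seed = 1)
  out <- detect_invalid_pixels(cube, sc$tau2 + sc$fp_delay + c(-2.5, 2.5))
  expect_equal(sum(!out$valid_mask), 4L)
  expect_false(any(attr(out, "flagged")))
  expect_error(detect_invalid_pixels(cube, c(100, 110)),
               class = "thzburn_config_error")
})

test_that("the Blackman gate crops to a fixed width and weights pointwise", {
  # 25-ps width at dt = 0.01 ps: exactly 2500 samples
  n <- 4096
  samp <- numeric(n)
  center <- 2000
  samp[center + (-150:150)] <- thzburn:::ricker(0.01 * (-150:150), 0.5)
  tr <- waveform_trace(samp, dt = 0.01)
  g <- gate_tissue_reflection(tr, gate_spec(width = 25))
  expect_length(g$samples, 2500)
  # trace zero outside the gate: output is the window-weighted input
  idx <- (center - 2500 %/% 2 + 1):(center + 2500 %/% 2)
  expect_equal(g$samples, samp[idx] * thzburn:::blackman_window(2500))
})

test_that("peak-centered gating is translation invariant and idempotent", {
  pulse <- thzburn:::ricker(0.05 * (-100:100), 1)
  mk <- function(center, n = 1024) {
    s <- numeric(n); s[center + (-100:100)] <- pulse
    waveform_trace(s, dt = 0.05)
  }
  spec <- gate_spec(width = 20)
  g1 <- gate_tissue_reflection(mk(300), spec)
  g2 <- gate_tissue_reflection(mk(650), spec)
  expect_equal(g1$samples, g2$samples)
  # idempotence: regating with the same spec is a no-op
  expect_identical(gate_tissue_reflection(g1, spec), g1)
  # truncation at the boundary is an error
  expect_error(gate_tissue_reflection(mk(150), spec),
               class = "thzburn_gating_error")
})

test_that("ROI extraction tiles, drops contaminated blocks, and averages", {
  n <- 64
  arr <- array(rnorm(25 * 25 * n), dim = c(25, 25, n))
  cube <- thz_cube(arr, dt = 0.05,
                   label = site_label("s", "healthy", 0, 100))
  obs <- extract_roi_observations(cube, 5)
  expect_length(obs, 25)
  expect_lte(length(obs), floor(25 / 5)^2)
  # hand-check one block mean
  b <- obs[[1]]
  expect_equal(b$mean_trace$samples,
               colMeans(matrix(arr[1:5, 1:5, ], 25, n)))
  # any invalid pixel drops its block
  cube$valid_mask[7, 3] <- FALSE
  expect_length(extract_roi_observations(cube, 5), 24)
  # identical traces average to themselves
  arr2 <- array(rep(arr[1, 1, ], each = 25), dim = c(5, 5, n))
  cube2 <- thz_cube(arr2, dt = 0.05)
  expect_equal(extract_roi_observations(cube2, 5)[[1]]$mean_trace$samples,
               arr[1, 1, ])
  expect_error(extract_roi_observations(cube2, 6),
               class = "thzburn_config_error")
})
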