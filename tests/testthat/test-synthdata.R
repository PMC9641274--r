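# Synthetic THz-TDS scene generator.

spectral_peak_thz <- function(trace, pad = 8) {
  n <- length(trace$samples) * pad
  amp <- Mod(fft(c(trace$samples, rep(0, n - length(trace$samples)))))
  half <- 1:(n %/% 2)
  (half[which.max(amp[half])] - 1) / (n * trace$dt)
}

test_that("the generated pulse is unit-peak, DC-free and in-band", {
  sc <- demo_scene()
  p <- generate_pulse(sc)
  expect_equal(max(p$samples), 1)
  expect_equal(time_axis(p)[which.max(p$samples)], 0)
  expect_lt(abs(sum(p$samples)) / sum(abs(p$samples)), 1e-9)
  pk <- spectral_peak_thz(p)
  expect_gt(pk, 0.1); expect_lt(pk, 1.0)
})

test_that("halving the pulse width doubles the spectral peak frequency", {
  f1 <- spectral_peak_thz(generate_pulse(demo_scene(pulse_width = 2)), pad = 32)
  f2 <- spectral_peak_thz(generate_pulse(demo_scene(pulse_width = 1)), pad = 32)
  expect_equal(f2 / f1, 2, tolerance = 0.05)
})

test_that("scene configuration is validated", {
  expect_error(scene_config(dt = 0), class = "thzburn_config_error")
  expect_error(scene_config(n_samples = 32), class = "thzburn_config_error")
  expect_error(scene_config(tau1 = 30, tau2 = 28),
               class = "thzburn_config_error")
  expect_error(scene_config(tau2 = 80, n_samples = 8192),
               class = "thzburn_config_error")  # echo past the trace end
  expect_error(scene_config(reflectivity_by_class = list(H = c(rho = 1))),
               class = "thzburn_config_error")
})

test_that("without noise, drift or biopsy, every pixel trace is identical", {
  sc <- demo_scene(snr_db = Inf, drift_max = 0, nx = 6, ny = 6)
  cube <- generate_site_cube(sc, site_label("s", "healthy", 0, 100),
                             class = "H", seed = 1)
  base <- cube$traces[1, 1, ]
  for (i in 1:6) for (j in 1:6)
    expect_identical(cube$traces[i, j, ], base)
  expect_equal(sum(!cube$valid_mask), 4L)   # only the corners are masked
})

test_that("biopsy pixels carry extra post-pulse Fabry-Perot energy", {
  sc <- demo_scene(nx = 10, ny = 10)
  cube <- generate_site_cube(sc, site_label("s", "scald", 95, 10),
                             biopsy_region = list(rows = 3:6, cols = 4:7),
                             class = "FT", seed = 2)
  idx <- round((sc$tau2 + sc$fp_delay + c(-2.5, 2.5)) / sc$dt)
  gate <- (idx[1]:idx[2]) + 1
  energy <- apply(cube$traces[, , gate], c(1, 2), function(v) sum(v^2))
  bm <- attr(cube, "biopsy_mask")
  expect_gt(min(energy[bm]), max(energy[!bm]))
})

test_that("dataset generation is bit-reproducible under a fixed seed", {
  sc <- demo_scene(nx = 8, ny = 8)
  d1 <- generate_dataset(sc, c(H = 1, FT = 1), seed = 99)
  d2 <- generate_dataset(sc, c(H = 1, FT = 1), seed = 99)
  expect_identical(d1$cubes, d2$cubes)
  expect_identical(d1$air$samples, d2$air$samples)
  d3 <- generate_dataset(sc, c(H = 1, FT = 1), seed = 100)
  expect_false(identical(d1$cubes, d3$cubes))
})

test_that("site labels fall in their class threshold intervals and healing tracks severity", {
  sc <- demo_scene(nx = 8, ny = 8)
  ds <- generate_dataset(sc, c(H = 3, SPT = 3, DPT = 3, FT = 3), seed = 5,
                         biopsy_size = 0)
  meta <- do.call(rbind, lapply(ds$cubes, function(cb) {
    cl <- assign_labels(cb$label)
    data.frame(class = attr(cb, "class_name"), severity = cl$severity,
               healing = cl$healing, reepi = cb$label$reepi_pct_day28)
  }))
  expect_identical(meta$severity, meta$class)
  expect_true(all(meta$healing[meta$class == "H"] == "FR"))
  expect_true(all(meta$healing[meta$class == "FT"] == "NPR"))
  expect_true(mean(meta$reepi[meta$class %in% c("H", "SPT")]) >
              mean(meta$reepi[meta$class %in% c("DPT", "FT")]))
})

test_that("a 25x25 grid tiles into 25 ROIs per cube before masking", {
  sc <- demo_scene(nx = 25, ny = 25, n_samples = 256, tau2 = 18,
                   fp_delay = 5)
  ds <- generate_dataset(sc, c(H = 2, SPT = 2, DPT = 2, FT = 2), seed = 3,
                         biopsy_size = 0)
  expect_length(ds$cubes, 8)
  for (cb in ds$cubes) {
    cb$valid_mask[] <- TRUE              # "before masking"
    expect_length(extract_roi_observations(cb, 5), 25)
  }
})
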