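# Shared study-condition profiles for the tests.
#
# demo_scene(): a reduced acquisition profile (dt = 0.1 ps, 512 samples,
# Nyquist 5 THz) used wherever the full 0.01-ps profile would be
# needlessly slow.  tau2 = 28.05 places the tissue-reflection peak away
# from a sample-grid tie so the peak-centered gate lands on the same
# sample at every site.
demo_scene <- function(reflectivity = NULL, ...) {
  args <- utils::modifyList(list(dt = 0.1, n_samples = 512, tau2 = 28.05),
                            list(...))
  if (!is.null(reflectivity)) args$reflectivity_by_class <- reflectivity
  do.call(scene_config, args)
}

# Two-class reflectivity maps: a strong spectral-tilt contrast, and a null
# pair whose responses are practically identical (ESER is insensitive to
# the 1e-4 rho difference, which only exists to keep the ladder ordered).
strong_pair <- list(A = c(rho = 0.45, beta = 0.3),
                    B = c(rho = 0.60, beta = 4.5))
null_pair <- list(A = c(rho = 0.5, beta = 1),
                  B = c(rho = 0.5001, beta = 1))

# Condition every cube of a generated dataset and return the pooled ROI
# observations.
condition_dataset <- function(ds) {
  sc <- ds$config
  obs <- list()
  for (cube in ds$cubes) {
    cc <- condition_cube(cube, air = ds$air,
                         first_gate = sc$tau1 + c(-6, 6),
                         post_pulse_gate = sc$tau2 + sc$fp_delay + c(-2.5, 2.5),
                         tissue_search = sc$tau2 + c(-5, 5))
    obs <- c(obs, cc$observations)
  }
  obs
}

# Demo-profile two-class feature set: level-8 ESER features over the
# sub-bands covering 0.1-1 THz, labels FR (class A) vs NPR (class B).
demo_binary_features <- function(reflectivity, seed, sites_per_class = 5) {
  sc <- demo_scene(reflectivity)
  counts <- c(A = sites_per_class, B = sites_per_class)
  ds <- generate_dataset(sc, class_counts = counts, seed = seed,
                         fr_prob = c(A = 1, B = 0), biopsy_size = 0)
  obs <- condition_dataset(ds)
  sb <- select_subbands(8, sc$dt, 0.1, 1.0)
  fx <- eser_features(obs, condition_air(ds$air), "db1", 8, subbands = sb)
  list(x = fx, y = attr(fx, "meta")$healing, scene = sc)
}

small_grid <- function() {
  tuning_grid(kernels = "gaussian", kernel_scale = c(0.5, 2, 8),
              box_constraint = c(1, 10), wavelets = "db1", levels = 8)
}
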