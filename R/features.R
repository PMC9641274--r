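#' ESER feature matrix for a set of observations
#'
#' Computes the deconvolved ESER features of each region-of-interest
#' observation: the gated mean trace is decomposed with [modwpt()] at the
#' requested wavelet and level, the ESER of the in-band sub-bands is taken,
#' and each coefficient is divided by the ESER of the identically
#' conditioned air reference to cancel the instrument response.
#'
#' @param observations list of `roi_observation` objects from
#'   [extract_roi_observations()] / [condition_cube()].
#' @param air the conditioned air reference (see [condition_air()]); must
#'   share the observations' sampling step and length.
#' @param wavelet Daubechies wavelet name (default `"db1"`).
#' @param level decomposition level (default 12).
#' @param subbands sub-band indices; by default, sub-bands 10-80 when the
#'   level-12/50-THz-Nyquist correspondence applies, otherwise all sub-bands
#'   overlapping 0.1-1 THz.
#' @return A numeric matrix (observations x sub-bands, columns `n10`, `n11`,
#'   ...), with attributes `wavelet`, `level`, `subbands` and `meta` (a
#'   data frame of per-observation identifiers and labels).
#' @export
eser_features <- function(observations, air, wavelet = "db1", level = 12,
                          subbands = NULL) {
  if (length(observations) == 0) config_error("no observations supplied")
  stopifnot(inherits(air, "waveform_trace"))
  dt <- observations[[1]]$mean_trace$dt
  if (length(air$samples) != length(observations[[1]]$mean_trace$samples))
    config_error("air reference and observations differ in length; condition them identically")
  if (is.null(subbands)) {
    subbands <- if (level == 12 && isTRUE(all.equal(dt, 0.01))) 10:80
                else select_subbands(level, dt, 0.1, 1.0)
  }
  air_eser <- eser_vector(modwpt(air, wavelet, level, subbands))
  feats <- t(vapply(observations, function(ob) {
    ev <- eser_vector(modwpt(ob$mean_trace, wavelet, level, subbands))
    deconvolve_reference(ev, air_eser)$eser
  }, numeric(length(subbands))))
  colnames(feats) <- paste0("n", subbands)
  meta <- observation_meta(observations)
  structure(feats, wavelet = wavelet, level = level, subbands = subbands,
            meta = meta)
}

#' @rdname eser_features
#' @param wavelets,levels vectors of combinations to precompute.
#' @return `eser_feature_set()` returns a named list of feature matrices
#'   keyed by [feature_key()], directly usable as the `x` of [burn_svm()].
#' @export
eser_feature_set <- function(observations, air, wavelets = "db1",
                             levels = 12, subbands = NULL) {
  out <- list()
  for (w in wavelets) for (l in levels)
    out[[feature_key(w, l)]] <-
      eser_features(observations, air, w, l, subbands)
  out
}

#' Observation metadata and class labels
#'
#' @param observations list of `roi_observation` objects.
#' @param scheme a [label_scheme()].
#' @return A data frame with `roi_id`, `site_id`, `etiology`,
#'   `dermal_burn_pct`, `reepi_pct_day28`, and the derived `severity` and
#'   `healing` factors.
#' @export
observation_meta <- function(observations, scheme = label_scheme()) {
  rows <- lapply(observations, function(ob) {
    lab <- ob$label
    cls <- assign_labels(lab, scheme)
    data.frame(roi_id = ob$roi_id, site_id = ob$site_id,
               etiology = lab$etiology,
               dermal_burn_pct = lab$dermal_burn_pct,
               reepi_pct_day28 = lab$reepi_pct_day28,
               severity = cls$severity, healing = cls$healing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$severity <- factor(out$severity, levels = c("H", "SPT", "DPT", "FT"))
  out$healing <- factor(out$healing, levels = c("FR", "NPR"))
  out
}
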