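#' @name eser
#' @title Energy-to-Shannon-entropy-ratio (ESER) features
#'
#' @description
#' The classification feature for each wavelet packet sub-band is the ratio of
#' its energy proportion to its Shannon entropy.  For sub-band coefficients
#' \eqn{\tilde W_{J,n}(t)} of a trace \eqn{X}:
#' \itemize{
#'   \item normalized energy distribution
#'     \eqn{P(t) = |\tilde W_{J,n}(t)|^2 / \sum_t |\tilde W_{J,n}(t)|^2};
#'   \item Shannon entropy \eqn{H = -\sum_t P(t) \log P(t)} (natural log,
#'     with \eqn{0 \log 0 = 0});
#'   \item energy ratio
#'     \eqn{E = \sum_t |\tilde W_{J,n}(t)|^2 / \sum_t |X(t)|^2};
#'   \item \eqn{\mathrm{ESER}_n = E / H}.
#' }
#' Both \eqn{E} and \eqn{P} are invariant to rescaling the input trace, so
#' the ESER features carry spectral-shape information, not absolute
#' reflectivity.  Sub-bands whose energy is below `1e-12` of the input energy
#' are treated as degenerate: `P` is undefined there, so `H` and the ESER are
#' set to 0 and the sub-band is flagged.
NULL

#' @describeIn eser Normalized energy distribution of one sub-band's
#'   coefficients. Returns a probability vector (non-negative, sums to 1).
#' @param w numeric vector of sub-band coefficients.
#' @export
subband_probability <- function(w) {
  e <- sum(w^2)
  if (e <= 0) degenerate_error("sub-band has zero energy; P(t) is undefined")
  w^2 / e
}

#' @describeIn eser Shannon entropy (nats by default) of a probability
#'   vector, with the `0 log 0 = 0` convention.
#' @param p probability vector.
#' @param base logarithm base; `exp(1)` gives nats.
#' @export
subband_entropy <- function(p, base = exp(1)) {
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    config_error("'p' must be a probability vector summing to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

#' @describeIn eser Energy of one sub-band as a proportion of the input
#'   trace energy.
#' @param input_energy energy of the trace fed to the transform.
#' @export
subband_energy_ratio <- function(w, input_energy) {
  if (!is.finite(input_energy) || input_energy <= 0)
    degenerate_error("input trace has zero energy")
  sum(w^2) / input_energy
}

#' ESER vector of selected sub-bands
#'
#' Computes per-sub-band energy ratio, Shannon entropy and their ratio from a
#' [modwpt()] packet table.
#'
#' @param table a `packet_table` from [modwpt()].
#' @param subbands sub-band indices to evaluate; default: all present in the
#'   table.
#' @param base entropy logarithm base (nats by default; the deconvolved
#'   features are invariant to this choice).
#' @param degenerate_tol sub-bands with energy below `degenerate_tol *
#'   input_energy` are flagged and given `H = 0`, `eser = 0`.
#' @return An object of class `eser_vector`: a data frame with columns
#'   `subband`, `energy_ratio`, `entropy`, `eser`, `degenerate`, plus
#'   attributes `level`, `wavelet`, `deconvolved`, `reference_id`.
#' @examples
#' pt <- modwpt(rep(1, 32), "db1", 3)
#' ev <- eser_vector(pt)
#' ev$eser[1] * log(32)   # constant trace: ESER = 1/log(N) in sub-band 0
#' @export
eser_vector <- function(table, subbands = NULL, base = exp(1),
                        degenerate_tol = 1e-12) {
  stopifnot(inherits(table, "packet_table"))
  if (is.null(subbands)) subbands <- table$subbands
  missing_n <- setdiff(subbands, table$subbands)
  if (length(missing_n))
    config_error(sprintf("sub-band(s) %s not present in the packet table",
                         paste(missing_n, collapse = ", ")))
  if (table$input_energy <= 0)
    degenerate_error("input trace has zero energy")
  rows <- lapply(subbands, function(n) {
    w <- table$coef[as.character(n), ]
    e <- sum(w^2)
    ratio <- e / table$input_energy
    if (e < degenerate_tol * table$input_energy) {
      data.frame(subband = n, energy_ratio = ratio, entropy = 0,
                 eser = 0, degenerate = TRUE)
    } else {
      H <- subband_entropy(subband_probability(w), base = base)
      data.frame(subband = n, energy_ratio = ratio, entropy = H,
                 eser = if (H > 0) ratio / H else 0, degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("eser_vector", "data.frame"),
            level = table$level, wavelet = table$wavelet,
            deconvolved = FALSE, reference_id = NULL)
}

#' Deconvolve the instrument response with an air reference
#'
#' Divides the tissue ESER coefficients by the ESER coefficients of an
#' identically conditioned air/mirror reference measurement, cancelling the
#' spectral signature of the instrument (and, with it, the entropy log base).
#'
#' @param tissue,air `eser_vector` objects over the same sub-bands, wavelet
#'   and level.
#' @param reference_id identifier stored on the result.
#' @return The deconvolved `eser_vector`.
#' @export
deconvolve_reference <- function(tissue, air, reference_id = "air") {
  stopifnot(inherits(tissue, "eser_vector"), inherits(air, "eser_vector"))
  if (!identical(tissue$subband, air$subband) ||
      !identical(attr(tissue, "level"), attr(air, "level")) ||
      !identical(attr(tissue, "wavelet"), attr(air, "wavelet")))
    config_error("tissue and air ESER vectors use different sub-bands, wavelet or level")
  bad <- air$subband[air$degenerate | air$eser == 0]
  if (length(bad))
    reference_error(sprintf(
      "air reference is degenerate at sub-band(s) %s; cannot deconvolve",
      paste(bad, collapse = ", ")))
  out <- tissue
  out$eser <- tissue$eser / air$eser
  attr(out, "deconvolved") <- TRUE
  attr(out, "reference_id") <- reference_id
  out
}

#' @export
print.eser_vector <- function(x, ...) {
  cat(sprintf("<eser_vector> %s level %d, %d sub-bands%s\n",
              attr(x, "wavelet"), attr(x, "level"), nrow(x),
              if (isTRUE(attr(x, "deconvolved")))
                sprintf(", deconvolved by '%s'", attr(x, "reference_id"))
              else ""))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat(sprintf("  ... %d more sub-bands\n", nrow(x) - 8))
  invisible(x)
}
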