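#' Daubechies filters with maximal-overlap normalization
#'
#' Returns the scaling and wavelet filter pair of the Daubechies wavelet with
#' `vanishing_moments` vanishing moments (the extremal-phase family db1-db10),
#' rescaled by 1/sqrt(2) as required by the maximal-overlap (undecimated)
#' transforms.  With this normalization the scaling filter sums to 1, the
#' wavelet filter sums to 0, and the two squared norms sum to 1, which is what
#' makes the undecimated packet tree conserve energy exactly.
#'
#' The coefficients are computed by spectral factorization of the Daubechies
#' half-band polynomial: the binomial polynomial
#' \eqn{P(y) = \sum_{k=0}^{p-1} \binom{p-1+k}{k} y^k} is rooted, each root is
#' mapped to its minimum-modulus zero in the z-plane, and the minimal-phase
#' factor is assembled with `(1+z)^p`.  Roots are Newton-polished so the
#' orthonormality identities hold to machine precision.  The wavelet filter
#' follows from the quadrature-mirror relation
#' \eqn{\tilde h(k) = (-1)^k \tilde g(L-1-k)}.
#'
#' @param vanishing_moments integer between 1 and 10 (db1 ... db10).
#' @return A list with elements `g` (scaling filter), `h` (wavelet filter),
#'   both of length `2 * vanishing_moments`, and `name` (e.g. `"db4"`).
#' @examples
#' f <- daubechies_filters(1)   # Haar: g = (1/2, 1/2), h = (1/2, -1/2)
#' sum(f$g); sum(f$h)
#' @export
daubechies_filters <- function(vanishing_moments) {
  p <- vanishing_moments
  if (!is.numeric(p) || length(p) != 1L || p != round(p) || p < 1 || p > 10)
    config_error("'vanishing_moments' must be an integer in 1..10")
  p <- as.integer(p)
  g <- daub_scaling_orthonormal(p) / sqrt(2)
  L <- 2L * p
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g, h = h, name = paste0("db", p))
}

# Orthonormal Daubechies scaling filter (sums to sqrt(2)), extremal phase.
daub_scaling_orthonormal <- function(p) {
  if (p == 1L) return(c(1, 1) / sqrt(2))
  # Half-band polynomial P(y) = sum_{k=0}^{p-1} C(p-1+k, k) y^k
  a <- choose(p - 1 + 0:(p - 1), 0:(p - 1))
  r <- polyroot(a)                 # coefficients in increasing order
  r <- vapply(r, function(y) newton_polish(a, y), complex(1))
  # Map each y-root to the z-plane: y = (2 - z - 1/z)/4  =>
  # z^2 - (2 - 4y) z + 1 = 0; keep the root inside the unit circle.
  zin <- vapply(r, function(y) {
    b <- 2 - 4 * y
    d <- sqrt(b^2 - 4 + 0i)
    z1 <- (b + d) / 2; z2 <- (b - d) / 2
    if (Mod(z1) < Mod(z2)) z1 else z2
  }, complex(1))
  # Assemble (1+z)^p * prod (z - z_i), combining conjugate pairs so the
  # convolution stays real.
  coefs <- 1
  for (k in seq_len(p)) coefs <- convolve_poly(coefs, c(1, 1))
  used <- rep(FALSE, length(zin))
  for (i in seq_along(zin)) {
    if (used[i]) next
    zi <- zin[i]
    if (abs(Im(zi)) < 1e-10) {
      coefs <- convolve_poly(coefs, c(-Re(zi), 1))
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(zin - Conj(zi)) < 1e-6 & seq_along(zin) != i)[1]
      if (is.na(j)) config_error("failed to pair complex roots in spectral factorization")
      coefs <- convolve_poly(coefs, c(Mod(zi)^2, -2 * Re(zi), 1))
      used[c(i, j)] <- TRUE
    }
  }
  h <- coefs * sqrt(2) / sum(coefs)
  # Extremal-phase convention: energy concentrated at the front of the filter
  # (energy centroid in the first half).
  centroid <- sum((seq_along(h) - 1) * h^2) / sum(h^2)
  if (centroid <= (length(h) - 1) / 2) h else rev(h)
}

newton_polish <- function(a, y, iters = 30L) {
  n <- length(a) - 1L
  for (it in seq_len(iters)) {
    pv <- 0i; dv <- 0i
    for (k in n:0) {                       # Horner for P and P'
      dv <- dv * y + pv
      pv <- pv * y + a[k + 1L]
    }
    if (Mod(dv) == 0) break
    step <- pv / dv
    y <- y - step
    if (Mod(step) < 1e-15 * max(1, Mod(y))) break
  }
  y
}

convolve_poly <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}
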