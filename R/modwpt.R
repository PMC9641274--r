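#' Maximal-overlap discrete wavelet packet transform
#'
#' Decomposes a 1-D trace into `2^level` sequency-ordered sub-bands of equal
#' nominal bandwidth.  The transform is undecimated: every sub-band holds as
#' many coefficients as the input has samples, so the level-J table carries
#' `2^J * N` coefficients.  Filtering is circular (periodic), the standard
#' maximal-overlap convention, which makes the full tree conserve energy
#' exactly.
#'
#' The packet recursion is
#' \deqn{\tilde W_{j,n}(t) = \sum_k \tilde u(k)\, \tilde W_{j-1,\lfloor n/2
#' \rfloor}\big((t - 2^{j-1}k) \bmod N\big),}
#' where \eqn{\tilde u} is the scaling filter \eqn{\tilde g} when
#' \eqn{n \bmod 4 \in \{0, 3\}} and the wavelet filter \eqn{\tilde h} when
#' \eqn{n \bmod 4 \in \{1, 2\}}.  This filter-selection rule yields sub-bands
#' directly in sequency order: sub-band `n` has nominal passband
#' `[n, n+1] * f_Nyquist / 2^level`.
#'
#' When `subbands` names only part of the tree, only branches ancestral to the
#' requested terminal sub-bands are evaluated (pruned evaluation); the
#' returned rows are identical to the corresponding rows of a full-tree
#' evaluation.
#'
#' @param x a [waveform_trace()] or numeric vector.
#' @param wavelet Daubechies wavelet name `"db1"` ... `"db10"`, or the number
#'   of vanishing moments.
#' @param level decomposition level J (>= 1).
#' @param subbands `"all"`, or an integer vector of terminal sub-band indices
#'   in `0:(2^level - 1)` (sequency order).
#' @return An object of class `packet_table`: a list with `coef` (matrix,
#'   one row per requested sub-band, `N` columns), `subbands`, `level`,
#'   `wavelet`, `input_energy`, and the time axis metadata `dt`, `t0`.
#' @examples
#' w <- modwpt(sin(2 * pi * (0:63) / 8), wavelet = "db2", level = 3)
#' rowSums(w$coef^2) / w$input_energy   # sub-band energy split
#' @export
modwpt <- function(x, wavelet = "db1", level, subbands = "all") {
  J <- level
  if (!is.numeric(J) || length(J) != 1L || J != round(J) || J < 1)
    config_error("'level' must be a positive integer")
  J <- as.integer(J)
  filt <- resolve_wavelet(wavelet)
  samp <- as_trace_samples(x)
  N <- length(samp)
  nmax <- 2^J - 1
  if (identical(subbands, "all")) {
    wanted <- 0:nmax
  } else {
    wanted <- as.integer(subbands)
    if (length(wanted) == 0L || any(wanted < 0 | wanted > nmax))
      config_error(sprintf("'subbands' must lie in 0..%d at level %d", nmax, J))
    wanted <- sort(unique(wanted))
  }
  g <- filt$g; h <- filt$h; L <- length(g)

  # Pruned breadth-first pass: at level j only nodes ancestral to a wanted
  # terminal sub-band are kept.  Nodes are stored in a named list keyed by n.
  current <- list(`0` = samp)
  for (j in seq_len(J)) {
    need <- sort(unique(wanted %/% 2^(J - j)))
    shift <- (2^(j - 1) * (0:(L - 1))) %% N
    nxt <- vector("list", length(need))
    names(nxt) <- as.character(need)
    for (n in need) {
      parent <- current[[as.character(n %/% 2L)]]
      u <- if (n %% 4L %in% c(0L, 3L)) g else h
      acc <- numeric(N)
      for (k in seq_len(L)) {
        s <- shift[k]
        acc <- acc + u[k] *
          (if (s == 0) parent else c(parent[(N - s + 1):N], parent[1:(N - s)]))
      }
      nxt[[as.character(n)]] <- acc
    }
    current <- nxt
  }
  coef <- do.call(rbind, current[as.character(wanted)])
  rownames(coef) <- as.character(wanted)
  structure(list(coef = coef, subbands = wanted, level = J,
                 wavelet = filt$name, input_energy = sum(samp^2),
                 dt = if (inherits(x, "waveform_trace")) x$dt else NA_real_,
                 t0 = if (inherits(x, "waveform_trace")) x$t0 else NA_real_),
            class = "packet_table")
}

#' @export
print.packet_table <- function(x, ...) {
  cat(sprintf("<packet_table> %s, level %d: %d of %d sub-bands, %d coefficients each\n",
              x$wavelet, x$level, length(x$subbands), 2^x$level, ncol(x$coef)))
  invisible(x)
}

resolve_wavelet <- function(wavelet) {
  if (is.numeric(wavelet)) return(daubechies_filters(wavelet))
  if (is.character(wavelet) && length(wavelet) == 1L &&
      grepl("^db([1-9]|10)$", wavelet))
    return(daubechies_filters(as.integer(sub("^db", "", wavelet))))
  if (is.list(wavelet) && all(c("g", "h") %in% names(wavelet)))
    return(wavelet)
  config_error("'wavelet' must be \"db1\"..\"db10\" or vanishing moments 1..10")
}

#' Nominal passband of a sequency-ordered sub-band
#'
#' Under sequency ordering, sub-band `n` at level `J` nominally occupies the
#' frequency interval `[n, n+1] * f_Nyquist / 2^J`, where
#' `f_Nyquist = 1 / (2 * dt)`.  With `dt` in picoseconds the result is in THz.
#'
#' @param n sub-band index (vectorised), in `0:(2^level - 1)`.
#' @param level decomposition level J.
#' @param dt sampling step (ps).
#' @return A two-column matrix with columns `f_low`, `f_high` (THz), one row
#'   per element of `n`.
#' @export
subband_passband <- function(n, level, dt) {
  if (any(n != round(n)) || any(n < 0) || any(n > 2^level - 1))
    config_error("sub-band index out of range for this level")
  if (dt <= 0) config_error("'dt' must be positive")
  width <- (1 / (2 * dt)) / 2^level
  cbind(f_low = n * width, f_high = (n + 1) * width)
}

#' Select sub-bands covering a frequency interval
#'
#' Returns the terminal sub-band indices whose nominal passbands overlap the
#' interval `(f_lo, f_hi)` (THz), or `explicit_range` verbatim when given.
#' The explicit form exists because the in-band index range is often quoted
#' directly (e.g. sub-bands 10-80 at level 12 for a 0.1-1 THz measurement
#' band at a 50-THz Nyquist rate).
#'
#' @param level decomposition level J.
#' @param dt sampling step (ps).
#' @param f_lo,f_hi frequency interval bounds (THz).
#' @param explicit_range optional integer vector of indices returned as-is
#'   (after range validation).
#' @return Integer vector of sub-band indices in sequency order.
#' @export
select_subbands <- function(level, dt, f_lo = 0.1, f_hi = 1.0,
                            explicit_range = NULL) {
  nmax <- 2^level - 1
  if (!is.null(explicit_range)) {
    n <- as.integer(explicit_range)
    if (any(n < 0 | n > nmax))
      config_error("explicit sub-band range outside the level's tree")
    return(n)
  }
  nyq <- 1 / (2 * dt)
  if (f_lo >= nyq)
    config_error("requested band lies entirely above the Nyquist frequency")
  if (f_lo >= f_hi || f_lo < 0) config_error("need 0 <= f_lo < f_hi")
  width <- nyq / 2^level
  n <- 0:nmax
  sel <- n[(n + 1) * width > f_lo & n * width < f_hi]
  if (length(sel) == 0L) config_error("empty sub-band selection")
  sel
}
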