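# Independent DFT-domain oracle for the wavelet packet transform: the
# terminal sub-band equals the inverse DFT of the input spectrum multiplied
# by the cascade product of up-sampled filter transfer functions.  This
# never touches the package's time-domain recursion.
modwpt_oracle <- function(x, vanishing_moments, J, n) {
  filt <- daubechies_filters(vanishing_moments)
  N <- length(x)
  Tf <- rep(1 + 0i, N)
  freqs <- 0:(N - 1)
  nn <- n
  for (j in J:1) {
    u <- if ((nn %% 4) %in% c(0, 3)) filt$g else filt$h
    k <- 0:(length(u) - 1)
    U <- vapply(freqs, function(ff)
      sum(u * exp(-2i * pi * 2^(j - 1) * k * ff / N)), complex(1))
    Tf <- Tf * U
    nn <- nn %/% 2
  }
  Re(fft(fft(x) * Tf, inverse = TRUE) / N)
}
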