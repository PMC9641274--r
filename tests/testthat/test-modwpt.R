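# Wavelet packet transform: filters, recursion, bookkeeping.

test_that("Daubechies filter pairs satisfy the maximal-overlap identities", {
  for (p in 1:10) {
    f <- daubechies_filters(p)
    expect_length(f$g, 2 * p)
    expect_equal(sum(f$g), 1, tolerance = 1e-12)
    expect_equal(sum(f$h), 0, tolerance = 1e-12)
    expect_equal(sum(f$g^2) + sum(f$h^2), 1, tolerance = 1e-12)
    # quadrature-mirror relation
    L <- 2 * p
    expect_equal(f$h, (-1)^(0:(L - 1)) * rev(f$g), tolerance = 1e-15)
    # orthonormality of the unscaled filter at even shifts
    g <- f$g * sqrt(2)
    for (m in seq_len(p - 1))
      expect_lt(abs(sum(g[1:(L - 2 * m)] * g[(2 * m + 1):L])), 1e-12)
  }
  expect_equal(daubechies_filters(1)$g, c(0.5, 0.5))
  expect_equal(daubechies_filters(1)$h, c(0.5, -0.5))
  expect_error(daubechies_filters(11), class = "thzburn_config_error")
  expect_error(daubechies_filters(0), class = "thzburn_config_error")
})

test_that("Haar level-1 coefficients match the closed form with circular wrap", {
  set.seed(5)
  x <- rnorm(64)
  w <- modwpt(x, "db1", 1)
  lag1 <- c(x[64], x[-64])
  expect_equal(w$coef["0", ], (x + lag1) / 2, tolerance = 1e-14)
  expect_equal(w$coef["1", ], (x - lag1) / 2, tolerance = 1e-14)
})

test_that("a constant trace puts all energy in sub-band 0", {
  w <- modwpt(rep(2, 32), "db4", 3)
  e <- rowSums(w$coef^2) / w$input_energy
  expect_equal(unname(e["0"]), 1, tolerance = 1e-12)
  expect_lt(max(abs(w$coef[-1, ])), 1e-12)
})

test_that("full-tree sub-band energies conserve the input energy", {
  set.seed(11)
  for (p in c(1, 3, 7, 10)) {
    x <- rnorm(128)
    for (J in c(1, 4, 6)) {
      w <- modwpt(x, p, J)
      expect_equal(sum(w$coef^2), w$input_energy, tolerance = 1e-10)
      expect_equal(nrow(w$coef), 2^J)
    }
  }
})

test_that("cascade transform matches the DFT-domain oracle", {
  set.seed(7)
  x <- rnorm(64)
  for (p in c(1, 2, 4)) {
    J <- 3
    w <- modwpt(x, p, J)
    for (n in 0:(2^J - 1))
      expect_equal(w$coef[as.character(n), ], modwpt_oracle(x, p, J, n),
                   tolerance = 1e-9)
  }
})

test_that("pruned evaluation equals the full-tree rows exactly", {
  set.seed(9)
  x <- rnorm(128)
  wf <- modwpt(x, "db3", 4)
  wp <- modwpt(x, "db3", 4, subbands = c(3, 10, 15))
  for (n in c("3", "10", "15"))
    expect_identical(wp$coef[n, ], wf$coef[n, ])
})

test_that("a tone lands in the sub-band holding its frequency (sequency order)", {
  N <- 256
  for (n in c(0, 5, 9, 14, 15)) {
    fc <- (n + 0.5) * 0.5 / 2^4     # center of sub-band n at unit dt
    tone <- cos(2 * pi * fc * (0:(N - 1)))
    w <- modwpt(tone, "db8", 4)
    expect_equal(w$subbands[which.max(rowSums(w$coef^2))], n)
  }
})

test_that("level-3 decomposition yields eight equal-bandwidth sub-bands", {
  w <- modwpt(rnorm(64), "db2", 3)
  expect_equal(nrow(w$coef), 8L)
  pb <- subband_passband(0:7, 3, dt = 0.01)
  expect_equal(unique(round(pb[, "f_high"] - pb[, "f_low"], 9)), 50 / 8)
})

test_that("sub-band passbands partition the spectrum", {
  expect_equal(as.vector(subband_passband(0, 3, 0.01)), c(0, 6.25))
  # adjacent bands share an edge exactly
  pb <- subband_passband(0:15, 4, 0.05)
  expect_identical(pb[-1, "f_low"], pb[-16, "f_high"])
  # the level-12 in-band range at a 50-THz Nyquist rate
  pb <- subband_passband(c(10, 80), 12, 0.01)
  expect_equal(unname(pb[1, "f_low"]), 0.1220703125)
  expect_equal(unname(pb[2, "f_high"]), 0.98876953125)
  expect_error(subband_passband(8, 3, 0.01), class = "thzburn_config_error")
})

test_that("sub-band selection covers a frequency interval or an explicit range", {
  expect_length(select_subbands(12, 0.01, explicit_range = 10:80), 71)
  sel <- select_subbands(12, 0.01, 0.1, 1.0)
  expect_true(all(10:80 %in% sel))
  expect_error(select_subbands(12, 0.01, 60, 80),
               class = "thzburn_config_error")
  expect_error(select_subbands(3, 0.01, explicit_range = 7:9),
               class = "thzburn_config_error")
})

test_that("transform rejects bad sub-band requests and levels", {
  expect_error(modwpt(rnorm(32), "db1", 0), class = "thzburn_config_error")
  expect_error(modwpt(rnorm(32), "db1", 3, subbands = 8),
               class = "thzburn_config_error")
  expect_error(modwpt(rnorm(32), "db11", 3), class = "thzburn_config_error")
})
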