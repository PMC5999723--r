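test_that("central difference is exact on linear ramps", {
  fs <- 500
  t <- seq(0, 1, by = 1 / fs)
  c0 <- 0.37
  v <- central_diff(c0 * t, fs)
  expect_equal(v[2:(length(v) - 1)], rep(c0, length(v) - 2), tolerance = 1e-9)
  expect_error(central_diff(c(1, 2), fs), "3 samples")
})

test_that("pass-band sine keeps unit gain and zero peak shift", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  y <- lowpass_zerophase(x, fs, cutoff = 20)
  core <- 300:(length(t) - 300)
  # amplitude via projection onto the quadrature pair
  amp <- function(z) {
    s <- sin(2 * pi * 2 * t[core]); c <- cos(2 * pi * 2 * t[core])
    sqrt(mean(z[core] * s * 2)^2 + mean(z[core] * c * 2)^2)
  }
  expect_equal(amp(y) / amp(x), 1, tolerance = 0.01)
  # zero phase: quadrature phase unchanged (a 2-Hz sine has several equal
  # peaks, so compare phases, not argmax indices)
  phase <- function(z) {
    s <- sin(2 * pi * 2 * t[core]); c <- cos(2 * pi * 2 * t[core])
    atan2(mean(z[core] * c), mean(z[core] * s))
  }
  expect_equal(phase(y), phase(x), tolerance = 1e-4)
})

test_that("stop-band attenuation matches the designed squared response", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  f0 <- 100
  x <- sin(2 * pi * f0 * t)
  y <- lowpass_zerophase(x, fs, cutoff = 20, order = 4)
  # oracle: evaluate the designed transfer function at f0, squared (2 passes)
  bf <- signal::butter(4, 20 / (fs / 2))
  z <- exp(-1i * 2 * pi * f0 / fs)
  H1 <- sum(bf$b * z^(0:(length(bf$b) - 1))) /
    sum(bf$a * z^(0:(length(bf$a) - 1)))
  expected <- Mod(H1)^2
  core <- 500:(length(t) - 500)
  s <- sin(2 * pi * f0 * t[core]); cc <- cos(2 * pi * f0 * t[core])
  measured <- sqrt(mean(y[core] * s * 2)^2 + mean(y[core] * cc * 2)^2)
  expect_lt(measured, 1e-4)
  expect_lt(abs(measured - expected), 0.05 * expected)
})

test_that("zero-phase filtering preserves the argmax of symmetric pulses", {
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)
  for (ctr in c(0.7, 1.0, 1.31)) {
    x <- exp(-(t - ctr)^2 / (2 * 0.05^2))
    y <- lowpass_zerophase(x, fs)
    expect_equal(which.max(y), which.max(x))
  }
})

test_that("derive_and_filter rejects non-uniform time bases", {
  t <- c(seq(0, 1, by = 0.002), 1.01)
  n <- length(t)
  tr <- trial_series(seq(0, by = 0.002, length.out = n), rep(0, n), rep(0, n),
                     rep(0, n), rep(0, n), rep(1, n))
  tr$t <- t  # corrupt after construction
  expect_error(derive_and_filter(tr), "non-uniform")
})
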