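test_that("polynomial extremum recovers known argmaxima", {
  # exact inverted parabola: analytic argmax
  x <- seq(3, 8, by = 0.25)
  for (ctr in c(4.2, 5.07, 6.9)) {
    fit <- fit_extremum(x, -(x - ctr)^2, order = 4)
    expect_equal(fit$x_star, ctr, tolerance = 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
  # noiseless quartic with interior argmax; oracle: dense grid evaluation
  co <- c(1, 0.3, 2, -0.1, -0.15)
  y <- drop(outer(x, 0:4, `^`) %*% co)
  g <- seq(min(x), max(x), by = 1e-6)
  oracle <- g[which.max(drop(outer(g, 0:4, `^`) %*% co))]
  fit <- fit_extremum(x, y)
  expect_equal(fit$x_star, oracle, tolerance = 1e-4)
  expect_error(fit_extremum(c(1, 2, 3), c(1, 2, 3)), "distinct")
})

test_that("extrema on the data boundary are flagged", {
  x <- seq(3, 8, by = 0.25)
  fit <- fit_extremum(x, x + 0.001 * x^2)  # monotone: argmax at the edge
  expect_true(fit$boundary)
  expect_equal(fit$x_star, max(x), tolerance = 1e-3)
})

test_that("bootstrap CI degenerates correctly and covers known effects", {
  b <- rnorm(18)
  same <- bootstrap_diff(b, b, reps = 1000, seed = 1)
  expect_equal(c(same$lo, same$hi), c(0, 0))
  expect_false(same$excludes_zero)
  shift <- bootstrap_diff(b + 1, b, reps = 1000, seed = 1)
  expect_equal(c(shift$lo, shift$hi), c(1, 1))
  expect_true(shift$excludes_zero)
  expect_error(bootstrap_diff(1:2, 1:2), "at least 3")
})

test_that("bootstrap percentile CI has near-nominal coverage", {
  # Monte-Carlo oracle: true difference 0.3, n = 18, sd 0.18
  set.seed(42)
  cover <- logical(500)
  for (r in seq_len(500)) {
    a <- rnorm(18, 0.3, 0.18); b <- rnorm(18, 0, 0.18)
    ci <- bootstrap_diff(a, b, reps = 1000, seed = r)
    cover[r] <- ci$lo <= 0.3 && 0.3 <= ci$hi
  }
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 0.99)
})

test_that("hinge regression matches an independent optimizer", {
  set.seed(9)
  x <- seq(3.5, 7.9, by = 0.11)
  y <- 5 + 18 * pmin(x - 5, 0) + 2 * pmax(x - 5, 0) + rnorm(length(x), 0, 1)
  pw <- piecewise_fit(x, y, xb = 5)
  # oracle: direct numeric minimization of the hinge RSS
  rss <- function(p) sum((y - (p[1] + p[2] * pmin(x - 5, 0) +
                                 p[3] * pmax(x - 5, 0)))^2)
  opt <- optim(c(0, 0, 0), rss, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(pw$rss_piecewise), opt$value, tolerance = 1e-6)
  expect_equal(unname(c(pw$intercept, pw$s_lo, pw$s_hi)), opt$par,
               tolerance = 1e-4)
})

test_that("hinge fits recover exact generating slopes and nest the line", {
  x <- seq(3.5, 7.9, by = 0.2)
  # exact hinge, no noise
  y <- 2 + 18 * pmin(x - 5.2, 0) + 0 * pmax(x - 5.2, 0)
  pw <- piecewise_fit(x, y, xb = 5.2)
  expect_equal(unname(pw$s_lo), 18, tolerance = 1e-9)
  expect_equal(unname(pw$s_hi), 0, tolerance = 1e-9)
  expect_lt(pw$rss_piecewise, 1e-18)
  # exact line: both slopes equal the line slope, both RSS ~ 0
  yl <- 1 + 3 * x
  pl <- piecewise_fit(x, yl, xb = 5.2)
  expect_equal(unname(pl$s_lo), 3, tolerance = 1e-9)
  expect_equal(unname(pl$s_hi), 3, tolerance = 1e-9)
  expect_lt(abs(pl$rss_piecewise - pl$rss_linear), 1e-15)
  # nestedness on arbitrary noisy data
  set.seed(1)
  for (r in 1:20) {
    yr <- rnorm(length(x))
    pr <- piecewise_fit(x, yr, xb = 5.2)
    expect_lte(pr$rss_piecewise, pr$rss_linear + 1e-12)
  }
  expect_error(piecewise_fit(x, yl, xb = 10), "each side")
})

test_that("least-squares AIC follows the closed form", {
  expect_equal(aic_ls(10, 10, 2), 10 * log(1) + 2 * 3)
  expect_equal(aic_ls(25, 3.7, 3) - aic_ls(25, 3.7, 2), 2)
  expect_warning(v <- aic_ls(10, 0, 2), "-Inf")
  expect_identical(v, -Inf)
  # AICc correction: + 2 q (q+1) / (n - q - 1)
  expect_equal(aic_ls(20, 5, 2, correct = TRUE) - aic_ls(20, 5, 2),
               2 * 3 * 4 / (20 - 3 - 1))
  expect_error(aic_ls(3, 1, 3), "exceed")
})

test_that("AIC prefers the hinge on hinge data and the line on line data", {
  x <- seq(3.5, 7.9, by = 0.11)
  set.seed(7)
  hinge_wins <- line_wins <- logical(200)
  for (r in 1:200) {
    yh <- 40 + 23 * pmin(x - 5, 0) + rnorm(length(x), 0, 3)
    ph <- piecewise_fit(x, yh, xb = 5)
    hinge_wins[r] <- ph$aic_piecewise < ph$aic_linear
    yl <- 10 + 4 * x + rnorm(length(x), 0, 3)
    pl <- piecewise_fit(x, yl, xb = 5)
    line_wins[r] <- pl$aic_linear < pl$aic_piecewise
  }
  expect_gte(mean(hinge_wins), 0.95)
  expect_gt(mean(line_wins), 0.5)
})

test_that("binned divergence test finds constructed change points", {
  set.seed(5)
  t <- seq(-0.05, 0.3, by = 0.002)
  base <- matrix(rnorm(12 * length(t), 0, 0.001), nrow = 12)
  acc_catch <- base[1:6, ]
  acc_real <- base[7:12, ]
  expect_true(is.na(divergence_time(acc_real, acc_catch, t)$t_div))
  # 1 m/s^2 offset injected from exactly 40 ms
  acc_real2 <- acc_real + outer(rep(1, 6), as.numeric(t >= 0.040))
  dv <- divergence_time(acc_real2, acc_catch, t)
  expect_equal(dv$t_div, 0.040)
  expect_error(divergence_time(acc_real[, 1:10], acc_catch, t), "misaligned")
})

test_that("acceleration-sign threshold interpolates the zero crossing", {
  lnk <- seq(3.5, 7.9, by = 0.11)
  expect_equal(acc_sign_threshold(lnk, 5 - lnk), 5, tolerance = 1e-9)
  # order invariance
  set.seed(2)
  o <- sample(length(lnk))
  expect_equal(acc_sign_threshold(lnk[o], (5 - lnk)[o]), 5, tolerance = 1e-9)
  # constant sign: flagged, no flip fabricated
  res <- acc_sign_threshold(lnk, lnk + 1)
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "constant sign")
})

test_that("threshold correlation behaves on exact and null data", {
  x <- rnorm(18)
  expect_equal(threshold_correlation(x, x)$r, 1)
  expect_equal(threshold_correlation(x, -x)$r, -1)
  expect_error(threshold_correlation(x, rep(1, 18)), "zero variance")
  # null: false-positive rate near alpha
  set.seed(31)
  p <- replicate(200, threshold_correlation(rnorm(18), rnorm(18))$p)
  expect_gt(mean(p < 0.05), 0.005)
  expect_lt(mean(p < 0.05), 0.12)
  expect_lt(mean(abs(replicate(200, threshold_correlation(rnorm(18), rnorm(18))$r))), 0.35)
})
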