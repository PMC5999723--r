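#' Polynomial extremum of grip-force peak versus ln stiffness
#'
#' Least-squares polynomial fit (default 4th order) of grip-force peak
#' against ln(k), with the extremum located as the argmax of the fitted
#' polynomial restricted to the observed ln(k) range: a 1e-3 grid search
#' refined by the real roots of the fitted derivative inside the bracketing
#' grid cell. Extrema landing on the range boundary are flagged.
#'
#' @param lnk ln stiffness values.
#' @param gf_peak Grip-force peaks (same length).
#' @param order Polynomial order.
#' @return Object of class `extremum_fit`: list with `coeffs` (increasing
#'   powers), `x_star`, `y_star`, `r2`, `boundary` (logical), `order`, and the
#'   data range.
#' @export
fit_extremum <- function(lnk, gf_peak, order = 4) {
  ok <- is.finite(lnk) & is.finite(gf_peak)
  lnk <- lnk[ok]; gf_peak <- gf_peak[ok]
  if (length(unique(lnk)) < order + 2)
    stop("need at least order + 2 distinct lnk values")
  X <- outer(lnk, 0:order, `^`)
  fit <- stats::lm.fit(X, gf_peak)
  if (fit$rank < order + 1) stop("rank-deficient polynomial design")
  beta <- fit$coefficients
  r2 <- 1 - sum(fit$residuals^2) / sum((gf_peak - mean(gf_peak))^2)

  rng <- range(lnk)
  grid <- seq(rng[1], rng[2], by = 1e-3)
  px <- function(x) drop(outer(x, 0:order, `^`) %*% beta)
  vals <- px(grid)
  i0 <- which.max(vals)
  x_star <- grid[i0]
  # refine by derivative root inside the bracketing cell
  dcoef <- beta[-1] * seq_len(order)
  rts <- polyroot(dcoef)
  rts <- Re(rts[abs(Im(rts)) < 1e-8])
  lo <- grid[max(i0 - 1L, 1L)]; hi <- grid[min(i0 + 1L, length(grid))]
  rts <- rts[rts >= lo & rts <= hi]
  if (length(rts)) {
    cand <- c(x_star, rts)
    x_star <- cand[which.max(px(cand))]
  }
  boundary <- x_star <= rng[1] + 1e-9 || x_star >= rng[2] - 1e-9
  structure(list(coeffs = beta, x_star = x_star, y_star = px(x_star),
                 r2 = r2, boundary = boundary, order = order, range = rng),
            class = "extremum_fit")
}

#' @export
print.extremum_fit <- function(x, ...) {
  cat(sprintf("<extremum_fit> order %d, x* = %.3f (k = %.1f N/m), r2 = %.3f%s\n",
              x$order, x$x_star, exp(x$x_star), x$r2,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Participant-level bootstrap confidence interval
#'
#' Resamples participants with replacement and recomputes a difference
#' statistic between two equal-length paired samples; the 95% percentile
#' interval (2.5 and 97.5 percentiles) is reported along with whether it
#' excludes zero. The statistic is `mean(a) - mean(b)` by default, or its
#' absolute value (`statistic = "abs_mean_diff"`) as used for the
#' low-versus-high stiffness slope comparison.
#'
#' @param sample_a,sample_b Paired per-participant values (equal length).
#' @param reps Bootstrap repetitions.
#' @param seed Integer seed.
#' @param statistic `"mean_diff"` or `"abs_mean_diff"`.
#' @param label Statistic label carried in the result.
#' @return Object of class `bootstrap_ci`: list with `label`, `statistic`,
#'   `estimate` (on the original sample), `reps`, `seed`, `lo`, `hi`,
#'   `excludes_zero`, `boot_sd`.
#' @export
bootstrap_diff <- function(sample_a, sample_b, reps = 10000, seed = 20180607,
                           statistic = c("mean_diff", "abs_mean_diff"),
                           label = "mean difference") {
  statistic <- match.arg(statistic)
  n <- length(sample_a)
  if (length(sample_b) != n) stop("paired samples must have equal length")
  if (n < 3) stop("need at least 3 paired values")
  stat <- function(a, b) {
    d <- mean(a) - mean(b)
    if (statistic == "abs_mean_diff") abs(d) else d
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
  boot <- vapply(seq_len(reps),
                 function(r) stat(sample_a[idx[r, ]], sample_b[idx[r, ]]),
                 numeric(1))
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  structure(list(label = label, statistic = statistic,
                 estimate = stat(sample_a, sample_b), reps = reps,
                 seed = seed, lo = ci[1], hi = ci[2],
                 excludes_zero = !(ci[1] <= 0 && 0 <= ci[2]),
                 boot_sd = stats::sd(boot)),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %s: %.3f, 95%% CI [%.3f, %.3f]%s (reps = %d)\n",
              x$label, x$estimate, x$lo, x$hi,
              if (x$excludes_zero) ", excludes zero" else "", x$reps))
  invisible(x)
}

#' Hinge (piecewise-linear) regression with a fixed breakpoint, versus a line
#'
#' Fits the continuous two-slope model
#' `y = b0 + s_lo (x - xb) [x < xb] + s_hi (x - xb) [x >= xb]`
#' by least squares (3 mean parameters; the breakpoint `xb` is fixed, supplied
#' from an independent upstream estimate), together with the single-line fit
#' on the same points, and compares them by [aic_ls()]. With
#' `continuous = FALSE` the two sides are fitted as unconstrained separate
#' lines (4 mean parameters).
#'
#' @param x,y Data (e.g. ln stiffness and lag in ms).
#' @param xb Fixed breakpoint on the x axis.
#' @param continuous Constrain the two segments to meet at `xb`?
#' @return Object of class `piecewise_fit`: list with `xb`, `s_lo`, `s_hi`,
#'   `intercept` (fitted value at `xb` when continuous), `rss_piecewise`,
#'   `rss_linear`, `aic_piecewise`, `aic_linear`, `n`, `p_piecewise`,
#'   `slope_linear`, `continuous`.
#' @export
piecewise_fit <- function(x, y, xb, continuous = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  lo <- x < xb
  if (sum(lo) < 2 || sum(!lo) < 2)
    stop("need at least 2 points on each side of the breakpoint")
  if (continuous) {
    X <- cbind(1, (x - xb) * lo, (x - xb) * !lo)
    p <- 3L
  } else {
    X <- cbind(lo * 1, (x - xb) * lo, (!lo) * 1, (x - xb) * !lo)
    p <- 4L
  }
  fit <- stats::lm.fit(X, y)
  rss_pw <- sum(fit$residuals^2)
  linfit <- stats::lm.fit(cbind(1, x), y)
  rss_lin <- sum(linfit$residuals^2)
  cf <- fit$coefficients
  structure(list(
    xb = xb,
    s_lo = if (continuous) cf[2] else cf[2],
    s_hi = if (continuous) cf[3] else cf[4],
    intercept = if (continuous) cf[1] else NA_real_,
    rss_piecewise = rss_pw, rss_linear = rss_lin,
    aic_piecewise = aic_ls(n, rss_pw, p),
    aic_linear = aic_ls(n, rss_lin, 2L),
    n = n, p_piecewise = p,
    slope_linear = linfit$coefficients[2],
    continuous = continuous), class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(paste0("<piecewise_fit> xb = %.3f, slopes %.2f / %.2f; ",
                     "AIC %.1f (piecewise) vs %.1f (linear), n = %d\n"),
              x$xb, x$s_lo, x$s_hi, x$aic_piecewise, x$aic_linear, x$n))
  invisible(x)
}

#' AIC for Gaussian least squares
#'
#' `AIC = n log(RSS / n) + 2 (p + 1)`, counting the residual variance as a
#' parameter alongside the `p` mean parameters. The small-sample correction
#' (AICc) adds `2 q (q + 1) / (n - q - 1)` with `q = p + 1`.
#'
#' @param n Number of observations.
#' @param rss Residual sum of squares.
#' @param p_mean_params Number of mean parameters.
#' @param correct Apply the small-sample (AICc) correction?
#' @return The AIC value; `-Inf` with a warning when `rss` is zero.
#' @export
aic_ls <- function(n, rss, p_mean_params, correct = FALSE) {
  if (n <= p_mean_params) stop("n must exceed the number of parameters")
  if (rss < 0) stop("rss must be >= 0")
  if (rss == 0) {
    warning("zero residual sum of squares; AIC is -Inf")
    return(-Inf)
  }
  aic <- n * log(rss / n) + 2 * (p_mean_params + 1)
  if (correct) {
    q <- p_mean_params + 1
    if (n - q - 1 <= 0) stop("AICc undefined: n too small")
    aic <- aic + 2 * q * (q + 1) / (n - q - 1)
  }
  aic
}

#' Divergence time of real versus catch acceleration
#'
#' Two-sample t-tests on bin-mean acceleration in consecutive bins (default
#' 20 ms), from time zero (force onset) onward. The divergence time is the
#' start of the earliest bin from which p < alpha holds for all consecutive
#' bins spanning at least `sustain` seconds. Rows are independent traces
#' (typically per-participant means); columns are time samples on a common
#' axis `t` aligned to force onset (may start before zero; pre-onset samples
#' are ignored).
#'
#' @param acc_real,acc_catch Matrices, rows = traces, columns = time samples.
#' @param t Common time axis, s, relative to force onset.
#' @param bin Bin width, s.
#' @param alpha Significance level per bin.
#' @param sustain Required span of consecutive significant bins, s.
#' @return List with `t_div` (s; `NA` if no sustained divergence),
#'   `bin_starts`, `p_values`, `significant`.
#' @export
divergence_time <- function(acc_real, acc_catch, t, bin = 0.020,
                            alpha = 0.05, sustain = 0.150) {
  if (ncol(acc_real) != length(t) || ncol(acc_catch) != length(t))
    stop("misaligned matrices: columns must match the time axis")
  if (nrow(acc_real) < 2 || nrow(acc_catch) < 2)
    stop("need at least 2 traces per group")
  t_end <- max(t)
  starts <- seq(0, t_end - bin + 1e-12, by = bin)
  if (length(starts) == 0L) stop("time axis too short for one bin")
  pv <- vapply(starts, function(s) {
    cols <- which(t >= s & t < s + bin)
    br <- rowMeans(acc_real[, cols, drop = FALSE])
    bc <- rowMeans(acc_catch[, cols, drop = FALSE])
    if (stats::sd(br) == 0 && stats::sd(bc) == 0)
      return(if (isTRUE(all.equal(mean(br), mean(bc)))) 1 else 0)
    stats::t.test(br, bc)$p.value
  }, numeric(1))
  sig <- pv < alpha
  need <- as.integer(ceiling(sustain / bin))
  t_div <- NA_real_
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  run_starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit)) t_div <- starts[run_starts[hit[1L]]]
  list(t_div = t_div, bin_starts = starts, p_values = pv, significant = sig)
}

#' Acceleration-sign threshold on the ln-stiffness axis
#'
#' Orders the trials by ln(k), averages acceleration-at-field-onset per ln(k)
#' level, and locates the first sign change of that mean curve; the crossing
#' is linearly interpolated between the two bracketing levels. The result is
#' invariant to the input order.
#'
#' @param lnk ln stiffness per trial.
#' @param acc_at_field_onset Acceleration at the (expected) field-onset
#'   crossing, m/s^2, per trial.
#' @return ln(k) of the sign flip, or `NA` (with attribute `reason`) when the
#'   mean curve never changes sign.
#' @export
acc_sign_threshold <- function(lnk, acc_at_field_onset) {
  ok <- is.finite(lnk) & is.finite(acc_at_field_onset)
  lnk <- lnk[ok]; acc <- acc_at_field_onset[ok]
  if (!length(lnk)) stop("no finite observations")
  mu <- tapply(acc, lnk, mean)
  xs <- as.numeric(names(mu))
  o <- order(xs)
  xs <- xs[o]; mu <- as.numeric(mu)[o]
  s <- sign(mu)
  flip <- which(s[-1] * s[-length(s)] < 0)
  if (!length(flip)) {
    zero <- which(s == 0)
    if (length(zero)) return(xs[zero[1L]])
    return(structure(NA_real_, reason = "constant sign"))
  }
  i <- flip[1L]
  xs[i] + (0 - mu[i]) * (xs[i + 1] - xs[i]) / (mu[i + 1] - mu[i])
}

#' Correlation between per-participant switch thresholds
#'
#' Pearson correlation (with two-sided p-value) between the strategy-switch
#' threshold and the acceleration-sign threshold across participants.
#'
#' @param x_strategy,x_accsign Per-participant thresholds (paired).
#' @return List with `r`, `p`, `n`.
#' @export
threshold_correlation <- function(x_strategy, x_accsign) {
  ok <- is.finite(x_strategy) & is.finite(x_accsign)
  x <- x_strategy[ok]; y <- x_accsign[ok]
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
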