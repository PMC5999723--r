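#' Central-difference derivative
#'
#' Interior samples use `(x[i+1] - x[i-1]) * fs / 2`; the edges use one-sided
#' differences so the output has the length of the input.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @return Derivative, same length as `x`.
#' @export
central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 3) stop("central difference needs at least 3 samples")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth low-pass (per pass) run forward then backward, so the
#' net phase shift is zero and the magnitude response is the squared one-pass
#' response. Edge transients are handled by odd (point-symmetric) reflection
#' padding before filtering.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency per pass, Hz.
#' @param order Filter order per pass.
#' @return Filtered vector, same length as `x`.
#' @export
lowpass_zerophase <- function(x, fs, cutoff = 20, order = 4) {
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2))
  np <- min(3L * ceiling(fs / cutoff), n - 1L)
  left <- 2 * x[1] - x[(np + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - np)]
  xx <- c(left, x, right)
  xx <- as.numeric(signal::filter(bf, xx))
  xx <- rev(as.numeric(signal::filter(bf, rev(xx))))
  xx[(np + 1L):(np + n)]
}

#' Derive and smooth the kinematic and grip channels
#'
#' The preprocessing chain applied to every trial: velocity, acceleration and
#' grip-force rate are obtained by central differences and smoothed with the
#' zero-phase 20-Hz low-pass of [lowpass_zerophase()]; the grip-force channel
#' itself is smoothed with the same filter before peak extraction.
#' Acceleration is the central difference of the already-smoothed velocity.
#'
#' @param series A [trial_series()] (uniform time base enforced).
#' @param fs Sampling rate, Hz; taken from the series time base by default.
#' @param cutoff Filter cutoff per pass, Hz.
#' @return List with smoothed `v`, `a`, `gfr` (grip-force rate, N/s) and `gf`
#'   (smoothed grip force, N), all the length of the input.
#' @export
derive_and_filter <- function(series, fs = NULL, cutoff = 20) {
  stopifnot(inherits(series, "trial_series"))
  dts <- diff(series$t)
  if (length(dts) >= 2 && max(abs(dts - dts[1])) > 1e-9)
    stop("non-uniform time base")
  if (is.null(fs)) fs <- 1 / dts[1]
  v <- lowpass_zerophase(central_diff(series$y, fs), fs, cutoff)
  a <- lowpass_zerophase(central_diff(v, fs), fs, cutoff)
  gf <- lowpass_zerophase(series$f_grip, fs, cutoff)
  gfr <- lowpass_zerophase(central_diff(series$f_grip, fs), fs, cutoff)
  list(v = v, a = a, gfr = gfr, gf = gf, fs = fs)
}
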