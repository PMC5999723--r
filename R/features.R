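#' Movement onset by sustained velocity threshold
#'
#' Movement onset is the earliest sample from which velocity stays above the
#' threshold for at least the hold duration.
#'
#' @param v Velocity, m/s (typically smoothed).
#' @param fs Sampling rate, Hz.
#' @param threshold Velocity threshold, m/s (3 cm/s).
#' @param hold Required supra-threshold duration, s (100 ms).
#' @return Onset sample index (1-based).
#' @export
movement_onset <- function(v, fs = 500, threshold = 0.03, hold = 0.1) {
  need <- as.integer(round(hold * fs))
  above <- v > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0L) stop("onset-not-found: no sustained supra-threshold epoch")
  starts[ok[1L]]
}

# strict local maxima: x[i] greater than its 2 neighbors on each side
.local_maxima <- function(x, halfwin = 2L) {
  n <- length(x)
  if (n < 2L * halfwin + 1L) return(integer(0))
  idx <- (halfwin + 1L):(n - halfwin)
  keep <- rep(TRUE, length(idx))
  for (d in seq_len(halfwin)) {
    keep <- keep & x[idx] > x[idx - d] & x[idx] > x[idx + d]
  }
  idx[keep]
}

#' Time of (expected) impact and peak elastic force
#'
#' On real trials, impact is the argmax of the rendered elastic load force. On
#' catch trials (where no force is rendered) it is the argmax of the expected
#' elastic force, i.e. [elastic_force()] with the scheduled `(k, y0)` applied
#' to the recorded position. Ties break to the earliest sample.
#'
#' @param series A [trial_series()].
#' @param fp Scheduled [field_params()]; reconstructed from `series$meta`
#'   (`k_Npm`, `y0_cm`, `is_catch`, `w_m`) if `NULL`.
#' @return List with `idx`, `t_impact` (s) and `lf_peak` (N, expected value on
#'   catch trials).
#' @export
impact_time <- function(series, fp = NULL) {
  if (is.null(fp)) {
    m <- series$meta
    if (is.null(m$k_Npm) || is.null(m$y0_cm))
      stop("impact_time needs the scheduled field (fp or meta k_Npm/y0_cm)")
    fp <- field_params(m$k_Npm, m$y0_cm / 100, w = m$w_m %||% 0.001,
                       is_catch = isTRUE(m$is_catch))
  }
  f <- if (fp$is_catch) elastic_force(series$y, fp, expected = TRUE)
       else series$f_load
  if (max(f) <= 0)
    stop("impact-not-found: position never enters the (expected) field")
  idx <- which.max(f)
  list(idx = idx, t_impact = series$t[idx], lf_peak = f[idx])
}

#' Extract per-trial scalar features
#'
#' Runs the preprocessing chain ([derive_and_filter()]), locates movement
#' onset and (expected) impact, and extracts the scalar features used by the
#' switching analyses: the global grip-force peak in `[onset, end]` and its
#' lag to (expected) impact; the first (inertial) grip peak - the dominant
#' local grip maximum within +/- 150 ms of the first acceleration peak after
#' onset - and its lag to that acceleration peak; peak velocity; grip-force
#' rate and acceleration at
#' the time the (expected) field boundary `y0` is first crossed. Features
#' whose defining peak is absent are returned as `NA`, never fabricated.
#'
#' @param series A [trial_series()] whose `meta` carries the scheduled field
#'   (as produced by [simulate_trial()] or read with a manifest row).
#' @param cutoff Filter cutoff, Hz.
#' @param first_peak_win Half-window around the first acceleration peak in
#'   which the first local grip peak is sought, s.
#' @return One-row data.frame with identifiers and features; times in s, lags
#'   in ms, rates in N/s.
#' @export
extract_features <- function(series, cutoff = 20, first_peak_win = 0.150) {
  m <- series$meta
  der <- derive_and_filter(series, cutoff = cutoff)
  fs <- der$fs
  onset_idx <- movement_onset(der$v, fs)
  imp <- impact_time(series)
  n <- length(series$t)

  mov <- onset_idx:n
  gf_peak_idx <- mov[which.max(der$gf[mov])]

  # the first acceleration peak is the dominant hump shortly after onset;
  # noise ripples on the rising flank and filter ringing at the field impact
  # must not pre-empt it, so locate it as the argmax in an early window
  early <- onset_idx:min(n, onset_idx + as.integer(round(0.25 * fs)))
  acc1 <- early[which.max(der$a[early])]
  if (der$a[acc1] > 0) {
    win <- as.integer(round(first_peak_win * fs))
    gmax <- .local_maxima(der$gf)
    gmax <- gmax[abs(gmax - acc1) <= win]
    # the inertial grip peak is the dominant local maximum in the window;
    # taking the literal earliest would latch onto noise ripples
    gf1 <- if (length(gmax)) gmax[which.max(der$gf[gmax])] else NA_integer_
  } else {
    acc1 <- NA_integer_; gf1 <- NA_integer_
  }

  # first crossing of the (expected) field boundary
  y0 <- m$y0_cm / 100
  cross <- which(series$y >= y0)
  cross <- if (length(cross)) cross[1L] else NA_integer_

  data.frame(
    participant = m$participant %||% NA, block = m$block %||% NA,
    trial = m$trial %||% NA, condition = m$condition %||% NA,
    mini_block = m$mini_block %||% NA,
    k_Npm = m$k_Npm, y0_cm = m$y0_cm, lnk = log(m$k_Npm),
    is_catch = isTRUE(m$is_catch),
    t_onset = series$t[onset_idx], t_impact = imp$t_impact,
    lf_peak = imp$lf_peak,
    gf_peak = der$gf[gf_peak_idx], t_gf_peak = series$t[gf_peak_idx],
    gf_first_peak = if (is.na(gf1)) NA_real_ else der$gf[gf1],
    t_gf_first_peak = if (is.na(gf1)) NA_real_ else series$t[gf1],
    acc_first_peak = if (is.na(acc1)) NA_real_ else der$a[acc1],
    t_acc_first_peak = if (is.na(acc1)) NA_real_ else series$t[acc1],
    vp = max(der$v[mov]),
    lag_impact_ms = 1000 * (series$t[gf_peak_idx] - imp$t_impact),
    lag_inertial_ms = if (is.na(gf1) || is.na(acc1)) NA_real_
      else 1000 * (series$t[gf1] - series$t[acc1]),
    gfr_at_onset = if (is.na(cross)) NA_real_ else der$gfr[cross],
    acc_at_field_onset = if (is.na(cross)) NA_real_ else der$a[cross],
    truth_lag_ms = m$lag_actual_ms %||% NA_real_,
    theta_eff = m$theta_eff %||% NA_real_)
}

#' Catch-minus-neighbor differences of grip-force rate
#'
#' For every catch trial C_t of a block, the differences `C_t - R_{t-1}` and
#' `C_t - R_{t+1}` of grip-force rate at expected force onset, where R are the
#' immediately neighboring real trials. A side whose neighbor is missing (a
#' block edge) or is itself a catch trial yields `NA` on that side.
#'
#' @param features Feature rows of one block (one row per trial, as returned
#'   by [extract_features()]); must contain `trial`, `is_catch`,
#'   `gfr_at_onset`.
#' @return data.frame with `trial`, `diff_prev`, `diff_next` (N/s), one row
#'   per catch trial.
#' @export
catch_neighbor_diffs <- function(features) {
  f <- features[order(features$trial), ]
  ci <- which(f$is_catch)
  out <- lapply(ci, function(i) {
    prev <- if (i > 1L && !f$is_catch[i - 1L])
      f$gfr_at_onset[i] - f$gfr_at_onset[i - 1L] else NA_real_
    nxt <- if (i < nrow(f) && !f$is_catch[i + 1L])
      f$gfr_at_onset[i] - f$gfr_at_onset[i + 1L] else NA_real_
    data.frame(trial = f$trial[i], diff_prev = prev, diff_next = nxt)
  })
  if (length(out)) do.call(rbind, out)
  else data.frame(trial = integer(0), diff_prev = numeric(0),
                  diff_next = numeric(0))
}
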