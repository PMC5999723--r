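test_that("movement onset matches a direct-scan oracle", {
  fs <- 500
  scan_oracle <- function(v, need = 50) {
    for (i in seq_len(length(v) - need + 1))
      if (all(v[i:(i + need - 1)] > 0.03)) return(i)
    NA_integer_
  }
  # step that stays up
  v1 <- c(rep(0, 99), rep(0.10, 400))
  expect_equal(movement_onset(v1, fs), 100)
  expect_equal(movement_onset(v1, fs), scan_oracle(v1))
  # 50-ms blip must not trigger; sustained crossing at sample 300 must
  v2 <- c(rep(0, 99), rep(0.10, 25), rep(0, 175), rep(0.10, 300))
  expect_equal(movement_onset(v2, fs), 300)
  expect_equal(movement_onset(v2, fs), scan_oracle(v2))
  expect_error(movement_onset(rep(0, 1000), fs), "onset-not-found")
})

test_that("onset detection is translation-equivariant", {
  fs <- 500
  v <- c(rep(0, 200), seq(0, 0.5, length.out = 200), rep(0.5, 200))
  i0 <- movement_onset(v, fs)
  expect_equal(movement_onset(c(rep(0, 500), v), fs), i0 + 500L)
})

test_that("impact localization matches the penetration argmax oracle", {
  tr <- fx_stiff_trial()
  imp <- impact_time(tr)
  # oracle: argmax of k (y - y0)+ over samples (w = 1 mm blend only widens
  # the foot, not the peak)
  pen <- pmax(tr$y - 0.145, 0)
  expect_equal(imp$idx, which.max(pen))
  expect_equal(imp$lf_peak, max(tr$f_load))
  # monotone rise-fall: argmax is the turning point
  expect_true(all(diff(tr$f_load[1:imp$idx]) >= 0 | tr$f_load[2:imp$idx] == 0))
})

test_that("catch and real trials with identical kinematics agree on impact", {
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)
  pl <- plan_trajectory(t, 0.5, 0.175, t_move = 0.3)
  fp <- field_params(100, 0.08)
  f_load <- elastic_force(pl$y, fp)
  meta_real <- list(k_Npm = 100, y0_cm = 8, is_catch = FALSE, w_m = 0.001)
  meta_catch <- modifyList(meta_real, list(is_catch = TRUE))
  tr_real <- trial_series(t, pl$y, pl$v, pl$a, f_load, 2 + f_load / 10,
                          meta = meta_real)
  tr_catch <- trial_series(t, pl$y, pl$v, pl$a, 0 * f_load, 2 + f_load / 10,
                           meta = meta_catch)
  ir <- impact_time(tr_real); ic <- impact_time(tr_catch)
  expect_equal(ic$t_impact, ir$t_impact)
  expect_equal(ic$lf_peak, ir$lf_peak, tolerance = 1e-9)
  expect_error(impact_time(trial_series(t, 0 * t, 0 * t, 0 * t, 0 * t,
                                        rep(2, length(t)),
                                        meta = meta_catch)),
               "impact-not-found")
})

test_that("constructed grip shifts are recovered as lags", {
  fs <- 500
  t <- seq(0, 2.2, by = 1 / fs)
  pl <- plan_trajectory(t, 0.5, 0.175, t_move = 0.3)
  fp <- field_params(100, 0.08)
  f_load <- elastic_force(pl$y, fp)
  meta <- list(participant = 1, block = 1, trial = 1, mini_block = 1,
               condition = "ascending", k_Npm = 100, y0_cm = 8,
               is_catch = FALSE, w_m = 0.001)
  for (shift_ms in c(0, 40)) {
    s <- as.integer(shift_ms / 1000 * fs)
    f_grip <- 2 + c(rep(0, s), f_load[seq_len(length(t) - s)])
    tr <- trial_series(t, pl$y, pl$v, pl$a, f_load, f_grip, meta = meta)
    ft <- extract_features(tr)
    expect_equal(ft$lag_impact_ms, shift_ms, tolerance = 1e-9)
  }
})

test_that("zero-noise simulated stiffest trial recovers the plateau lag", {
  ft <- extract_features(fx_stiff_trial())
  expect_equal(ft$lag_impact_ms, 40, tolerance = 2)
  expect_equal(ft$lag_inertial_ms, 0, tolerance = 2)
  expect_lt(ft$t_onset, ft$t_impact)
})

test_that("catch-neighbor grip-rate differences are plain arithmetic", {
  f <- data.frame(trial = 1:5, is_catch = c(FALSE, TRUE, FALSE, FALSE, TRUE),
                  gfr_at_onset = c(10, 12, 10, 10, 10))
  d <- catch_neighbor_diffs(f)
  expect_equal(d$trial, c(2L, 5L))
  expect_equal(d$diff_prev, c(2, 0))
  expect_equal(d$diff_next, c(2, NA))  # block edge: only one side
  # identical rates give all-zero differences
  f$gfr_at_onset <- rep(7, 5)
  expect_true(all(unlist(catch_neighbor_diffs(f)[, -1]) %in% c(0, NA)))
})
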