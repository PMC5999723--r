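test_that("lag model reproduces the rise-then-plateau endpoints", {
  cp <- controller_params()
  expect_equal(lag_model(log(2800), cp), 40)
  expect_equal(lag_model(log(4 / 0.12), cp), 4)
  # continuity at the threshold: exactly the plateau value
  expect_equal(lag_model(cp$theta_asc, cp, theta_eff = cp$theta_asc), 40)
  # linear in between
  mid <- (log(4 / 0.12) + cp$theta_asc) / 2
  expect_equal(lag_model(mid, cp, cp$theta_asc), (4 + 40) / 2)
})

test_that("effective threshold lags the crossing by the switch inertia", {
  cp <- controller_params(switch_inertia_trials = 3)
  lnk <- seq(3.5, 8, by = 0.1)
  cross <- which(lnk > cp$theta_asc)[1]          # direct-scan oracle
  expect_equal(effective_threshold(lnk, "ascending", cp), lnk[cross + 3])
  lnk_d <- rev(lnk)
  cross_d <- which(lnk_d < cp$theta_desc)[1]
  expect_equal(effective_threshold(lnk_d, "descending", cp), lnk_d[cross_d + 3])
  # never crossing: regime never flips
  expect_equal(effective_threshold(c(3, 4), "ascending", cp), Inf)
})

test_that("parameter validation enforces hysteresis and ordering", {
  expect_error(controller_params(theta_asc = 4.5, theta_desc = 4.9), "hysteresis")
  expect_error(controller_params(lag_soft = 50, lag_plateau = 40), "exceed")
  expect_error(controller_params(lag_sd = -1), "SD")
})

test_that("grip profile degenerates to baseline and peaks at the threshold", {
  cp0 <- controller_params(inertial_gain = 0, amp_peak = 0, lag_sd = 0,
                           pos_noise_sd = 0, gf_noise_sd = 0)
  fp <- field_params(150, 0.09)
  kin <- simulate_kinematics(0.5, fp)
  gp <- grip_profile(kin, fp, cp0)
  expect_equal(gp$f_grip, rep(cp0$gf_baseline, length(kin$t)))
  # at ln k = condition threshold the anticipatory amplitude is amp_peak
  cp <- controller_params(lag_sd = 0)
  fp_th <- field_params(exp(cp$theta_asc), 0.09)
  gp_th <- grip_profile(simulate_kinematics(0.5, fp_th), fp_th, cp,
                        theta_cond = cp$theta_asc)
  expect_equal(gp_th$amp, cp$amp_peak)
})

test_that("noiseless stiffest trial peaks exactly lag_plateau after impact", {
  tr <- fx_stiff_trial()
  cp <- controller_params(lag_sd = 0, pos_noise_sd = 0, gf_noise_sd = 0)
  # oracle: argmax of the constructed profile vs the recorded impact
  t_peak <- tr$t[which.max(tr$f_grip)]
  t_imp <- tr$t[which.max(tr$f_load)]
  expect_equal(1000 * (t_peak - t_imp), cp$lag_plateau, tolerance = 2)
})
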