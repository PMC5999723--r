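#' Switched feedforward grip-controller parameters
#'
#' Parameters of the generative grip-force controller. The controller has two
#' feedforward regimes selected around a stiffness threshold on the ln(k)
#' axis, with hysteresis: the threshold is `theta_asc` when stiffness grows
#' over trials and `theta_desc` when it shrinks (`theta_asc > theta_desc`),
#' and the regime flips only `switch_inertia_trials` trials after the
#' schedule crosses the condition's threshold.
#'
#' The grip-peak lag to (expected) impact follows [lag_model()]: it rises
#' linearly with ln(k) from `lag_soft` at the softest field to `lag_plateau`
#' at the effective threshold and stays at `lag_plateau` above it; each trial
#' adds Gaussian timing noise of SD `lag_sd`. The anticipatory grip bump has a
#' Gaussian amplitude profile on the ln(k) axis centered at the condition's
#' threshold (`amp_peak`, width `amp_width`), producing the inverted-U of grip
#' peak versus ln stiffness; `bump_sd` is its temporal width. Grip force also
#' tracks the upward inertial load through `inertial_gain` (rectified planned
#' acceleration, producing a first local grip peak synchronized with the first
#' acceleration peak) on top of the constant `gf_baseline`.
#'
#' @param theta_asc,theta_desc Switch thresholds on ln(k / (N/m)), ascending /
#'   descending condition; hysteresis requires `theta_asc > theta_desc`.
#' @param lag_soft Grip-peak lag at the softest stiffness, ms.
#' @param lag_plateau Grip-peak lag above the threshold, ms; must exceed
#'   `lag_soft`.
#' @param lag_sd Trial-level lag noise SD, ms.
#' @param amp_peak Anticipatory grip-bump amplitude at the threshold, N.
#' @param amp_width Width (SD) of the amplitude curve on the ln(k) axis.
#' @param bump_sd Temporal SD of the anticipatory bump, s.
#' @param inertial_gain Grip response to inertial load, N per m/s^2.
#' @param gf_baseline Baseline grip force, N (> 0: grip never released).
#' @param m_eff Effective hand-plus-handle mass, kg.
#' @param m_eff_sd Between-participant SD of the effective mass, kg
#'   (anthropometric variability; drawn once per participant).
#' @param switch_inertia_trials Trials after threshold crossing before the lag
#'   regime switches.
#' @param force_delay Force-transmission transport latency from rendered
#'   field force to hand acceleration, s.
#' @param force_tau Compliance time constant of the force transmission, s.
#' @param amplitude Planned movement amplitude, m (overshoots the 15-cm
#'   target).
#' @param vp_mean,vp_sd Mean and trial-level SD of the planned peak-speed
#'   draw, m/s, truncated to `[0.45, 0.55]`.
#' @param vp_mean_sd Between-participant SD of the habitual mean peak speed,
#'   m/s (drawn once per participant).
#' @param pos_noise_sd Position measurement noise SD, m.
#' @param gf_noise_sd Grip-force channel noise SD, N.
#' @return An object of class `controller_params` (a validated list).
#' @export
controller_params <- function(theta_asc = 5.07, theta_desc = 4.89,
                              lag_soft = 4, lag_plateau = 40, lag_sd = 6,
                              amp_peak = 4, amp_width = 2.5, bump_sd = 0.08,
                              inertial_gain = 0.4, gf_baseline = 2,
                              m_eff = 1.2, m_eff_sd = 0.1,
                              switch_inertia_trials = 3L,
                              force_delay = 0.030, force_tau = 0.010,
                              amplitude = 0.175,
                              vp_mean = 0.499, vp_sd = 0.02,
                              vp_mean_sd = 0.015,
                              pos_noise_sd = 1e-4, gf_noise_sd = 0.05) {
  cp <- list(theta_asc = theta_asc, theta_desc = theta_desc,
             lag_soft = lag_soft, lag_plateau = lag_plateau, lag_sd = lag_sd,
             amp_peak = amp_peak, amp_width = amp_width, bump_sd = bump_sd,
             inertial_gain = inertial_gain, gf_baseline = gf_baseline,
             m_eff = m_eff, m_eff_sd = m_eff_sd,
             switch_inertia_trials = as.integer(switch_inertia_trials),
             force_delay = force_delay, force_tau = force_tau,
             amplitude = amplitude,
             vp_mean = vp_mean, vp_sd = vp_sd, vp_mean_sd = vp_mean_sd,
             pos_noise_sd = pos_noise_sd, gf_noise_sd = gf_noise_sd)
  if (cp$lag_plateau <= cp$lag_soft)
    stop("lag_plateau must exceed lag_soft")
  if (cp$theta_asc <= cp$theta_desc)
    stop("hysteresis requires theta_asc > theta_desc")
  if (cp$lag_sd < 0 || cp$pos_noise_sd < 0 || cp$gf_noise_sd < 0 ||
      cp$vp_sd < 0 || cp$m_eff_sd < 0 || cp$vp_mean_sd < 0)
    stop("noise SDs must be >= 0")
  if (cp$gf_baseline <= 0) stop("gf_baseline must be > 0 (grip never released)")
  class(cp) <- "controller_params"
  cp
}

#' @export
print.controller_params <- function(x, ...) {
  cat(sprintf(paste0("<controller_params> thresholds ln k = %.2f (asc) / ",
                     "%.2f (desc); lag %g -> %g ms (SD %g)\n"),
              x$theta_asc, x$theta_desc, x$lag_soft, x$lag_plateau, x$lag_sd))
  invisible(x)
}

# reference softest stiffness of the design: 4 N over 12 cm
.lnk_soft_ref <- function() log(4 / 0.12)

#' Generative grip-peak lag as a function of ln stiffness
#'
#' Piecewise-linear rise-then-plateau: the lag grows linearly with ln(k) from
#' `lag_soft` at the softest scheduled stiffness (ln(33.33) = 3.507) up to
#' `lag_plateau` at the effective threshold `theta_eff`, and is constant at
#' `lag_plateau` above it. The effective threshold carries the hysteresis and
#' switch inertia; see [effective_threshold()].
#'
#' @param ln_k ln stiffness, ln(N/m) (vectorized).
#' @param cp [controller_params()].
#' @param theta_eff Effective switch threshold on the ln(k) axis; defaults to
#'   the ascending threshold.
#' @return Lag in ms.
#' @export
lag_model <- function(ln_k, cp, theta_eff = cp$theta_asc) {
  lo <- .lnk_soft_ref()
  frac <- pmin(pmax((ln_k - lo) / (theta_eff - lo), 0), 1)
  cp$lag_soft + (cp$lag_plateau - cp$lag_soft) * frac
}

#' Effective switch threshold of a block schedule
#'
#' The regime flips `switch_inertia_trials` trials after the scheduled ln(k)
#' sequence crosses the condition's threshold (`theta_asc` when ascending,
#' `theta_desc` when descending); the effective threshold is the scheduled
#' ln(k) of the flip trial. Catch trials count: they carry their scheduled
#' (expected) stiffness.
#'
#' @param lnk_seq Scheduled ln(k) sequence in trial order.
#' @param condition `"ascending"` or `"descending"`.
#' @param cp [controller_params()].
#' @return The effective threshold (scalar, ln(N/m)).
#' @export
effective_threshold <- function(lnk_seq, condition = c("ascending", "descending"),
                                cp = controller_params()) {
  condition <- match.arg(condition)
  n <- length(lnk_seq)
  cross <- if (condition == "ascending") which(lnk_seq > cp$theta_asc)[1]
           else which(lnk_seq < cp$theta_desc)[1]
  if (is.na(cross)) return(if (condition == "ascending") Inf else -Inf)
  flip <- min(cross + cp$switch_inertia_trials, n)
  lnk_seq[flip]
}

#' Generative grip-force profile for one trial
#'
#' Grip force is the sum of a constant baseline, an inertial component
#' `inertial_gain * max(a_plan, 0)` (time-jittered by `lag_sd`, yielding a
#' first local grip peak synchronized with the first acceleration peak), and
#' an anticipatory Gaussian bump centered at the (expected) impact time plus
#' the generative lag [lag_model()] plus trial noise `N(0, lag_sd)`. The bump
#' amplitude follows the inverted-U
#' `amp_peak * exp(-(ln k - theta_cond)^2 / (2 amp_width^2))` on the ln(k)
#' axis. Catch trials use the identical construction with the expected impact
#' time; the rendered field plays no role here.
#'
#' @param kin Kinematics from [simulate_kinematics()].
#' @param fp [field_params()] with the scheduled (expected) field.
#' @param cp [controller_params()].
#' @param theta_cond Condition threshold centering the amplitude curve.
#' @param theta_eff Effective threshold for the lag regime
#'   ([effective_threshold()]).
#' @param t_impact (Expected) impact time, s: argmax of the expected elastic
#'   force along the realized trajectory. Computed from `kin` if `NULL`.
#' @return List: `f_grip` (N, no measurement noise), `t_impact`,
#'   `lag_nominal_ms` ([lag_model()] output), `lag_actual_ms` (with trial
#'   noise), `amp` (bump amplitude, N).
#' @export
grip_profile <- function(kin, fp, cp, theta_cond = cp$theta_asc,
                         theta_eff = cp$theta_asc, t_impact = NULL) {
  lnk <- log(fp$k)
  if (is.null(t_impact)) {
    f_exp <- elastic_force(kin$y, fp, expected = TRUE)
    if (max(f_exp) <= 0)
      stop("impact-not-found: trajectory never enters the (expected) field")
    t_impact <- kin$t[which.max(f_exp)]
  }
  lag_nominal <- lag_model(lnk, cp, theta_eff)
  lag_actual <- lag_nominal + stats::rnorm(1, 0, cp$lag_sd)
  amp <- cp$amp_peak * exp(-(lnk - theta_cond)^2 / (2 * cp$amp_width^2))

  # inertial drive: rectified planned acceleration, re-evaluated at jittered
  # time via the closed-form plan (no resampling error)
  jit <- stats::rnorm(1, 0, cp$lag_sd) / 1000
  vp <- 1.875 * cp$amplitude / kin$T_seg
  plan_j <- plan_trajectory(kin$t - jit, vp, cp$amplitude, t_move = kin$t_move)
  inertial <- cp$inertial_gain * pmax(plan_j$a, 0)

  t_c <- t_impact + lag_actual / 1000
  bump <- amp * exp(-(kin$t - t_c)^2 / (2 * cp$bump_sd^2))
  list(f_grip = cp$gf_baseline + inertial + bump,
       t_impact = t_impact, lag_nominal_ms = lag_nominal,
       lag_actual_ms = lag_actual, amp = amp)
}
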