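#' Minimum-jerk point-to-point segment
#'
#' Closed-form minimum-jerk trajectory from 0 to amplitude `A` over duration
#' `T`: with \eqn{\tau = t/T}, position is
#' \eqn{A (10\tau^3 - 15\tau^4 + 6\tau^5)}. The peak speed of such a segment
#' is `1.875 * A / T`, so a segment with prescribed peak speed `vp` lasts
#' `T = 1.875 * A / vp`.
#'
#' @param t Time within the segment, s (vectorized; clamped to `[0, T]`).
#' @param A Amplitude, m (may be negative for a downward segment).
#' @param T Segment duration, s.
#' @return List with `y`, `v`, `a` evaluated at `t`.
#' @export
min_jerk <- function(t, A, T) {
  tau <- pmin(pmax(t / T, 0), 1)
  y <- A * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  v <- A / T * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  a <- A / T^2 * (60 * tau - 180 * tau^2 + 120 * tau^3)
  inside <- t >= 0 & t <= T
  v[!inside] <- 0
  a[!inside] <- 0
  list(y = y, v = v, a = a)
}

#' Planned up-and-down reaching trajectory
#'
#' Two back-to-back minimum-jerk segments (home -> `A` -> home), each of
#' duration `T = 1.875 * A / vp` so the planned peak speed equals `vp`.
#' Movement starts at `t_move`; the hand is at rest before and after.
#'
#' @param t Time axis, s.
#' @param vp Planned peak speed, m/s.
#' @param A Planned amplitude, m.
#' @param t_move Movement start time, s.
#' @return List with `y`, `v`, `a`, and segment duration `T_seg`.
#' @export
plan_trajectory <- function(t, vp, A, t_move = 0) {
  T_seg <- 1.875 * A / vp
  up <- min_jerk(t - t_move, A, T_seg)
  dn <- min_jerk(t - t_move - T_seg, -A, T_seg)
  after <- t >= t_move + T_seg
  y <- up$y
  y[after] <- A + dn$y[after]
  v <- up$v + dn$v
  a <- up$a + dn$a
  list(y = y, v = v, a = a, T_seg = T_seg)
}

#' Simulate trial kinematics in an elastic force field
#'
#' The planned trajectory is the two-segment minimum-jerk reach of
#' [plan_trajectory()], with planned amplitude deliberately overshooting the
#' 15-cm target (participants plan to push through the spring; catch trials
#' therefore overshoot). On real (non-catch) trials the realized acceleration
#' is the planned acceleration minus `F_field / m_eff`, where the rendered
#' field force acts on the hand's measured acceleration through a fixed
#' transmission latency `force_delay` (grasp/arm compliance plus device force
#' loop); the perturbation is forward-integrated (semi-implicit Euler) on top
#' of the plan, so real and catch accelerations are identical until shortly
#' after field entry and diverge thereafter. On catch trials the realized
#' trajectory equals the planned trajectory exactly.
#'
#' @param vp_target Planned peak speed, m/s; must lie in `[0.45, 0.55]`.
#' @param fp [field_params()] for the trial (catch flag respected).
#' @param m_eff Effective hand-plus-handle mass, kg.
#' @param fs Sampling rate, Hz.
#' @param amplitude Planned movement amplitude, m.
#' @param pre,post Still time before movement onset / after movement end, s.
#' @param force_delay Force-transmission transport latency, s.
#' @param force_tau Time constant of the first-order compliance lag through
#'   which the delayed force reaches the hand, s (0 disables it).
#' @return List with `t`, `y`, `v`, `a` (realized), `f_load` (rendered elastic
#'   force, zero on catch trials), planned channels `y_plan`, `v_plan`,
#'   `a_plan`, and `t_move`, `T_seg`.
#' @export
simulate_kinematics <- function(vp_target, fp, m_eff = 1.2, fs = 500,
                                amplitude = 0.175, pre = 0.3, post = 0.25,
                                force_delay = 0.030, force_tau = 0.010) {
  if (vp_target < 0.45 || vp_target > 0.55)
    stop("peak-speed target outside the prescribed 45-55 cm/s window")
  stopifnot(inherits(fp, "field_params"), m_eff > 0, fs > 0)
  dt <- 1 / fs
  T_seg <- 1.875 * amplitude / vp_target
  n <- ceiling((pre + 2 * T_seg + post) * fs) + 1L
  t <- (seq_len(n) - 1L) * dt
  plan <- plan_trajectory(t, vp_target, amplitude, t_move = pre)

  if (fp$is_catch || fp$k == 0) {
    return(list(t = t, y = plan$y, v = plan$v, a = plan$a,
                f_load = numeric(n), y_plan = plan$y, v_plan = plan$v,
                a_plan = plan$a, t_move = pre, T_seg = T_seg))
  }

  k <- fp$k; y0 <- fp$y0; w <- fp$w
  d <- as.integer(round(force_delay * fs))
  alpha <- if (force_tau > 0) dt / force_tau else 1
  f_load <- numeric(n)
  dy <- 0; dv <- 0; ftrans <- 0
  dys <- numeric(n); dvs <- numeric(n); das <- numeric(n)
  for (i in seq_len(n)) {
    dys[i] <- dy; dvs[i] <- dv
    yi <- plan$y[i] + dy
    f_load[i] <- if (yi <= y0 - w) 0
      else if (w > 0 && yi < y0 + w) k * (yi - y0 + w)^2 / (4 * w)
      else k * (yi - y0)
    fd <- if (i > d) f_load[i - d] else 0
    ftrans <- ftrans + alpha * (fd - ftrans)
    dai <- -ftrans / m_eff
    das[i] <- dai
    dv <- dv + dai * dt
    dy <- dy + dv * dt
  }
  list(t = t, y = plan$y + dys, v = plan$v + dvs, a = plan$a + das,
       f_load = f_load, y_plan = plan$y, v_plan = plan$v, a_plan = plan$a,
       t_move = pre, T_seg = T_seg)
}
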