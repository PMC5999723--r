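#' Trial time-series container
#'
#' Uniformly sampled channels of one trial: time, vertical position, velocity,
#' acceleration, rendered elastic load force (zero on catch trials) and grip
#' force, plus a metadata list (identifiers, scheduled field, generative
#' ground truth where the trial is synthetic).
#'
#' @param t Time, s (uniform grid).
#' @param y Position, m.
#' @param v Velocity, m/s.
#' @param a Acceleration, m/s^2.
#' @param f_load Rendered elastic force, N (>= 0).
#' @param f_grip Grip force, N (> 0 throughout).
#' @param meta Named list of metadata.
#' @return Object of class `trial_series`.
#' @export
trial_series <- function(t, y, v, a, f_load, f_grip, meta = list()) {
  n <- length(t)
  if (!all(lengths(list(y, v, a, f_load, f_grip)) == n))
    stop("all channels must have the same length")
  if (n >= 3) {
    dts <- diff(t)
    if (max(abs(dts - dts[1])) > 1e-9)
      stop("non-uniform time base")
  }
  structure(list(t = t, y = y, v = v, a = a, f_load = f_load,
                 f_grip = f_grip, meta = meta),
            class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  m <- x$meta
  id <- if (length(m))
    sprintf(" p%s b%s t%s %s%s", m$participant, m$block, m$trial,
            substr(m$condition %||% "?", 1, 3),
            if (isTRUE(m$is_catch)) " [catch]" else "")
  else ""
  cat(sprintf("<trial_series>%s: %d samples @ %g Hz\n", id, length(x$t),
              1 / diff(x$t[1:2])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw a planned peak speed from the truncated normal prescription
.draw_vp <- function(cp) {
  repeat {
    vp <- stats::rnorm(1, cp$vp_mean, cp$vp_sd)
    if (vp >= 0.45 && vp <= 0.55) return(vp)
  }
}

#' Simulate one trial
#'
#' Draws a planned peak speed (truncated normal within 45-55 cm/s), simulates
#' the field-perturbed kinematics and the switched feedforward grip profile,
#' and adds position and grip measurement noise. Catch trials use the
#' identical grip construction with the expected impact time; their rendered
#' load force is zero.
#'
#' @param fp [field_params()] for the trial (carries the catch flag and, on
#'   catch trials, the scheduled expected field).
#' @param condition `"ascending"` or `"descending"`.
#' @param cp [controller_params()].
#' @param theta_eff Effective lag-switch threshold for this block
#'   ([effective_threshold()]).
#' @param fs Sampling rate, Hz.
#' @param meta Extra metadata (identifiers) merged into the result.
#' @return A [trial_series()] whose `meta` records the scheduled field and the
#'   generative ground truth (`lag_nominal_ms`, `lag_actual_ms`,
#'   `t_impact_true`, thresholds, planned peak speed).
#' @export
simulate_trial <- function(fp, condition, cp = controller_params(),
                           theta_eff = cp$theta_asc, fs = 500, meta = list()) {
  vp <- .draw_vp(cp)
  kin <- simulate_kinematics(vp, fp, m_eff = cp$m_eff, fs = fs,
                             amplitude = cp$amplitude,
                             force_delay = cp$force_delay,
                             force_tau = cp$force_tau)
  theta_cond <- if (condition == "ascending") cp$theta_asc else cp$theta_desc
  gp <- grip_profile(kin, fp, cp, theta_cond = theta_cond,
                     theta_eff = theta_eff)
  n <- length(kin$t)
  y_meas <- kin$y + stats::rnorm(n, 0, cp$pos_noise_sd)
  g_meas <- gp$f_grip + stats::rnorm(n, 0, cp$gf_noise_sd)
  meta <- c(meta, list(
    condition = condition, k_Npm = fp$k, y0_cm = 100 * fp$y0,
    lnk = log(fp$k), is_catch = fp$is_catch, w_m = fp$w,
    theta_cond = theta_cond, theta_eff = theta_eff,
    lag_nominal_ms = gp$lag_nominal_ms, lag_actual_ms = gp$lag_actual_ms,
    t_impact_true = gp$t_impact, vp_target = vp,
    t_move = kin$t_move, T_seg = kin$T_seg, fs = fs))
  trial_series(kin$t, y_meas, kin$v, kin$a, kin$f_load, g_meas, meta)
}

#' Simulate a full synthetic cohort
#'
#' Reproduces the experimental design: each participant performs 10 blocks of
#' 45 trials (5 ascending-stiffness and 5 descending-stiffness blocks; block
#' order per participant given by `order`), with 6 randomly placed catch
#' trials per block. All randomness is governed by `seed`; the same seed gives
#' bit-identical output.
#'
#' For large cohorts the raw series (roughly 40 MB per participant) need not
#' be retained: supply `trial_fun` to reduce each [trial_series()] to whatever
#' is needed (features, aligned windows, ...) as trials are generated.
#'
#' @param n_participants Number of participants (original design: 18).
#' @param order Block-order assignment: `"study"` (first 10 participants
#'   ascending-first, remainder descending-first), `"asc-first"`,
#'   `"desc-first"`, or a character vector of per-participant values.
#' @param cp [controller_params()].
#' @param seed Integer master seed.
#' @param n_blocks_per_condition Blocks per condition per participant (5).
#' @param fs Sampling rate, Hz.
#' @param trial_fun Optional `function(trial_series)`; when given, its return
#'   values are collected instead of the raw series.
#' @return List with `trials` (list of [trial_series()] or of `trial_fun`
#'   outputs, in generation order), `truth` (ground-truth data.frame, one row
#'   per trial), `cp`, and `seed`.
#' @export
simulate_cohort <- function(n_participants = 18, order = "study",
                            cp = controller_params(), seed = 1,
                            n_blocks_per_condition = 5, fs = 500,
                            trial_fun = NULL) {
  stopifnot(n_participants >= 1)
  if (length(order) == 1L && order == "study")
    order <- rep(c("asc-first", "desc-first"),
                 c(min(10L, n_participants), max(0L, n_participants - 10L)))
  order <- rep_len(order, n_participants)
  set.seed(seed)
  pseeds <- sample.int(.Machine$integer.max - 1L, n_participants)

  out <- vector("list", 0L)
  truth <- vector("list", 0L)
  nb <- n_blocks_per_condition
  for (p in seq_len(n_participants)) {
    set.seed(pseeds[p])
    # participant-level plant heterogeneity: effective mass and habitual speed
    cp_p <- cp
    repeat {
      cp_p$m_eff <- stats::rnorm(1, cp$m_eff, cp$m_eff_sd)
      if (cp_p$m_eff > 0.5 * cp$m_eff) break
    }
    repeat {
      cp_p$vp_mean <- stats::rnorm(1, cp$vp_mean, cp$vp_mean_sd)
      if (cp_p$vp_mean > 0.46 && cp_p$vp_mean < 0.54) break
    }
    conds <- if (order[p] == "asc-first")
      rep(c("ascending", "descending"), each = nb)
    else rep(c("descending", "ascending"), each = nb)
    for (b in seq_along(conds)) {
      sch <- make_schedule(conds[b])
      th_eff <- effective_threshold(sch$table$lnk, conds[b], cp_p)
      for (i in seq_len(nrow(sch$table))) {
        tr <- simulate_trial(sch$trials[[i]], conds[b], cp_p, th_eff, fs,
                             meta = list(participant = p, block = b,
                                         trial = i,
                                         mini_block = sch$table$mini_block[i]))
        m <- tr$meta
        truth[[length(truth) + 1L]] <- data.frame(
          participant = p, block = b, trial = i, condition = m$condition,
          mini_block = m$mini_block, k_Npm = m$k_Npm, y0_cm = m$y0_cm,
          lnk = m$lnk, is_catch = m$is_catch, theta_cond = m$theta_cond,
          theta_eff = m$theta_eff, lag_nominal_ms = m$lag_nominal_ms,
          lag_actual_ms = m$lag_actual_ms, t_impact_true = m$t_impact_true,
          vp_target = m$vp_target, seed = pseeds[p])
        out[[length(out) + 1L]] <-
          if (is.null(trial_fun)) tr else trial_fun(tr)
      }
    }
  }
  list(trials = out, truth = do.call(rbind, truth), cp = cp, seed = seed)
}

#' Write / read trial CSVs and a cohort manifest
#'
#' One CSV per trial with columns `t_s, y_m, v_mps, a_mps2, f_load_N,
#' f_grip_N`, plus a manifest CSV (one row per trial: identifiers, scheduled
#' field, catch flag, ground-truth lag, seed). The same layout is accepted for
#' externally recorded data.
#'
#' @param cohort Result of [simulate_cohort()] (with raw series).
#' @param dir Output directory (created if needed).
#' @return `write_cohort_csv`: the manifest path, invisibly.
#'   `read_trial_csv`: a [trial_series()].
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$trials))
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    if (!inherits(tr, "trial_series"))
      stop("write_cohort_csv needs raw trial series (trial_fun = NULL)")
    m <- tr$meta
    paths[i] <- sprintf("trial_p%02d_b%02d_t%02d.csv",
                        m$participant, m$block, m$trial)
    utils::write.csv(
      data.frame(t_s = tr$t, y_m = tr$y, v_mps = tr$v, a_mps2 = tr$a,
                 f_load_N = tr$f_load, f_grip_N = tr$f_grip),
      file.path(dir, paths[i]), row.names = FALSE)
  }
  manifest <- cbind(cohort$truth, file = paths)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' @param path Trial CSV path.
#' @param meta Metadata list (typically one manifest row as a list).
#' @rdname write_cohort_csv
#' @export
read_trial_csv <- function(path, meta = list()) {
  d <- utils::read.csv(path)
  need <- c("t_s", "y_m", "v_mps", "a_mps2", "f_load_N", "f_grip_N")
  if (!all(need %in% names(d)))
    stop("trial CSV must have columns ", paste(need, collapse = ", "))
  trial_series(d$t_s, d$y_m, d$v_mps, d$a_mps2, d$f_load_N, d$f_grip_N,
               meta = meta)
}
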