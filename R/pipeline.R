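#' Run configuration
#'
#' Bundles every knob of the pipeline: cohort size, block-order assignment,
#' controller parameters, filter settings, bootstrap settings and the output
#' directory. Serialized verbatim (YAML) into the output directory by
#' [run_all()].
#'
#' @param n_participants Cohort size.
#' @param order Block-order assignment (see [simulate_cohort()]).
#' @param cp [controller_params()].
#' @param seed Master seed.
#' @param fs Sampling rate, Hz.
#' @param cutoff Filter cutoff, Hz.
#' @param reps Bootstrap repetitions.
#' @param boot_seed Bootstrap seed.
#' @param n_blocks_per_condition Blocks per condition.
#' @param out_dir Output directory for [run_all()].
#' @return Object of class `run_config` (a list).
#' @export
run_config <- function(n_participants = 18, order = "study",
                       cp = controller_params(), seed = 1, fs = 500,
                       cutoff = 20, reps = 10000, boot_seed = 20180607,
                       n_blocks_per_condition = 5, out_dir = "results") {
  structure(list(n_participants = n_participants, order = order, cp = cp,
                 seed = seed, fs = fs, cutoff = cutoff, reps = reps,
                 boot_seed = boot_seed,
                 n_blocks_per_condition = n_blocks_per_condition,
                 out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_config`: a [run_config()].
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$cp <- unclass(x$cp)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cp <- do.call(controller_params, x$cp)
  x$cp <- NULL
  do.call(run_config, c(x, list(cp = cp)))
}

# time axis of the acceleration window relative to (expected) force onset
.win_rel <- function(fs = 500, lo = -0.06, hi = 0.30) {
  seq(round(lo * fs), round(hi * fs)) / fs
}

# reduce one trial to features + the force-onset-aligned acceleration window
.reduce_trial <- function(tr, cutoff = 20) {
  feats <- extract_features(tr, cutoff = cutoff)
  der <- derive_and_filter(tr, cutoff = cutoff)
  fs <- der$fs
  rel <- .win_rel(fs)
  y0 <- tr$meta$y0_cm / 100
  cross <- which(tr$y >= y0)[1]
  acc_win <- rep(NA_real_, length(rel))
  if (!is.na(cross)) {
    idx <- cross + round(rel * fs)
    inb <- idx >= 1 & idx <= length(tr$t)
    acc_win[inb] <- der$a[idx[inb]]
  }
  list(features = feats, acc_win = acc_win)
}

#' Simulate a cohort and extract per-trial features (streaming)
#'
#' Generates the synthetic cohort of [simulate_cohort()] and reduces every
#' trial on the fly to its scalar features plus a short acceleration window
#' aligned to the (expected) force onset, so raw series are never all held in
#' memory.
#'
#' @param config A [run_config()].
#' @return List with `features` (data.frame, one row per trial), `acc_win`
#'   (matrix, one row per trial), `win_t` (window time axis, s, relative to
#'   force onset), `truth`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  co <- simulate_cohort(
    n_participants = config$n_participants, order = config$order,
    cp = config$cp, seed = config$seed,
    n_blocks_per_condition = config$n_blocks_per_condition, fs = config$fs,
    trial_fun = function(tr) .reduce_trial(tr, cutoff = config$cutoff))
  features <- do.call(rbind, lapply(co$trials, `[[`, "features"))
  acc_win <- do.call(rbind, lapply(co$trials, `[[`, "acc_win"))
  list(features = features, acc_win = acc_win, win_t = .win_rel(config$fs),
       truth = co$truth, config = config)
}

# per-level means: aggregate y by (participant x) rounded lnk level
.level_means <- function(d, value, by_participant = TRUE) {
  d$lvl <- round(d$lnk, 9)
  if (by_participant)
    stats::aggregate(d[[value]], list(participant = d$participant,
                                      lvl = d$lvl), mean, na.rm = TRUE)
  else stats::aggregate(d[[value]], list(lvl = d$lvl), mean, na.rm = TRUE)
}

#' Cohort-level switching analysis
#'
#' Runs the full statistical battery on a feature table: per-condition
#' quartic extremum of grip peak versus ln(k) (cohort and per participant),
#' the hysteresis bootstrap (ascending minus descending extremum), the
#' averaged switch threshold in N/m, per-participant hinge fits of lag versus
#' ln(k) at the participant's own threshold with the slope-difference
#' bootstrap, cohort hinge-versus-line AIC comparison per condition, the
#' binned real-versus-catch acceleration divergence per mini-block, the
#' acceleration-sign threshold and its across-participant correlation with
#' the strategy threshold, the inertial-lag summary, and the catch-neighbor
#' grip-force-rate differences.
#'
#' @param pipe Result of [run_pipeline()] (or a compatible list with
#'   `features`, `acc_win`, `win_t`).
#' @param reps Bootstrap repetitions.
#' @param boot_seed Bootstrap seed.
#' @return Object of class `switch_result` (a nested list; see the elements
#'   in the source or `print()` it).
#' @export
analyze_cohort <- function(pipe, reps = 10000, boot_seed = 20180607) {
  f <- pipe$features
  parts <- sort(unique(f$participant))

  # --- extremum of grip peak vs ln k, per condition -----------------------
  ext <- list(); xstar_p <- list()
  for (cond in c("ascending", "descending")) {
    d <- f[f$condition == cond, ]
    lm_all <- .level_means(d, "gf_peak", by_participant = TRUE)
    grand <- stats::aggregate(lm_all$x, list(lvl = lm_all$lvl), mean)
    ext[[cond]] <- fit_extremum(grand$lvl, grand$x)
    xstar_p[[cond]] <- vapply(parts, function(p) {
      dp <- lm_all[lm_all$participant == p, ]
      fit_extremum(dp$lvl, dp$x)$x_star
    }, numeric(1))
  }
  x_asc <- ext$ascending$x_star
  x_desc <- ext$descending$x_star
  threshold_Npm <- (exp(x_asc) + exp(x_desc)) / 2
  thr_participant <- (xstar_p$ascending + xstar_p$descending) / 2
  hysteresis <- tryCatch(
    bootstrap_diff(xstar_p$ascending, xstar_p$descending,
                   reps = reps, seed = boot_seed,
                   label = "x* ascending - descending"),
    error = function(e) NULL)  # cohorts of < 3 participants

  # --- lags at the extreme stiffness levels -------------------------------
  lnk_max <- max(f$lnk); lnk_min <- min(f$lnk)
  at_max <- f$lnk > lnk_max - 1e-9 & !f$is_catch
  at_min <- f$lnk < lnk_min + 1e-9
  lag_stiff <- mean(f$lag_impact_ms[at_max], na.rm = TRUE)
  lag_soft <- mean(f$lag_impact_ms[at_min], na.rm = TRUE)

  # --- hinge fits of lag vs ln k ------------------------------------------
  pw_p <- lapply(parts, function(p) {
    dp <- .level_means(f[f$participant == p, ], "lag_impact_ms",
                       by_participant = FALSE)
    piecewise_fit(dp$lvl, dp$x, xb = thr_participant[match(p, parts)])
  })
  s_lo <- vapply(pw_p, `[[`, numeric(1), "s_lo")
  s_hi <- vapply(pw_p, `[[`, numeric(1), "s_hi")
  slope_boot <- tryCatch(
    bootstrap_diff(s_lo, s_hi, reps = reps, seed = boot_seed + 1,
                   statistic = "abs_mean_diff",
                   label = "|slope low - slope high|"),
    error = function(e) NULL)
  pw_cond <- lapply(c(ascending = "ascending", descending = "descending"),
                    function(cond) {
    d <- .level_means(f[f$condition == cond, ], "lag_impact_ms",
                      by_participant = FALSE)
    piecewise_fit(d$lvl, d$x, xb = mean(thr_participant))
  })

  # --- divergence of real vs catch acceleration per mini-block ------------
  t_div <- rep(NA_real_, 7)
  for (mb in 1:7) {
    rows_r <- which(f$mini_block == mb & !f$is_catch)
    rows_c <- which(f$mini_block == mb & f$is_catch)
    mr <- t(vapply(parts, function(p)
      colMeans(pipe$acc_win[rows_r[f$participant[rows_r] == p], ,
                            drop = FALSE]),
      numeric(ncol(pipe$acc_win))))
    mc <- t(vapply(parts, function(p)
      colMeans(pipe$acc_win[rows_c[f$participant[rows_c] == p], ,
                            drop = FALSE]),
      numeric(ncol(pipe$acc_win))))
    ok <- stats::complete.cases(mr) & stats::complete.cases(mc)
    if (sum(ok) >= 2) {
      dv <- divergence_time(mr[ok, , drop = FALSE], mc[ok, , drop = FALSE],
                            pipe$win_t)
      t_div[mb] <- dv$t_div
    }
  }
  divergence_ms <- 1000 * mean(t_div, na.rm = TRUE)

  # --- acceleration-sign threshold and correlation ------------------------
  acc_flip <- acc_sign_threshold(f$lnk, f$acc_at_field_onset)
  acc_flip_p <- vapply(parts, function(p) {
    dp <- f[f$participant == p, ]
    acc_sign_threshold(dp$lnk, dp$acc_at_field_onset)
  }, numeric(1))
  corr <- tryCatch(threshold_correlation(thr_participant, acc_flip_p),
                   error = function(e) list(r = NA_real_, p = NA_real_,
                                            n = sum(is.finite(acc_flip_p))))

  # --- inertial lag -------------------------------------------------------
  li <- f$lag_inertial_ms[is.finite(f$lag_inertial_ms)]
  inertial_t <- stats::t.test(li, mu = 0)
  lev <- .level_means(f[is.finite(f$lag_inertial_ms), ], "lag_inertial_ms",
                      by_participant = FALSE)
  trend <- stats::lm(x ~ lvl, data = lev)
  trend_ci <- stats::confint(trend)["lvl", ]

  # --- catch-neighbor grip-force-rate differences -------------------------
  nd <- do.call(rbind, lapply(split(f, list(f$participant, f$block),
                                    drop = TRUE), catch_neighbor_diffs))
  diffs <- c(nd$diff_prev, nd$diff_next)
  diffs <- diffs[is.finite(diffs)]
  nb_t <- if (length(diffs) >= 3) stats::t.test(diffs, mu = 0) else NULL

  structure(list(
    extremum = ext, xstar_participant = xstar_p,
    threshold_participant = thr_participant,
    threshold_Npm = threshold_Npm,
    threshold_Npm_geometric = exp((x_asc + x_desc) / 2),
    hysteresis = hysteresis,
    lag_stiff_ms = lag_stiff, lag_soft_ms = lag_soft,
    piecewise_participant = pw_p, s_lo = s_lo, s_hi = s_hi,
    slope_boot = slope_boot, piecewise_condition = pw_cond,
    t_div_ms = 1000 * t_div, divergence_ms = divergence_ms,
    acc_sign_lnk = acc_flip, acc_sign_participant = acc_flip_p,
    threshold_correlation = corr,
    inertial_lag_ms = mean(li), inertial_t = inertial_t,
    inertial_trend_ci = trend_ci,
    neighbor_diffs = nd, neighbor_t = nb_t,
    vp_mean_cms = 100 * mean(f$vp, na.rm = TRUE),
    n_participants = length(parts)), class = "switch_result")
}

#' @export
print.switch_result <- function(x, ...) {
  cat("Switching analysis (", x$n_participants, " participants)\n", sep = "")
  cat(sprintf("  grip-peak extremum: ln k = %.3f (asc), %.3f (desc)\n",
              x$extremum$ascending$x_star, x$extremum$descending$x_star))
  cat(sprintf("  averaged switch threshold: %.1f N/m\n", x$threshold_Npm))
  if (!is.null(x$hysteresis))
    cat(sprintf("  hysteresis CI: [%.3f, %.3f]%s\n", x$hysteresis$lo,
                x$hysteresis$hi,
                if (x$hysteresis$excludes_zero) " (excludes zero)" else ""))
  cat(sprintf("  lag: %.1f ms (stiffest), %.1f ms (softest)\n",
              x$lag_stiff_ms, x$lag_soft_ms))
  cat(sprintf("  slopes below/above threshold: %.2f / %.2f ms per ln-unit\n",
              mean(x$s_lo), mean(x$s_hi)))
  if (!is.null(x$slope_boot))
    cat(sprintf("  slope-difference CI: [%.2f, %.2f]%s\n", x$slope_boot$lo,
                x$slope_boot$hi,
                if (x$slope_boot$excludes_zero) " (excludes zero)" else ""))
  cat(sprintf("  AIC piecewise vs linear: %.1f < %.1f (asc), %.1f < %.1f (desc)\n",
              x$piecewise_condition$ascending$aic_piecewise,
              x$piecewise_condition$ascending$aic_linear,
              x$piecewise_condition$descending$aic_piecewise,
              x$piecewise_condition$descending$aic_linear))
  cat(sprintf("  real-catch acceleration divergence: %.0f ms after force onset\n",
              x$divergence_ms))
  cat(sprintf("  acceleration-sign threshold: ln k = %.3f\n", x$acc_sign_lnk))
  cat(sprintf("  inertial lag: %.2f ms (t-test vs 0: p = %.3f)\n",
              x$inertial_lag_ms, x$inertial_t$p.value))
  cat(sprintf("  mean peak velocity: %.1f cm/s\n", x$vp_mean_cms))
  invisible(x)
}

#' End-to-end reproduction run
#'
#' Executes simulate -> preprocess -> analyze and writes the manifest-style
#' ground-truth table, the feature table, the per-mini-block divergence and
#' per-participant results, plotting-ready long-format tables (grip peak and
#' lag versus ln stiffness; inertial lag; acceleration sign), the
#' configuration (YAML) and a human-readable summary into
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages?
#' @return The [analyze_cohort()] result, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say("simulating ", config$n_participants, " participants ...")
  pipe <- run_pipeline(config)
  say("analyzing ...")
  res <- analyze_cohort(pipe, reps = config$reps,
                        boot_seed = config$boot_seed)

  w <- function(d, name) utils::write.csv(
    d, file.path(config$out_dir, name), row.names = FALSE)
  w(pipe$truth, "truth.csv")
  w(pipe$features, "features.csv")
  w(data.frame(mini_block = 1:7, t_div_ms = res$t_div_ms), "divergence.csv")
  w(data.frame(participant = seq_along(res$threshold_participant),
               xstar_asc = res$xstar_participant$ascending,
               xstar_desc = res$xstar_participant$descending,
               threshold_lnk = res$threshold_participant,
               s_lo = res$s_lo, s_hi = res$s_hi,
               acc_sign_lnk = res$acc_sign_participant),
    "participants.csv")
  for (cond in c("ascending", "descending")) {
    d <- pipe$features[pipe$features$condition == cond, ]
    lm_gf <- .level_means(d, "gf_peak", by_participant = FALSE)
    lm_lag <- .level_means(d, "lag_impact_ms", by_participant = FALSE)
    lm_in <- .level_means(d[is.finite(d$lag_inertial_ms), ],
                          "lag_inertial_ms", by_participant = FALSE)
    w(data.frame(condition = cond, lnk = lm_gf$lvl, gf_peak = lm_gf$x,
                 lag_impact_ms = lm_lag$x,
                 lag_inertial_ms = lm_in$x[match(lm_gf$lvl, lm_in$lvl)]),
      paste0("curves_", substr(cond, 1, 4), ".csv"))
  }
  acc_lev <- .level_means(pipe$features, "acc_at_field_onset",
                          by_participant = FALSE)
  w(data.frame(lnk = acc_lev$lvl, acc_at_field_onset = acc_lev$x),
    "acc_sign.csv")
  write_config(config, file.path(config$out_dir, "config.yaml"))

  con <- file(file.path(config$out_dir, "summary.txt"), "w")
  sink(con); print(res); sink(); close(con)
  say("wrote results to ", config$out_dir)
  invisible(res)
}

#' Small deterministic fixture bundle
#'
#' Emits a 2-participant, 2-blocks-per-condition noiseless cohort (zero lag
#' noise, zero measurement noise) for exact ground-truth recovery tests, plus
#' hand-crafted pathological trials: `no_movement` (the hand never moves, so
#' onset detection must fail), `never_enters_field` (a small movement short of
#' the field boundary, so impact localization must fail) and
#' `double_peaked_grip` (two grip bumps of unequal height).
#'
#' @param seed Integer seed.
#' @return List with `cohort` (raw [simulate_cohort()] output) and
#'   `pathological` (named list of [trial_series()]).
#' @export
make_fixtures <- function(seed = 1) {
  cp0 <- controller_params(lag_sd = 0, pos_noise_sd = 0, gf_noise_sd = 0)
  cohort <- simulate_cohort(n_participants = 2, cp = cp0, seed = seed,
                            n_blocks_per_condition = 2)
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)
  meta0 <- list(participant = 99, block = 1, trial = 1,
                condition = "ascending", mini_block = 1,
                k_Npm = 100, y0_cm = 8, is_catch = FALSE, w_m = 0.001, fs = fs)
  no_movement <- trial_series(t, y = rep(0, length(t)),
                              v = rep(0, length(t)), a = rep(0, length(t)),
                              f_load = rep(0, length(t)),
                              f_grip = rep(2, length(t)), meta = meta0)
  small <- plan_trajectory(t, vp = 0.5, A = 0.05, t_move = 0.3)
  never_enters <- trial_series(t, small$y, small$v, small$a,
                               f_load = rep(0, length(t)),
                               f_grip = rep(2, length(t)),
                               meta = modifyList(meta0, list(is_catch = TRUE)))
  big <- plan_trajectory(t, vp = 0.5, A = 0.175, t_move = 0.3)
  grip2 <- 2 + 1.5 * exp(-(t - 0.8)^2 / (2 * 0.05^2)) +
    3 * exp(-(t - 1.1)^2 / (2 * 0.05^2))
  double_peak <- trial_series(t, big$y, big$v, big$a,
                              f_load = elastic_force(
                                big$y, field_params(100, 0.08)),
                              f_grip = grip2, meta = meta0)
  list(cohort = cohort,
       pathological = list(no_movement = no_movement,
                           never_enters_field = never_enters,
                           double_peaked_grip = double_peak))
}
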