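#' Build the 45-trial stiffness schedule for one block
#'
#' The experimental design couples the field-onset position and the stiffness:
#' onsets are linearly spaced from `y0_min` to `y0_max` in steps of exactly
#' 0.2875 cm (41 onsets), and the nominal peak force at the 15-cm target grows
#' linearly from `F_low` at the shallowest onset to `F_high` at the deepest, so
#' that stiffness `k(y0) = F_max(y0) / (0.15 - y0)` runs from
#' 4/0.12 = 33.33 N/m up to 14/0.005 = 2800 N/m. An ascending block presents
#' the 41 onsets in increasing-stiffness order followed by 4 plateau repeats of
#' the stiffest field; a descending block is the exact reverse. Six of the 45
#' trials are catch trials: their field is silently zeroed while the scheduled
#' `(k, y0)` pair is retained as the expected field.
#'
#' Catch positions are drawn uniformly without replacement, rejecting draws
#' that place two catch trials adjacently or leave any 5-trial mini-block
#' (see [mini_blocks()]) without a real trial.
#'
#' @param condition `"ascending"` or `"descending"`.
#' @param n_trials Trials per block (45).
#' @param n_catch Catch trials per block (6).
#' @param y0_min,y0_max Extreme onset positions, cm (3 and 14.5).
#' @param F_low,F_high Nominal target-peak forces at the extreme onsets, N.
#' @param step Onset grid step, cm (0.2875).
#' @param seed Optional integer seed for the catch-position draw. If `NULL`,
#'   the current RNG stream is used.
#' @return A `block_schedule`: list with `condition`, `trials` (list of 45
#'   [field_params()]), `catch_indices`, and a `table` data.frame with columns
#'   `trial`, `y0_cm`, `k_Npm`, `lnk`, `is_catch`, `mini_block`.
#' @examples
#' sch <- make_schedule("ascending", seed = 1)
#' range(sch$table$k_Npm)  # 33.33 ... 2800
#' @export
make_schedule <- function(condition = c("ascending", "descending"),
                          n_trials = 45L, n_catch = 6L,
                          y0_min = 3, y0_max = 14.5,
                          F_low = 4, F_high = 14,
                          step = 0.2875, seed = NULL) {
  condition <- match.arg(condition)
  if (n_catch >= n_trials) stop("n_catch must be smaller than n_trials")
  n_grid <- (y0_max - y0_min) / step
  if (abs(n_grid - round(n_grid)) > 1e-9)
    stop("schedule-construction error: onset range is not a multiple of the grid step")
  n_grid <- as.integer(round(n_grid)) + 1L
  n_plateau <- n_trials - n_grid
  if (n_plateau < 0L) stop("schedule-construction error: fewer trials than grid onsets")

  y0_cm <- y0_min + step * (seq_len(n_grid) - 1L)
  F_max <- F_low + (F_high - F_low) * (y0_cm - y0_min) / (y0_max - y0_min)
  k <- F_max / (0.15 - y0_cm / 100)

  # ascending: 41 increasing onsets then plateau repeats of the stiffest field
  y0_seq <- c(y0_cm, rep(y0_cm[n_grid], n_plateau))
  k_seq <- c(k, rep(k[n_grid], n_plateau))
  if (condition == "descending") {
    y0_seq <- rev(y0_seq)
    k_seq <- rev(k_seq)
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mb <- mini_blocks(seq_len(n_trials))
  repeat {
    catch_idx <- sort(sample.int(n_trials, n_catch))
    if (any(diff(catch_idx) == 1L)) next
    small <- which(tabulate(mb, 7L) == 5L)
    ok <- all(vapply(small, function(b) {
      idx <- which(mb == b)
      length(setdiff(idx, catch_idx)) > 0L
    }, logical(1)))
    if (ok) break
  }

  trials <- lapply(seq_len(n_trials), function(i)
    field_params(k = k_seq[i], y0 = y0_seq[i] / 100,
                 is_catch = i %in% catch_idx))
  tab <- data.frame(
    trial = seq_len(n_trials), y0_cm = y0_seq, k_Npm = k_seq,
    lnk = log(k_seq), is_catch = seq_len(n_trials) %in% catch_idx,
    mini_block = mb)
  structure(list(condition = condition, trials = trials,
                 catch_indices = catch_idx, table = tab),
            class = "block_schedule")
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule> %s, %d trials (%d catch), k in [%.4g, %.4g] N/m\n",
              x$condition, nrow(x$table), length(x$catch_indices),
              min(x$table$k_Npm), max(x$table$k_Npm)))
  invisible(x)
}

#' Mini-block labels for the 45 trials of a block
#'
#' Trials within a block are grouped into seven mini-blocks of sizes
#' 10, 5, 5, 5, 5, 5, 10 (in trial order) so that real and catch trials can be
#' compared at matched stiffness.
#'
#' @param trial_indices Integer trial indices 1..45 (any subset, any order).
#' @param n_trials Total trials per block; must be 45.
#' @return Integer mini-block labels (1-7), one per input index.
#' @examples
#' mini_blocks(c(1, 10, 11, 35, 45))  # 1 1 2 6 7
#' @export
mini_blocks <- function(trial_indices, n_trials = 45L) {
  sizes <- c(10L, 5L, 5L, 5L, 5L, 5L, 10L)
  if (n_trials != sum(sizes))
    stop("mini-block partition is defined for 45-trial blocks")
  if (any(trial_indices < 1L | trial_indices > n_trials))
    stop("trial indices out of range 1..45")
  findInterval(trial_indices, cumsum(sizes) - sizes + 1L)
}
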