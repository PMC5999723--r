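# shared fixtures, built once per test run

.fx <- new.env(parent = emptyenv())

# noiseless 2-participant mini-cohort (zero lag / measurement noise)
fx_noiseless <- function() {
  if (is.null(.fx$noiseless)) .fx$noiseless <- make_fixtures(seed = 11)
  .fx$noiseless
}

# small noisy cohort run through the streaming pipeline
fx_small_pipe <- function() {
  if (is.null(.fx$pipe)) {
    cfg <- run_config(n_participants = 3, seed = 7,
                      n_blocks_per_condition = 2, reps = 1000)
    .fx$pipe <- run_pipeline(cfg)
  }
  .fx$pipe
}

# full-scale cohort (18 participants, default configuration), built once
fx_study <- function() {
  if (is.null(.fx$study)) {
    cfg <- run_config(n_participants = 18, seed = 1, reps = 2000)
    pipe <- run_pipeline(cfg)
    res <- analyze_cohort(pipe, reps = 2000, boot_seed = 20180607)
    .fx$study <- list(pipe = pipe, res = res)
  }
  .fx$study
}

# a single noiseless stiffest real trial
fx_stiff_trial <- function() {
  if (is.null(.fx$stiff)) {
    cp0 <- controller_params(lag_sd = 0, pos_noise_sd = 0, gf_noise_sd = 0)
    set.seed(3)
    .fx$stiff <- simulate_trial(
      field_params(2800, 0.145), "ascending", cp0, theta_eff = 5.36,
      meta = list(participant = 1, block = 1, trial = 41, mini_block = 7))
  }
  .fx$stiff
}
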