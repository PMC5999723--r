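test_that("a full participant performs 10 x 45 trials with 13% catch", {
  co <- simulate_cohort(n_participants = 1, seed = 3,
                        trial_fun = function(tr) NULL)
  expect_equal(nrow(co$truth), 450)
  expect_equal(sum(co$truth$is_catch), 60)  # 6 per block
  per_block <- tapply(co$truth$is_catch, co$truth$block, sum)
  expect_true(all(per_block == 6))
  expect_equal(unname(table(co$truth$condition)), c(225L, 225L),
               ignore_attr = TRUE)
})

test_that("the same seed reproduces the cohort bit-identically", {
  a <- simulate_cohort(n_participants = 1, seed = 77,
                       n_blocks_per_condition = 1)
  b <- simulate_cohort(n_participants = 1, seed = 77,
                       n_blocks_per_condition = 1)
  expect_identical(a$truth, b$truth)
  expect_identical(a$trials[[17]]$y, b$trials[[17]]$y)
  expect_identical(a$trials[[17]]$f_grip, b$trials[[17]]$f_grip)
  # a different seed does not
  d <- simulate_cohort(n_participants = 1, seed = 78,
                       n_blocks_per_condition = 1)
  expect_false(identical(a$truth$vp_target, d$truth$vp_target))
})

test_that("trial series respect their structural invariants", {
  co <- fx_noiseless()$cohort
  for (tr in co$trials[c(1, 20, 45, 100)]) {
    expect_true(all(tr$f_load >= 0))
    expect_true(all(tr$f_grip > 0))  # grip never released
    expect_equal(length(unique(lengths(tr[c("t", "y", "v", "a", "f_load",
                                            "f_grip")]))), 1L)
  }
  # catch trials render no elastic force, yet the expected force is computable
  catch <- Filter(function(tr) tr$meta$is_catch, co$trials)[[1]]
  expect_equal(max(catch$f_load), 0)
  fp <- field_params(catch$meta$k_Npm, catch$meta$y0_cm / 100,
                     is_catch = TRUE)
  expect_gt(max(elastic_force(catch$y, fp, expected = TRUE)), 0)
  expect_error(trial_series(1:10 / 500, 1:9, 1:10, 1:10, 1:10, 1:10),
               "same length")
})

test_that("noiseless cohorts recover generative lags within one sample", {
  co <- fx_noiseless()$cohort
  feats <- do.call(rbind, lapply(co$trials, extract_features))
  expect_true(all(is.finite(feats$lag_impact_ms)))
  err <- feats$lag_impact_ms - co$truth$lag_actual_ms
  expect_lte(max(abs(err)), 2)  # one sample at 500 Hz
  # and across the full stiffness grid, not just on average
  expect_gt(length(unique(round(feats$lnk, 6))), 40)
})

test_that("trial CSVs and the manifest round-trip", {
  co <- simulate_cohort(n_participants = 1, seed = 5,
                        n_blocks_per_condition = 1)
  co$trials <- co$trials[1:3]
  co$truth <- co$truth[1:3, ]
  dir <- tempfile("cohort")
  mp <- write_cohort_csv(co, dir)
  man <- read.csv(mp)
  expect_equal(nrow(man), 3)
  tr0 <- co$trials[[2]]
  tr <- read_trial_csv(file.path(dir, man$file[2]),
                       meta = as.list(man[2, ]))
  expect_equal(tr$y, tr0$y, tolerance = 1e-12)
  expect_equal(tr$f_grip, tr0$f_grip, tolerance = 1e-12)
  ft0 <- extract_features(tr0)
  ft <- extract_features(tr)
  expect_equal(ft$lag_impact_ms, ft0$lag_impact_ms)
  unlink(dir, recursive = TRUE)
})
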