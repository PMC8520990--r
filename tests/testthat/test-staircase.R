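cond_quiet <- function() trial_condition(tone_stimulus("signal", 4, 0, 6))

test_that("same seed gives a bit-identical run", {
  l <- make_listener(run_noise = 1)
  cfg <- staircase_config_50trial()
  r1 <- run_staircase(cond_quiet(), l, cfg, seed = 77)
  r2 <- run_staircase(cond_quiet(), l, cfg, seed = 77)
  expect_identical(r1, r2)
  r3 <- run_staircase(cond_quiet(), l, cfg, seed = 78)
  expect_false(identical(r1$trials, r3$trials))
})

test_that("level moves by the step in force and obeys the schedule", {
  l <- make_listener()
  cfg <- staircase_config_50trial()
  run <- run_staircase(cond_quiet(), l, cfg, seed = 11)
  tr <- run$trials
  moves <- diff(tr$level_db)
  moved <- moves != 0
  expect_true(all(abs(moves[moved]) %in%
                    c(cfg$initial_step_db, cfg$final_step_db)))
  # the step never shrinks before the configured reversal index
  n_rev_before <- cumsum(dplyr::lag(tr$reversal, default = FALSE))
  expect_true(all(tr$step_db[n_rev_before < cfg$step_change_at_reversal] ==
                    cfg$initial_step_db))
  expect_true(all(tr$step_db[n_rev_before >= cfg$step_change_at_reversal] ==
                    cfg$final_step_db))
  # 50-trial regime stops at exactly 50 trials
  expect_identical(nrow(tr), 50L)
})

test_that("12-reversal regime stops at 12 reversals", {
  l <- make_listener()
  run <- run_staircase(cond_quiet(), l, staircase_config_12rev(), seed = 5)
  expect_identical(length(run$reversal_levels), 12L)
})

test_that("a near-step psychometric pins the track to the true threshold", {
  l <- make_listener(spread = 1e-6)
  run <- run_staircase(cond_quiet(), l, staircase_config_50trial(), seed = 3)
  expect_lt(abs(run$threshold_estimate_db - run$true_threshold_db), 2)
})

test_that("threshold extraction averages the final even reversal set", {
  run <- structure(list(reversal_levels = c(40, 36, 30, 34, 30, 34),
                        reversal_steps = c(5, 5, 2, 2, 2, 2)),
                   class = "staircase_run")
  cfg <- staircase_config_50trial()
  est <- extract_threshold(run, cfg)
  expect_equal(est$threshold_estimate_db, 32)
  expect_equal(est$reversal_sd_db, sd(c(30, 34, 30, 34)))
  # odd count at the final step: earliest dropped
  run$reversal_levels <- c(40, 36, 10, 30, 34, 30, 34)
  run$reversal_steps <- c(5, 5, 2, 2, 2, 2, 2)
  expect_equal(extract_threshold(run, cfg)$threshold_estimate_db, 32)
  # all-equal reversals have zero SD
  run$reversal_levels <- rep(28, 6)
  run$reversal_steps <- rep(2, 6)
  expect_equal(extract_threshold(run, cfg)$reversal_sd_db, 0)
  # no final-step reversals at all
  run$reversal_steps <- rep(5, 6)
  expect_error(extract_threshold(run, cfg),
               class = "mocgain_extraction_failure")
  # final-8 mode ignores step sizes
  cfg12 <- staircase_config_12rev()
  run$reversal_levels <- c(50, 1:8 * 2)
  run$reversal_steps <- c(5, rep(2, 8))
  expect_equal(extract_threshold(run, cfg12)$threshold_estimate_db,
               mean(1:8 * 2))
})

test_that("QC applies the strict 5-dB and six-reversal rules", {
  cfg <- staircase_config_50trial()
  base <- structure(list(reversal_levels = rep(30, 6),
                         reversal_steps = rep(2, 6), reversal_sd_db = 5,
                         bounds_hit = FALSE), class = "staircase_run")
  expect_true(qc_run(base, cfg)$pass)          # exactly 5 dB passes
  base$reversal_sd_db <- 5.01
  expect_false(qc_run(base, cfg)$pass)
  base$reversal_sd_db <- 6
  expect_false(qc_run(base, cfg)$pass)
  few <- base; few$reversal_levels <- rep(30, 5); few$reversal_sd_db <- 1
  expect_false(qc_run(few, cfg)$pass)
  bounds <- base; bounds$bounds_hit <- TRUE; bounds$reversal_sd_db <- 1
  expect_false(qc_run(bounds, cfg)$pass)
})

test_that("masker tracking converges on the masker threshold", {
  l <- make_listener(run_noise = 0)
  cfg <- staircase_config_50trial(tracked = "masker", start_offset_db = -10)
  cond <- trial_condition(sig4k(30), masker24k(65))
  ests <- sapply(1:60, function(s)
    run_staircase(cond, l, cfg, seed = s, true_threshold_db = 70)$threshold_estimate_db)
  expect_lt(abs(mean(ests, na.rm = TRUE) - 70), 1.5)
})

test_that("stationary oracle is translation-equivariant and concentrates", {
  pfun <- function(theta) function(x) percent_correct_3ifc(x, theta, 4)
  grid0 <- seq(10, 70, by = 2)
  o1 <- staircase_asymptote(pfun(40), 2, grid0)
  o2 <- staircase_asymptote(pfun(50), 2, grid0 + 10)
  expect_equal(o2$mean_level_db - o1$mean_level_db, 10, tolerance = 1e-9)
  # near-step psychometric: mass concentrates within one step of theta
  steep <- function(x) percent_correct_3ifc(x, 40, 0.01)
  o3 <- staircase_asymptote(steep, 2, grid0)
  near <- abs(o3$stationary$level_db - 40) <= 2
  expect_gt(sum(o3$stationary$occupancy[near]), 0.95)
})

test_that("simulator mean matches the stationary oracle on varied shapes", {
  l <- make_listener(run_noise = 0)
  cfg <- staircase_config_50trial()
  for (spread in c(2, 4, 8)) {
    l$psychometric_spread_db <- spread
    theta <- 30
    ests <- sapply(1:300, function(s)
      run_staircase(cond_quiet(), l, cfg, seed = s,
                    true_threshold_db = theta)$threshold_estimate_db)
    grid <- seq(theta - 40, theta + 40, by = 2)
    oracle <- staircase_asymptote(
      function(x) percent_correct_3ifc(x, theta, spread), 2, grid)
    expect_lt(abs(mean(ests, na.rm = TRUE) - oracle$mean_level_db), 0.5)
  }
})

test_that("threshold estimates track a shifted generative threshold", {
  l <- make_listener(run_noise = 0)
  cfg <- staircase_config_50trial()
  m1 <- mean(sapply(1:150, function(s)
    run_staircase(cond_quiet(), l, cfg, seed = s,
                  true_threshold_db = 20)$threshold_estimate_db), na.rm = TRUE)
  m2 <- mean(sapply(1:150, function(s)
    run_staircase(cond_quiet(), l, cfg, seed = s,
                  true_threshold_db = 35)$threshold_estimate_db), na.rm = TRUE)
  expect_equal(m2 - m1, 15, tolerance = 0.5)
})
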