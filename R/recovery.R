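#' Tracking-calibration study for the 2-down/1-up simulator
#'
#' Simulates many adaptive tracks on a listener with a known Gaussian-CDF
#' 3IFC psychometric function and a fixed generative threshold, and
#' evaluates where on the psychometric function the mean threshold
#' estimate sits. A well-calibrated 2-down/1-up track converges on the
#' 70.7%-correct point. The exact Markov-chain asymptote
#' ([staircase_asymptote()]) is computed alongside as an independent
#' reference.
#'
#' @param n_runs Number of simulated tracks (default 200).
#' @param seed Integer seed.
#' @param spread_db Psychometric spread in dB.
#' @param true_threshold_db Generative threshold in dB SPL.
#' @param cfg A [staircase_config()]; default the 50-trial regime.
#' @return A list: `mean_estimate_db`, `percent_correct_at_mean` (on the
#'   generative function, in percent), `oracle_mean_db`, `n_runs` (tracks
#'   contributing an estimate).
#' @export
simulate_tracking_calibration <- function(n_runs = 200, seed = 1,
                                          spread_db = 4,
                                          true_threshold_db = 30,
                                          cfg = staircase_config_50trial()) {
  l <- listener(
    id = "calib", quiet_threshold_db_spl = true_threshold_db,
    io = io_function(40, 0.3, 40), off_freq_attenuation_db = 9,
    psychometric_spread_db = spread_db, run_noise_sd_db = 0,
    gain_rule = gain_rule("mechanistic", elicitation_slope = 0.8,
                          elicitation_floor = 45, cap_db = 25))
  cond <- trial_condition(tone_stimulus("signal", l$signal_freq_khz, 0, 6))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  ests <- vapply(seeds, function(s) {
    run_staircase(cond, l, cfg, s,
                  true_threshold_db = true_threshold_db)$threshold_estimate_db
  }, numeric(1))
  ests <- ests[!is.na(ests)]
  m <- mean(ests)
  grid <- seq(true_threshold_db - 40, true_threshold_db + 40,
              by = cfg$final_step_db)
  oracle <- staircase_asymptote(
    function(x) percent_correct_3ifc(x, true_threshold_db, spread_db),
    cfg$final_step_db, grid)
  list(mean_estimate_db = m,
       percent_correct_at_mean =
         100 * percent_correct_3ifc(m, true_threshold_db, spread_db),
       oracle_mean_db = oracle$mean_level_db,
       n_runs = length(ests))
}

#' Parameter-recovery study for the gain-reduction mixed model
#'
#' Repeatedly draws synthetic cohorts from the generative hierarchical
#' model ([generate_threshold_dataset()]), applies the floor filter, fits
#' the matching mixed-effects structure ([fit_gain_reduction_lmm()]), and
#' averages the fitted fixed effects across replicates. This is the
#' package's evidence that the estimation pipeline recovers the growth
#' slopes it is meant to measure under realistic cohort sizes, run counts
#' and floor censoring.
#'
#' @param params A [cohort_params()]; its `random_structure` selects the
#'   fitted model.
#' @param n_cohorts Number of replicate cohorts (default 50).
#' @param seed Integer seed.
#' @param floor_db Floor filter threshold in dB; `NULL` disables filtering.
#' @return A list with `mean_fixed` (named mean fitted fixed effects),
#'   `fits` (tibble of per-replicate estimates), and `n_converged`.
#' @export
simulate_lmm_recovery <- function(params, n_cohorts = 50, seed = 1,
                                  floor_db = 4) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_cohorts)
  rows <- vector("list", n_cohorts)
  n_converged <- 0L
  for (i in seq_len(n_cohorts)) {
    d <- generate_threshold_dataset(params, seed = seeds[i])
    if (!is.null(floor_db)) d <- floor_filter(d, floor_db)
    fit <- suppressWarnings(
      fit_gain_reduction_lmm(d, params$random_structure))
    if (fit$converged) n_converged <- n_converged + 1L
    est <- setNames(fit$fixed$estimate, fit$fixed$term)
    rows[[i]] <- tibble::tibble(replicate = i, term = names(est),
                                estimate = unname(est))
  }
  fits <- dplyr::bind_rows(rows)
  mean_fixed <- tapply(fits$estimate, fits$term, mean)
  list(mean_fixed = mean_fixed, fits = fits, n_converged = n_converged)
}
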