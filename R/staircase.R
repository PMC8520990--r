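#' Adaptive-track configuration
#'
#' Parameters of a transformed up-down (2-down/1-up) track. Two stopping
#' regimes are supported, matching the two procedures used across the
#' experiments the package models:
#' * `stop_rule = "fixed_trials"` (default 50 trials): step 5 dB until the
#'   second reversal, then 2 dB; threshold is the mean of the final even
#'   number of reversals at the 2-dB step.
#' * `stop_rule = "fixed_reversals"` (default 12 reversals): step 5 dB until
#'   the fourth reversal, then 2 dB; threshold is the mean of the final
#'   eight reversals.
#'
#' @param tracked `"signal"` (level lowered after 2 correct) or `"masker"`
#'   (level raised after 2 correct, tracking the lowest masker level at
#'   which the fixed signal is detectable).
#' @param initial_step_db,final_step_db Step sizes in dB (> 0).
#' @param step_change_at_reversal Reversal count after which the final step
#'   size is in force.
#' @param stop_rule `"fixed_trials"` or `"fixed_reversals"`.
#' @param stop_n Number of trials or reversals for the stopping rule.
#' @param averaging `"final_even_at_final_step"` or `"final_8_reversals"`.
#' @param start_offset_db Starting level relative to the generative
#'   threshold, in dB.
#' @param level_bounds_db Length-2 numeric, allowed level range in dB SPL.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(tracked = c("signal", "masker"),
                             initial_step_db = 5, final_step_db = 2,
                             step_change_at_reversal = 2,
                             stop_rule = c("fixed_trials", "fixed_reversals"),
                             stop_n = NULL,
                             averaging = c("final_even_at_final_step",
                                           "final_8_reversals"),
                             start_offset_db = 10,
                             level_bounds_db = c(-20, 120)) {
  tracked <- match.arg(tracked)
  stop_rule <- match.arg(stop_rule)
  averaging <- match.arg(averaging)
  if (is.null(stop_n)) {
    stop_n <- if (stop_rule == "fixed_trials") 50 else 12
  }
  if (initial_step_db <= 0 || final_step_db <= 0 || stop_n <= 0 ||
      step_change_at_reversal <= 0) {
    stop_invalid("step sizes and stopping parameters must be positive")
  }
  if (length(level_bounds_db) != 2 || diff(level_bounds_db) <= 0) {
    stop_invalid("`level_bounds_db` must be an increasing length-2 range")
  }
  structure(
    list(tracked = tracked, initial_step_db = initial_step_db,
         final_step_db = final_step_db,
         step_change_at_reversal = step_change_at_reversal,
         stop_rule = stop_rule, stop_n = stop_n, averaging = averaging,
         start_offset_db = start_offset_db,
         level_bounds_db = level_bounds_db),
    class = "staircase_config"
  )
}

#' Configurations of the two tracking procedures
#'
#' `staircase_config_50trial()` is the 50-trial regime (step change at the
#' second reversal, final even reversals at the 2-dB step averaged);
#' `staircase_config_12rev()` is the 12-reversal regime (step change at the
#' fourth reversal, final eight reversals averaged).
#'
#' @param ... Overrides passed to [staircase_config()].
#' @return A [staircase_config()].
#' @export
staircase_config_50trial <- function(...) {
  staircase_config(stop_rule = "fixed_trials", stop_n = 50,
                   step_change_at_reversal = 2,
                   averaging = "final_even_at_final_step", ...)
}

#' @rdname staircase_config_50trial
#' @export
staircase_config_12rev <- function(...) {
  staircase_config(stop_rule = "fixed_reversals", stop_n = 12,
                   step_change_at_reversal = 4,
                   averaging = "final_8_reversals", ...)
}

#' Simulate one adaptive track
#'
#' Runs a 2-down/1-up track against a listener's generative psychometric
#' function. The generative ("model-true") threshold is the power-spectrum
#' prediction under the gain-reduction hypothesis plus a single per-run
#' Gaussian offset (SD `run_noise_sd_db`), emulating between-run threshold
#' variability. Responses are Bernoulli draws from
#' [percent_correct_3ifc()]. Signal tracking lowers the level after two
#' consecutive correct responses and raises it after any incorrect
#' response; masker tracking inverts the direction so the track converges
#' on the lowest masker level at which the fixed signal is detectable.
#'
#' @param cond A [trial_condition()].
#' @param listener A [listener()].
#' @param cfg A [staircase_config()].
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param true_threshold_db Optional override of the generative threshold
#'   (bypasses [predicted_threshold()]); used mainly for calibration
#'   studies against the Markov-chain oracle.
#' @return An object of class `staircase_run`: a list with the trial table
#'   (`trials`: level, correct, reversal, step in force), `reversal_levels`,
#'   `reversal_steps`, `threshold_estimate_db`, `reversal_sd_db`, `qc_pass`,
#'   `qc_reason`, `true_threshold_db` and `seed`.
#' @export
run_staircase <- function(cond, listener, cfg, seed,
                          true_threshold_db = NULL) {
  stopifnot(inherits(cfg, "staircase_config"), inherits(listener, "listener"))
  set.seed(seed)
  if (is.null(true_threshold_db)) {
    true_threshold_db <- as.numeric(predicted_threshold(cond, listener,
                                                        "gain_reduction")) +
      rnorm(1, 0, listener$run_noise_sd_db)
  }
  sigma <- listener$psychometric_spread_db
  # direction of the level change after 2 consecutive correct responses
  dir2c <- if (cfg$tracked == "signal") -1 else +1

  level <- true_threshold_db + cfg$start_offset_db
  level <- clamp(level, cfg$level_bounds_db[1], cfg$level_bounds_db[2])
  n_correct <- 0L
  last_move <- 0L
  n_rev <- 0L
  bounds_hit <- FALSE
  levels <- correct <- reversal <- step_rec <- numeric(0)
  rev_levels <- rev_steps <- numeric(0)

  trial <- 0L
  repeat {
    trial <- trial + 1L
    step <- if (n_rev >= cfg$step_change_at_reversal) cfg$final_step_db else
      cfg$initial_step_db
    # for masker tracking the psychometric falls with the tracked level
    p <- if (cfg$tracked == "signal") {
      percent_correct_3ifc(level, true_threshold_db, sigma)
    } else {
      percent_correct_3ifc(true_threshold_db, level, sigma)
    }
    is_correct <- runif(1) < p
    move <- 0L
    if (is_correct) {
      n_correct <- n_correct + 1L
      if (n_correct == 2L) {
        move <- dir2c
        n_correct <- 0L
      }
    } else {
      move <- -dir2c
      n_correct <- 0L
    }
    is_reversal <- FALSE
    if (move != 0L) {
      if (last_move != 0L && move != last_move) {
        is_reversal <- TRUE
        n_rev <- n_rev + 1L
        rev_levels <- c(rev_levels, level)
        rev_steps <- c(rev_steps, step)
      }
      last_move <- move
    }
    levels <- c(levels, level)
    correct <- c(correct, is_correct)
    reversal <- c(reversal, is_reversal)
    step_rec <- c(step_rec, step)
    if (move != 0L) {
      new_level <- level + move * step
      if (new_level < cfg$level_bounds_db[1] ||
          new_level > cfg$level_bounds_db[2]) {
        bounds_hit <- TRUE
        new_level <- clamp(new_level, cfg$level_bounds_db[1],
                           cfg$level_bounds_db[2])
      }
      level <- new_level
    }
    done <- if (cfg$stop_rule == "fixed_trials") trial >= cfg$stop_n else
      n_rev >= cfg$stop_n
    if (done) break
  }

  run <- structure(
    list(trials = tibble::tibble(trial = seq_along(levels),
                                 level_db = levels,
                                 correct = as.logical(correct),
                                 reversal = as.logical(reversal),
                                 step_db = step_rec),
         reversal_levels = rev_levels, reversal_steps = rev_steps,
         threshold_estimate_db = NA_real_, reversal_sd_db = NA_real_,
         bounds_hit = bounds_hit, qc_pass = NA, qc_reason = NA_character_,
         true_threshold_db = true_threshold_db, seed = seed),
    class = "staircase_run"
  )
  est <- tryCatch(extract_threshold(run, cfg), mocgain_error = function(e) NULL)
  if (!is.null(est)) {
    run$threshold_estimate_db <- est$threshold_estimate_db
    run$reversal_sd_db <- est$reversal_sd_db
  }
  qc <- qc_run(run, cfg)
  run$qc_pass <- qc$pass
  run$qc_reason <- qc$reason
  run
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf(
    "<staircase_run> %d trials, %d reversals, estimate %.2f dB (SD %.2f), QC %s\n",
    nrow(x$trials), length(x$reversal_levels), x$threshold_estimate_db,
    x$reversal_sd_db, if (isTRUE(x$qc_pass)) "pass" else
      paste0("fail (", x$qc_reason, ")")))
  invisible(x)
}

#' Threshold estimate from a completed track
#'
#' Averages reversal levels according to the configured rule: either the
#' final even number of reversals at the final (2-dB) step size -- dropping
#' the earliest if their count is odd -- or the final eight reversals
#' regardless of step. The SD of the same reversal set is returned for
#' run-level quality control.
#'
#' @param run A [run_staircase()] result.
#' @param cfg The [staircase_config()] used.
#' @return A list with `threshold_estimate_db` and `reversal_sd_db`.
#' @export
extract_threshold <- function(run, cfg) {
  stopifnot(inherits(run, "staircase_run"), inherits(cfg, "staircase_config"))
  if (cfg$averaging == "final_even_at_final_step") {
    sel <- run$reversal_levels[run$reversal_steps == cfg$final_step_db]
    if (length(sel) == 0) {
      stop_invalid("no reversals at the final step size",
                   class = "mocgain_extraction_failure")
    }
    if (length(sel) %% 2 == 1) sel <- sel[-1]
    if (length(sel) == 0) {
      stop_invalid("fewer than two reversals at the final step size",
                   class = "mocgain_extraction_failure")
    }
  } else {
    if (length(run$reversal_levels) < 8) {
      stop_invalid("fewer than eight reversals available",
                   class = "mocgain_extraction_failure")
    }
    sel <- utils::tail(run$reversal_levels, 8)
  }
  list(threshold_estimate_db = mean(sel),
       reversal_sd_db = if (length(sel) > 1) sd(sel) else 0)
}

#' Run-level quality control
#'
#' A run fails QC if the reversal SD entering the threshold estimate
#' exceeds 5 dB (strict inequality: 5.0 passes), if fewer than six
#' reversals are present in total, or if the track hit the level bounds.
#'
#' @param run A [run_staircase()] result.
#' @param cfg The [staircase_config()] used.
#' @param max_sd_db Exclusion threshold for the reversal SD (default 5 dB).
#' @param min_reversals Minimum total reversal count (default 6).
#' @return A list with logical `pass` and a `reason` string (`NA` on pass).
#' @export
qc_run <- function(run, cfg, max_sd_db = 5, min_reversals = 6) {
  stopifnot(inherits(run, "staircase_run"))
  if (isTRUE(run$bounds_hit)) {
    return(list(pass = FALSE, reason = "level bounds hit"))
  }
  if (length(run$reversal_levels) < min_reversals) {
    return(list(pass = FALSE,
                reason = sprintf("fewer than %d reversals", min_reversals)))
  }
  if (is.na(run$reversal_sd_db)) {
    return(list(pass = FALSE, reason = "threshold extraction failed"))
  }
  if (run$reversal_sd_db > max_sd_db) {
    return(list(pass = FALSE,
                reason = sprintf("reversal SD %.2f > %g dB",
                                 run$reversal_sd_db, max_sd_db)))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Exact asymptote of the 2-down/1-up rule
#'
#' Independent convergence oracle for [run_staircase()]: builds the discrete
#' Markov chain over (level, consecutive-correct-count) states of the
#' 2-down/1-up automaton in its final-step regime on a bounded level grid,
#' solves for the stationary distribution, and returns the stationary mean
#' level. The automaton balances exactly where the psychometric function
#' crosses `sqrt(1/2)` (70.7% correct), so for the anchored 3IFC
#' psychometric the asymptote sits at the generative threshold.
#'
#' @param pcorrect A function mapping level (dB) to probability correct.
#' @param step_db Step size of the final regime in dB.
#' @param level_grid Numeric vector of admissible levels in `step_db`
#'   increments (clamped at its ends).
#' @return A list with `mean_level_db` (stationary mean) and `stationary`
#'   (a tibble of level, occupancy).
#' @export
staircase_asymptote <- function(pcorrect, step_db, level_grid) {
  stopifnot(is.function(pcorrect), step_db > 0)
  m <- length(level_grid)
  if (m < 3) stop_invalid("`level_grid` needs at least 3 levels")
  if (any(abs(diff(level_grid) - step_db) > 1e-8)) {
    stop_invalid("`level_grid` must be spaced in `step_db` increments")
  }
  p <- pcorrect(level_grid)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_invalid("`pcorrect` must return probabilities on the grid",
                 class = "mocgain_oracle_failure")
  }
  # states: (i, cc) with cc in {0, 1}; index = i + cc * m
  up <- pmin(seq_len(m) + 1L, m)
  down <- pmax(seq_len(m) - 1L, 1L)
  P <- matrix(0, 2 * m, 2 * m)
  for (i in seq_len(m)) {
    # from (i, 0): correct -> (i, 1); incorrect -> (up, 0)
    P[i, i + m] <- p[i]
    P[i, up[i]] <- P[i, up[i]] + (1 - p[i])
    # from (i, 1): correct -> (down, 0); incorrect -> (up, 0)
    P[i + m, down[i]] <- p[i]
    P[i + m, up[i]] <- P[i + m, up[i]] + (1 - p[i])
  }
  # stationary distribution: solve pi (P - I) = 0 with sum(pi) = 1
  A <- t(P) - diag(2 * m)
  A[2 * m, ] <- 1
  b <- c(rep(0, 2 * m - 1), 1)
  pi_vec <- tryCatch(solve(A, b), error = function(e) {
    stop_invalid("stationary distribution is not unique on this grid",
                 class = "mocgain_oracle_failure")
  })
  if (any(pi_vec < -1e-8)) {
    stop_invalid("stationary solve produced negative mass",
                 class = "mocgain_oracle_failure")
  }
  occ <- pi_vec[seq_len(m)] + pi_vec[seq_len(m) + m]
  list(mean_level_db = sum(occ * level_grid),
       stationary = tibble::tibble(level_db = level_grid, occupancy = occ))
}
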