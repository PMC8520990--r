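#' Generative parameters for a synthetic cohort
#'
#' Describes the hierarchical linear model from which synthetic
#' gain-reduction datasets are drawn: fixed effects (intercept, level
#' slope, per-class offsets and level-by-class interactions, with the
#' on-frequency tone as reference), between-participant variance
#' components, residual noise, the per-class precursor level grids, and
#' the number of runs per condition.
#'
#' Two presets mirror the two study designs the package models:
#' * [cohort_params_tonal()]: 7 participants, on- and off-frequency tonal
#'   precursors (on-tone grid 20-90 dB SPL, off-tone 60-95 dB SPL),
#'   by-participant random intercepts and per-class offsets.
#' * [cohort_params_bbn()]: 4 participants, tonal classes plus a broadband
#'   noise whose overall levels 24-64 dB SPL (capped at 64 dB to stay
#'   clear of the middle-ear-muscle reflex) enter the model in dB/ERB at
#'   the 4-kHz place; random intercepts only.
#'
#' @param n_participants Number of participants.
#' @param fixed Named numeric vector of fixed effects: `intercept`,
#'   `level`, and optionally `off_tone`, `bbn`, `level:off_tone`,
#'   `level:bbn`.
#' @param sd_intercept Between-participant SD of intercepts (dB).
#' @param sd_class_offset Between-participant SD of the per-class offset
#'   (dB); 0 for an intercepts-only structure.
#' @param cor_intercept_class Correlation between random intercepts and
#'   class offsets.
#' @param sd_residual Residual SD (dB).
#' @param runs_per_condition Observations per (participant, class, level).
#' @param levels Named list of per-class level grids: `on_tone` and
#'   `off_tone` in dB SPL, `bbn_overall` in overall dB SPL (converted to
#'   dB/ERB internally).
#' @param random_structure `"slopes"` or `"intercepts"` (the matching fit
#'   structure).
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_participants, fixed, sd_intercept,
                          sd_class_offset = 0, cor_intercept_class = 0,
                          sd_residual, runs_per_condition = 2, levels,
                          random_structure = c("slopes", "intercepts")) {
  random_structure <- match.arg(random_structure)
  if (n_participants < 1) stop_invalid("`n_participants` must be >= 1")
  if (sd_intercept < 0 || sd_class_offset < 0 || sd_residual < 0) {
    stop_invalid("variance-component SDs must be >= 0")
  }
  if (abs(cor_intercept_class) > 1) {
    stop_invalid("`cor_intercept_class` must lie in [-1, 1]")
  }
  if (!all(c("intercept", "level") %in% names(fixed))) {
    stop_invalid("`fixed` needs at least `intercept` and `level`")
  }
  if (!is.list(levels) || is.null(names(levels)) ||
      !"on_tone" %in% names(levels)) {
    stop_invalid("`levels` must be a named list including `on_tone`")
  }
  if (!is.null(levels$bbn_overall) && any(levels$bbn_overall > 64)) {
    stop_invalid("broadband-noise overall levels are capped at 64 dB SPL")
  }
  structure(
    list(n_participants = n_participants, fixed = fixed,
         sd_intercept = sd_intercept, sd_class_offset = sd_class_offset,
         cor_intercept_class = cor_intercept_class,
         sd_residual = sd_residual,
         runs_per_condition = runs_per_condition, levels = levels,
         random_structure = random_structure),
    class = "cohort_params"
  )
}

#' @rdname cohort_params
#' @param ... Overrides forwarded to [cohort_params()].
#' @export
cohort_params_tonal <- function(...) {
  defaults <- list(
    n_participants = 7,
    fixed = c(intercept = -4.32, level = 0.33, off_tone = -49.47,
              `level:off_tone` = 0.47),
    sd_intercept = sqrt(31.23), sd_class_offset = sqrt(16.18),
    cor_intercept_class = -0.02, sd_residual = sqrt(11.98),
    runs_per_condition = 2,
    levels = list(on_tone = seq(20, 90, by = 10),
                  off_tone = seq(60, 95, by = 5)),
    random_structure = "slopes")
  do.call(cohort_params, utils::modifyList(defaults, list(...)))
}

#' @rdname cohort_params
#' @export
cohort_params_bbn <- function(...) {
  defaults <- list(
    n_participants = 4,
    fixed = c(intercept = -3.40, level = 0.29, off_tone = -47.50,
              bbn = 1.52, `level:off_tone` = 0.46, `level:bbn` = 0.11),
    sd_intercept = sqrt(48.90), sd_class_offset = 0,
    cor_intercept_class = 0, sd_residual = sqrt(15.62),
    runs_per_condition = 2,
    levels = list(on_tone = seq(20, 90, by = 10),
                  off_tone = seq(60, 95, by = 5),
                  bbn_overall = seq(24, 64, by = 10)),
    random_structure = "intercepts")
  do.call(cohort_params, utils::modifyList(defaults, list(...)))
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf(
    "<cohort_params> %d participants, %d runs/condition, classes: %s (%s)\n",
    x$n_participants, x$runs_per_condition,
    paste(names(x$levels), collapse = ", "), x$random_structure))
  invisible(x)
}

# fixed-effect linear predictor for one class at given levels
.linear_predictor <- function(fixed, class, level) {
  out <- fixed[["intercept"]] + fixed[["level"]] * level
  if (class != "on_tone") {
    out <- out + fixed[[class]] + fixed[[paste0("level:", class)]] * level
  }
  out
}

#' Draw a gain-reduction dataset from the generative mixed model
#'
#' Samples per-participant random effects (intercepts and, for the
#' `"slopes"` structure, correlated per-class offsets) from the configured
#' Gaussians, evaluates the fixed-effect linear predictor on each class's
#' level grid, and adds residual Gaussian noise per observation. Broadband
#' noise levels are converted from overall dB SPL to dB/ERB at 4 kHz
#' before entering the predictor, and both scales are reported. Negative
#' estimates are preserved; apply [floor_filter()] before fitting if floor
#' effects should be excluded.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @return A tibble with columns `participant`, `precursor_class`,
#'   `level_db` (dB SPL for tones, dB/ERB for noise), `level_overall_db`
#'   (overall dB SPL; equals `level_db` for tones), `run`, `estimate_db`.
#' @export
generate_threshold_dataset <- function(params, seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  n <- params$n_participants
  # correlated (intercept, class-offset) pairs via Cholesky of the 2x2 cov
  b0 <- rnorm(n, 0, params$sd_intercept)
  z <- rnorm(n)
  rho <- params$cor_intercept_class
  b_class <- if (params$sd_class_offset > 0) {
    params$sd_class_offset *
      (rho * (b0 / max(params$sd_intercept, .Machine$double.eps)) +
         sqrt(1 - rho^2) * z)
  } else {
    rep(0, n)
  }

  grids <- lapply(names(params$levels), function(cls) {
    if (cls == "bbn_overall") {
      tibble::tibble(precursor_class = "bbn",
                     level_overall_db = params$levels[[cls]],
                     level_db = bbn_level_per_erb(params$levels[[cls]]))
    } else {
      tibble::tibble(precursor_class = cls,
                     level_overall_db = params$levels[[cls]],
                     level_db = params$levels[[cls]])
    }
  })
  grid <- dplyr::bind_rows(grids)
  out <- tidyr::expand_grid(
    participant = sprintf("S%02d", seq_len(n)),
    grid,
    run = seq_len(params$runs_per_condition))
  idx <- match(out$participant, sprintf("S%02d", seq_len(n)))
  mu <- mapply(function(cls, lvl) .linear_predictor(params$fixed, cls, lvl),
               out$precursor_class, out$level_db)
  offset_applies <- out$precursor_class != "on_tone" &
    params$random_structure == "slopes"
  out$estimate_db <- mu + b0[idx] + ifelse(offset_applies, b_class[idx], 0) +
    rnorm(nrow(out), 0, params$sd_residual)
  out
}

#' Generate a cohort of mechanistic listeners
#'
#' Samples per-listener cochlear and decision parameters from ranges a
#' psychoacoustic study of young normal-hearing adults would consider
#' realistic: low-level gain G in 35-50 dB, compression exponent c in
#' 0.2-0.5, breakpoint 35-50 dB SPL, quiet threshold 5-20 dB SPL,
#' off-frequency attenuation 7-12 dB, and a mechanistic [gain_rule()]
#' whose elicitation slope s in 0.7-0.9 implies off-frequency
#' gain-reduction growth of s dB/dB and on-frequency growth of s*c dB/dB,
#' bracketing the empirically observed growth slopes. The gain-reduction
#' cap is 20-25 dB (never more than G).
#'
#' @param n_participants Cohort size (>= 1).
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @return A list of [listener()] objects.
#' @export
generate_cohort <- function(n_participants = 7, seed = 1) {
  if (n_participants < 1) stop_invalid("`n_participants` must be >= 1")
  set.seed(seed)
  lapply(seq_len(n_participants), function(i) {
    g <- runif(1, 35, 50)
    c_exp <- runif(1, 0.2, 0.5)
    bp <- runif(1, 35, 50)
    quiet <- runif(1, 5, 20)
    a <- runif(1, 7, 12)
    s <- runif(1, 0.7, 0.9)
    cap <- min(runif(1, 20, 25), g)
    # elicitation floor placed so a 40-dB on-frequency precursor (below the
    # breakpoint, excitation quiet-like) already elicits some reduction
    e0 <- runif(1, 38, 48)
    listener(
      id = sprintf("S%02d", i), quiet_threshold_db_spl = quiet,
      io = io_function(g, c_exp, bp), off_freq_attenuation_db = a,
      criterion_smr_db = 0, psychometric_spread_db = 4,
      run_noise_sd_db = runif(1, 0.5, 2),
      gain_rule = gain_rule("mechanistic", elicitation_slope = s,
                            elicitation_floor = e0, cap_db = cap))
  })
}

#' Default design of the simulated experiments
#'
#' Condition lists for the three simulated experiments: growth-of-masking
#' masker levels and matched-masker pairs with a 40-dB SPL on-frequency
#' precursor (experiment 1), tonal precursor level grids (experiment 2),
#' and broadband-noise precursor levels with the 12-reversal tracking
#' procedure (experiment 3).
#'
#' @return A named list of design settings.
#' @export
default_design <- function() {
  list(
    signal_freq_khz = 4, off_freq_khz = 2.4,
    precursor_level_db = 40,
    gom_levels_db = seq(30, 95, by = 5),
    matched_off_levels_db = c(65, 75),
    on_tone_levels_db = seq(20, 90, by = 10),
    off_tone_levels_db = seq(60, 95, by = 5),
    bbn_overall_levels_db = seq(24, 64, by = 10),
    runs_per_condition = 2)
}

# build the trial condition for a named simulated condition
.make_condition <- function(design, masker = NULL, precursor = NULL) {
  signal <- tone_stimulus("signal", design$signal_freq_khz, 0, 6)
  trial_condition(signal, masker = masker, precursor = precursor)
}

#' Simulate the full experiment suite for a cohort
#'
#' Chains the listener model, detection model and staircase simulator over
#' every condition of the three simulated experiments for every listener:
#' quiet and precursor-alone thresholds, growth-of-masking series with and
#' without a precursor, equally-effective matched-masker conditions
#' (experiment 1), tonal precursor level series (experiment 2), and
#' broadband-noise level series under the 12-reversal procedure
#' (experiment 3). Every staircase run is recorded with its QC outcome;
#' failing runs are kept in the run table and excluded from derived
#' summaries. The whole suite is deterministic given `seed`.
#'
#' @param cohort A list of [listener()]s, e.g. from [generate_cohort()].
#' @param seed Integer seed.
#' @param design A design list as from [default_design()].
#' @return A list with tibbles `runs` (one row per staircase run),
#'   `summary` (per-condition means/SDs/run counts over QC-passing runs)
#'   and `points` (gain-reduction points derived from the precursor-alone
#'   conditions of experiments 2-3).
#' @export
generate_full_experiment <- function(cohort, seed = 1,
                                     design = default_design()) {
  stopifnot(length(cohort) >= 1, inherits(cohort[[1]], "listener"))
  set.seed(seed)
  cfg50 <- staircase_config_50trial()
  cfg12 <- staircase_config_12rev()
  prec <- tone_stimulus("precursor", design$signal_freq_khz,
                        design$precursor_level_db, 50)
  rows <- list()
  add_run <- function(experiment, listener, label, class, level, masker_freq,
                      masker_level, precursor_on, cond, cfg) {
    n_runs <- design$runs_per_condition
    seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
    for (r in seq_len(n_runs)) {
      sr <- run_staircase(cond, listener, cfg, seeds[r])
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        experiment = experiment, participant = listener$id,
        condition = label, precursor_class = class,
        precursor_level_db = level, masker_freq_khz = masker_freq,
        masker_level_db = masker_level, precursor = precursor_on,
        run = r, seed = seeds[r],
        estimate_db = sr$threshold_estimate_db,
        reversal_sd_db = sr$reversal_sd_db, qc_pass = sr$qc_pass,
        true_threshold_db = sr$true_threshold_db)
    }
  }

  for (l in cohort) {
    off_freq <- design$off_freq_khz
    # quiet and precursor-alone anchors
    add_run("exp1", l, "quiet", "none", NA, NA, NA, "none",
            .make_condition(design), cfg50)
    add_run("exp1", l, "precursor_alone", "on_tone",
            design$precursor_level_db, NA, NA, "tone",
            .make_condition(design, precursor = prec), cfg50)
    # growth of masking, off-frequency masker, with/without precursor
    for (ml in design$gom_levels_db) {
      masker <- tone_stimulus("masker", off_freq, ml)
      add_run("exp1", l, sprintf("gom_%g", ml), "none", NA, off_freq, ml,
              "none", .make_condition(design, masker = masker), cfg50)
      add_run("exp1", l, sprintf("gom_%g_prec", ml), "on_tone",
              design$precursor_level_db, off_freq, ml, "tone",
              .make_condition(design, masker = masker, precursor = prec),
              cfg50)
    }
    # matched-masker pairs
    for (ml in design$matched_off_levels_db) {
      off_masker <- tone_stimulus("masker", off_freq, ml)
      on_level <- as.numeric(equally_effective_masker_level(off_masker, l))
      on_masker <- tone_stimulus("masker", design$signal_freq_khz, on_level)
      for (p_on in c(FALSE, TRUE)) {
        pstim <- if (p_on) prec else NULL
        add_run("exp1", l, sprintf("matched_off_%g%s", ml,
                                   if (p_on) "_prec" else ""),
                if (p_on) "on_tone" else "none",
                if (p_on) design$precursor_level_db else NA,
                off_freq, ml, if (p_on) "tone" else "none",
                .make_condition(design, masker = off_masker,
                                precursor = pstim), cfg50)
        add_run("exp1", l, sprintf("matched_on_%g%s", ml,
                                   if (p_on) "_prec" else ""),
                if (p_on) "on_tone" else "none",
                if (p_on) design$precursor_level_db else NA,
                design$signal_freq_khz, on_level,
                if (p_on) "tone" else "none",
                .make_condition(design, masker = on_masker,
                                precursor = pstim), cfg50)
      }
    }
    # experiment 2: tonal precursor level series
    for (pl in design$on_tone_levels_db) {
      p <- tone_stimulus("precursor", design$signal_freq_khz, pl, 50)
      add_run("exp2", l, sprintf("on_tone_%g", pl), "on_tone", pl, NA, NA,
              "tone", .make_condition(design, precursor = p), cfg50)
    }
    for (pl in design$off_tone_levels_db) {
      p <- tone_stimulus("precursor", off_freq, pl, 50)
      add_run("exp2", l, sprintf("off_tone_%g", pl), "off_tone", pl, NA, NA,
              "tone", .make_condition(design, precursor = p), cfg50)
    }
    # experiment 3: broadband-noise precursors, 12-reversal procedure
    for (pl in design$bbn_overall_levels_db) {
      p <- noise_stimulus("precursor", pl)
      add_run("exp3", l, sprintf("bbn_%g", pl), "bbn", pl, NA, NA, "bbn",
              .make_condition(design, precursor = p), cfg12)
    }
  }

  runs <- dplyr::bind_rows(rows)
  ok <- runs |> dplyr::filter(.data$qc_pass)
  summary <- ok |>
    dplyr::group_by(.data$experiment, .data$participant, .data$condition,
                    .data$precursor_class, .data$precursor_level_db,
                    .data$masker_freq_khz, .data$masker_level_db,
                    .data$precursor) |>
    dplyr::summarise(mean_db = mean(.data$estimate_db),
                     sd_db = if (dplyr::n() > 1) sd(.data$estimate_db) else 0,
                     n_runs = dplyr::n(), .groups = "drop")

  quiet <- ok |>
    dplyr::filter(.data$condition == "quiet") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(quiet_db = mean(.data$estimate_db), .groups = "drop")
  points <- ok |>
    dplyr::filter(.data$experiment %in% c("exp2", "exp3") |
                    .data$condition == "precursor_alone") |>
    dplyr::left_join(quiet, by = "participant") |>
    dplyr::mutate(
      level_overall_db = .data$precursor_level_db,
      level_db = ifelse(.data$precursor_class == "bbn",
                        bbn_level_per_erb(.data$precursor_level_db),
                        .data$precursor_level_db),
      estimate_db = gain_reduction_estimate(.data$estimate_db,
                                            .data$quiet_db)) |>
    dplyr::select(dplyr::all_of(c("experiment", "participant",
                                  "precursor_class", "level_db",
                                  "level_overall_db", "run",
                                  "estimate_db")))

  list(runs = runs, summary = summary, points = points)
}

#' Predicted matched-masker threshold shifts under both hypotheses
#'
#' The deterministic core of the hypothesis-discrimination experiment: for
#' equally effective on- and off-frequency maskers, compute the predicted
#' signal-threshold shift produced by adding the same on-frequency
#' precursor, under both the gain-reduction and additivity-of-masking
#' hypotheses. Under gain reduction the off-frequency shift exceeds the
#' on-frequency shift whenever the precursor elicits any gain reduction;
#' under additivity the two shifts are identical by construction.
#'
#' @param listener A [listener()].
#' @param off_levels_db Off-frequency masker levels in dB SPL.
#' @param precursor_level_db On-frequency precursor level in dB SPL.
#' @param off_freq_khz Off-frequency masker frequency in kHz.
#' @return A tibble with one row per (masker level, masker side,
#'   hypothesis): predicted thresholds without and with precursor, and the
#'   shift.
#' @export
hypothesis_shift_table <- function(listener, off_levels_db = c(65, 75),
                                   precursor_level_db = 40,
                                   off_freq_khz = 2.4) {
  stopifnot(inherits(listener, "listener"))
  fs <- listener$signal_freq_khz
  prec <- tone_stimulus("precursor", fs, precursor_level_db, 50)
  signal <- tone_stimulus("signal", fs, 0, 6)
  rows <- list()
  for (ml in off_levels_db) {
    off_m <- tone_stimulus("masker", off_freq_khz, ml)
    on_level <- as.numeric(equally_effective_masker_level(off_m, listener))
    on_m <- tone_stimulus("masker", fs, on_level)
    for (side in c("off", "on")) {
      m <- if (side == "off") off_m else on_m
      for (hyp in c("gain_reduction", "additivity")) {
        t0 <- as.numeric(predicted_threshold(
          trial_condition(signal, masker = m), listener, hyp))
        t1 <- as.numeric(predicted_threshold(
          trial_condition(signal, masker = m, precursor = prec), listener,
          hyp))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          off_masker_level_db = ml, masker_side = side,
          masker_level_db = m$level_db_spl, hypothesis = hyp,
          threshold_db = t0, threshold_precursor_db = t1,
          shift_db = t1 - t0)
      }
    }
  }
  dplyr::bind_rows(rows)
}
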