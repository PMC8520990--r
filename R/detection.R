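#' A forward-masking trial condition
#'
#' The stimulus complex of one trial: an optional precursor, an optional
#' masker, and the signal (always present). The temporal layout -- precursor,
#' then masker (or silent gap), then signal -- is fixed by design and chosen
#' so the precursor's efferent effect is fully active at signal onset; only
#' the stimulus identities vary. The high-pass background noise used to
#' limit off-frequency listening is carried as a metadata flag only.
#'
#' @param signal A [stimulus()] with role `"signal"`.
#' @param masker A [stimulus()] with role `"masker"`, or `NULL`.
#' @param precursor A [stimulus()] with role `"precursor"`, or `NULL`.
#' @param background_noise Logical metadata flag.
#' @return An object of class `trial_condition`.
#' @export
trial_condition <- function(signal, masker = NULL, precursor = NULL,
                            background_noise = TRUE) {
  stopifnot(inherits(signal, "stimulus"))
  if (signal$role != "signal") stop_invalid("`signal` must have role 'signal'")
  if (!is.null(masker)) {
    stopifnot(inherits(masker, "stimulus"))
    if (masker$role != "masker") stop_invalid("`masker` must have role 'masker'")
  }
  if (!is.null(precursor)) {
    stopifnot(inherits(precursor, "stimulus"))
    if (precursor$role != "precursor") {
      stop_invalid("`precursor` must have role 'precursor'")
    }
  }
  structure(
    list(signal = signal, masker = masker, precursor = precursor,
         background_noise = isTRUE(background_noise)),
    class = "trial_condition"
  )
}

#' @export
print.trial_condition <- function(x, ...) {
  parts <- c(
    if (!is.null(x$precursor)) "precursor",
    if (!is.null(x$masker)) "masker",
    "signal")
  cat(sprintf("<trial_condition> %s\n", paste(parts, collapse = " + ")))
  invisible(x)
}

# search bounds for predicted thresholds, dB SPL
.level_bounds <- c(-20, 120)

#' Power-spectrum-model threshold prediction
#'
#' Predicts the masked signal threshold for a trial condition under one of
#' two competing accounts of the extra masking a precursor produces:
#' \describe{
#'   \item{gain_reduction}{The precursor reduces the low-level gain of the
#'     input-output function at the signal place by `delta_G` (from the
#'     listener's [gain_rule()]). The signal and any on-frequency masker are
#'     evaluated through the reduced curve; off-frequency maskers are
#'     processed linearly and are unaffected. Threshold is the signal level
#'     whose place output first reaches the power sum of masker excitation
#'     and internal noise, plus the criterion SMR.}
#'   \item{additivity}{The curve is static. Masker and precursor excitations
#'     (full-gain curve) add in intensity at the place output, and threshold
#'     solves the same criterion equation against that combined excitation.}
#' }
#' The two accounts make sharply different predictions for equally effective
#' on- vs off-frequency maskers preceded by the same precursor, which is the
#' experimental signature the package is built around.
#'
#' @param cond A [trial_condition()].
#' @param listener A [listener()].
#' @param hypothesis `"gain_reduction"` or `"additivity"`.
#' @return Signal threshold in dB SPL. Solutions outside the search range
#'   (-20 to 120 dB SPL) saturate at the boundary, with attribute
#'   `saturated = TRUE` and a warning.
#' @examples
#' l <- listener("L1", 10, io_function(40, 0.3, 40), 9,
#'               gain_rule = gain_rule("mechanistic", 0.8, 45, cap_db = 25))
#' sig <- tone_stimulus("signal", 4, 0, 6) # level is the tracked variable
#' predicted_threshold(trial_condition(sig), l) # quiet threshold: 10
#' @export
predicted_threshold <- function(cond, listener,
                                hypothesis = c("gain_reduction", "additivity")) {
  stopifnot(inherits(cond, "trial_condition"), inherits(listener, "listener"))
  hypothesis <- match.arg(hypothesis)
  n0 <- listener$internal_noise_db
  k <- listener$criterion_smr_db

  if (hypothesis == "gain_reduction") {
    dg <- elicited_gain_reduction(cond$precursor, listener)
    io_sig <- apply_gain_reduction(listener$io, dg)
    em <- if (is.null(cond$masker)) -Inf else {
      place_excitation(cond$masker, listener, delta_g = dg)
    }
    target_out <- db_sum(em, n0) + k
    thr <- io_inverse(target_out, io_sig)
  } else {
    em <- if (is.null(cond$masker)) -Inf else {
      place_excitation(cond$masker, listener, delta_g = 0)
    }
    ep <- if (is.null(cond$precursor)) -Inf else {
      place_excitation(cond$precursor, listener, delta_g = 0)
    }
    target_out <- db_sum(em, ep, n0) + k
    thr <- io_inverse(target_out, listener$io)
  }

  if (thr < .level_bounds[1] || thr > .level_bounds[2]) {
    warning("predicted threshold saturates at the search boundary")
    thr <- clamp(thr, .level_bounds[1], .level_bounds[2])
    attr(thr, "saturated") <- TRUE
  }
  thr
}

#' On-frequency masker level equally effective as an off-frequency masker
#'
#' Finds the on-frequency (signal-frequency) masker level producing the same
#' place excitation -- and therefore the same predicted signal threshold --
#' as a given off-frequency masker, by inverting the input-output function
#' at the off-frequency masker's linear place excitation.
#'
#' @param off_masker A [stimulus()]: an off-frequency tonal masker.
#' @param listener A [listener()].
#' @return On-frequency masker level in dB SPL.
#' @examples
#' l <- listener("L1", 10, io_function(40, 0.3, 40), 9,
#'               gain_rule = gain_rule("mechanistic", 0.8, 45, cap_db = 25))
#' equally_effective_masker_level(
#'   tone_stimulus("masker", 2.4, 65), l) # 16
#' @export
equally_effective_masker_level <- function(off_masker, listener) {
  stopifnot(inherits(off_masker, "stimulus"), inherits(listener, "listener"))
  if (off_masker$kind != "tone" ||
      is_on_frequency(off_masker, listener$signal_freq_khz)) {
    stop_invalid("`off_masker` must be an off-frequency tone")
  }
  em <- off_masker$level_db_spl - listener$off_freq_attenuation_db
  l_on <- io_inverse(em, listener$io)
  if (l_on < .level_bounds[1] || l_on > .level_bounds[2]) {
    warning("matched masker level saturates at the search boundary")
    l_on <- clamp(l_on, .level_bounds[1], .level_bounds[2])
    attr(l_on, "saturated") <- TRUE
  }
  l_on
}

# anchor so that percent correct at the true threshold is exactly the
# 2-down/1-up convergence point, sqrt(1/2) ~ 70.7%
.p_track <- 1 / sqrt(2)
.z0_3ifc <- qnorm((1 / sqrt(2) - 1 / 3) * 3 / 2)

#' Psychometric function for 3-interval forced choice
#'
#' Gaussian-CDF psychometric function with chance level 1/3:
#' `p = 1/3 + (2/3) * Phi((L - theta)/sigma + z0)`, anchored so that
#' `p(theta)` equals the 2-down/1-up tracking point `sqrt(1/2)` (70.7%
#' correct). This makes "true threshold" and "tracked level" synonymous.
#'
#' @param signal_level_db Signal level(s) in dB SPL.
#' @param true_threshold_db The listener's threshold theta in dB SPL.
#' @param spread_db Psychometric spread sigma in dB (> 0).
#' @return Probability of a correct response, in (1/3, 1).
#' @examples
#' percent_correct_3ifc(30, 30, 4) # 0.7071
#' @export
percent_correct_3ifc <- function(signal_level_db, true_threshold_db,
                                 spread_db) {
  if (!is.numeric(spread_db) || any(spread_db <= 0)) {
    stop_invalid("`spread_db` must be > 0")
  }
  1 / 3 + (2 / 3) *
    pnorm((signal_level_db - true_threshold_db) / spread_db + .z0_3ifc)
}
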