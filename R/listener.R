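#' Gain-reduction rule
#'
#' How much efferent gain reduction a precursor elicits. Two modes:
#' \describe{
#'   \item{mechanistic}{The precursor's excitation at the signal place,
#'     `E` (through the full-gain input-output curve), drives gain reduction
#'     linearly above a floor: `delta_G = clamp(s * (E - E0), 0, cap)`.
#'     Because on-frequency precursors are compressed above the breakpoint
#'     while off-frequency precursors are processed linearly, the implied
#'     growth of `delta_G` with precursor level is `s * c` on-frequency and
#'     `s` off-frequency.}
#'   \item{empirical}{A per-class linear map from precursor level (dB SPL for
#'     tones, dB/ERB for broadband noise) to `delta_G`, clamped to
#'     `[0, cap]`. Classes: `on_tone`, `off_tone`, `bbn`.}
#' }
#'
#' @param mode `"mechanistic"` or `"empirical"`.
#' @param elicitation_slope dB of gain reduction per dB of place excitation
#'   (mechanistic; >= 0).
#' @param elicitation_floor Place-output level E0 in dB below which no gain
#'   reduction is elicited (mechanistic).
#' @param cap_db Maximum gain reduction in dB (cannot exceed the paired
#'   curve's gain).
#' @param intercepts,slopes Named numeric vectors over classes `on_tone`,
#'   `off_tone`, `bbn` (empirical mode; slopes >= 0).
#' @return An object of class `gain_rule`.
#' @export
gain_rule <- function(mode = c("mechanistic", "empirical"),
                      elicitation_slope = NULL, elicitation_floor = NULL,
                      cap_db = Inf, intercepts = NULL, slopes = NULL) {
  mode <- match.arg(mode)
  if (cap_db < 0) stop_invalid("`cap_db` must be >= 0")
  if (mode == "mechanistic") {
    if (is.null(elicitation_slope) || elicitation_slope < 0) {
      stop_invalid("mechanistic rule needs `elicitation_slope` >= 0")
    }
    if (is.null(elicitation_floor) || !is.finite(elicitation_floor)) {
      stop_invalid("mechanistic rule needs a finite `elicitation_floor`")
    }
  } else {
    classes <- c("on_tone", "off_tone", "bbn")
    intercepts <- unlist(intercepts)
    slopes <- unlist(slopes)
    if (is.null(intercepts) || is.null(slopes) ||
        !all(names(intercepts) %in% classes) ||
        !all(names(slopes) %in% classes) || any(slopes < 0)) {
      stop_invalid(
        "empirical rule needs named `intercepts` and `slopes` (>= 0) over classes on_tone/off_tone/bbn")
    }
  }
  structure(
    list(mode = mode, elicitation_slope = elicitation_slope,
         elicitation_floor = elicitation_floor, cap_db = cap_db,
         intercepts = intercepts, slopes = slopes),
    class = "gain_rule"
  )
}

#' A simulated listener
#'
#' One simulated ear: a quiet threshold, a cochlear input-output function at
#' the signal place, linear off-frequency attenuation, a detection criterion,
#' a psychometric spread, run-to-run threshold jitter, and a gain-reduction
#' rule. The internal-noise floor `N0` (place-output level) is calibrated at
#' construction so the power-spectrum detection model reproduces
#' `quiet_threshold_db_spl` exactly: `N0 = io_output(quiet) - K`.
#'
#' @param id Listener identifier.
#' @param quiet_threshold_db_spl Absolute threshold of the signal in quiet.
#' @param io An [io_function()] for the signal place.
#' @param off_freq_attenuation_db A: dB lost by an off-frequency tone on its
#'   way to the signal place (>= 0).
#' @param criterion_smr_db K: signal-to-masker ratio at the place output
#'   required for detection, in dB.
#' @param psychometric_spread_db Gaussian spread of the psychometric function
#'   in dB (> 0).
#' @param run_noise_sd_db Between-run threshold jitter SD in dB (>= 0).
#' @param gain_rule A [gain_rule()].
#' @param signal_freq_khz Signal frequency in kHz (default 4).
#' @return An object of class `listener`.
#' @examples
#' l <- listener(
#'   id = "L1", quiet_threshold_db_spl = 10,
#'   io = io_function(40, 0.3, 40), off_freq_attenuation_db = 9,
#'   gain_rule = gain_rule("mechanistic", elicitation_slope = 0.8,
#'                         elicitation_floor = 45, cap_db = 25))
#' @export
listener <- function(id, quiet_threshold_db_spl, io,
                     off_freq_attenuation_db, criterion_smr_db = 0,
                     psychometric_spread_db = 4, run_noise_sd_db = 1,
                     gain_rule, signal_freq_khz = 4) {
  stopifnot(inherits(io, "io_function"), inherits(gain_rule, "gain_rule"))
  if (off_freq_attenuation_db < 0) stop_invalid("`off_freq_attenuation_db` must be >= 0")
  if (psychometric_spread_db <= 0) stop_invalid("`psychometric_spread_db` must be > 0")
  if (run_noise_sd_db < 0) stop_invalid("`run_noise_sd_db` must be >= 0")
  if (is.finite(gain_rule$cap_db) && gain_rule$cap_db > io$gain_db) {
    stop_invalid("gain-reduction cap cannot exceed the curve's gain")
  }
  internal_noise_db <- io_output(quiet_threshold_db_spl, io) - criterion_smr_db
  structure(
    list(id = id, quiet_threshold_db_spl = quiet_threshold_db_spl, io = io,
         off_freq_attenuation_db = off_freq_attenuation_db,
         internal_noise_db = internal_noise_db,
         criterion_smr_db = criterion_smr_db,
         psychometric_spread_db = psychometric_spread_db,
         run_noise_sd_db = run_noise_sd_db, gain_rule = gain_rule,
         signal_freq_khz = signal_freq_khz),
    class = "listener"
  )
}

#' @export
print.listener <- function(x, ...) {
  cat(sprintf(
    "<listener %s> quiet %.1f dB SPL, G %.1f dB, c %.2f, BP %.1f, A %.1f dB, %s gain rule\n",
    x$id, x$quiet_threshold_db_spl, x$io$gain_db, x$io$compression,
    x$io$breakpoint_db, x$off_freq_attenuation_db, x$gain_rule$mode))
  invisible(x)
}

#' Place excitation of a stimulus at the signal place
#'
#' Output level, in dB, that a stimulus produces at the cochlear place tuned
#' to the signal frequency:
#' * on-frequency tones (within one ERB of the signal) pass through the
#'   (possibly gain-reduced) input-output function;
#' * off-frequency tones are processed linearly -- `level - A` -- and are
#'   unaffected by gain reduction;
#' * broadband noise is reduced to its dB/ERB level at the signal place and
#'   passed through the (possibly gain-reduced) curve;
#' * silence returns the internal-noise floor `N0`.
#'
#' @param stim A [stimulus()].
#' @param listener A [listener()].
#' @param delta_g Gain reduction in dB applied to the curve (default 0 =
#'   full gain). Only on-frequency and noise paths are affected.
#' @return Place output level in dB.
#' @export
place_excitation <- function(stim, listener, delta_g = 0) {
  stopifnot(inherits(stim, "stimulus"), inherits(listener, "listener"))
  io <- if (delta_g > 0) apply_gain_reduction(listener$io, delta_g) else listener$io
  switch(stim$kind,
    silence = listener$internal_noise_db,
    tone = {
      if (is_on_frequency(stim, listener$signal_freq_khz)) {
        io_output(stim$level_db_spl, io)
      } else {
        stim$level_db_spl - listener$off_freq_attenuation_db
      }
    },
    broadband_noise = {
      fs_hz <- listener$signal_freq_khz * 1000
      if (stim$band_low_hz > fs_hz || stim$band_high_hz < fs_hz) {
        stop_invalid("noise band does not cover the signal frequency")
      }
      io_output(bbn_level_per_erb(stim$level_db_spl, stim$band_low_hz,
                                  stim$band_high_hz,
                                  listener$signal_freq_khz), io)
    })
}

#' Gain reduction elicited by a precursor
#'
#' Applies the listener's [gain_rule()] to a precursor stimulus. Silence (or
#' a missing precursor) elicits nothing. In mechanistic mode the driver is
#' the precursor's excitation at the signal place through the full-gain
#' curve; in empirical mode it is the precursor level itself (dB SPL for
#' tones, dB/ERB for noise) with per-class coefficients.
#'
#' @param precursor A [stimulus()] with role `"precursor"`, or `NULL`.
#' @param listener A [listener()].
#' @return Gain reduction delta-G in dB, in `[0, cap]` (and never more than
#'   the curve's gain).
#' @export
elicited_gain_reduction <- function(precursor, listener) {
  stopifnot(inherits(listener, "listener"))
  if (is.null(precursor) || precursor$kind == "silence") return(0)
  stopifnot(inherits(precursor, "stimulus"))
  if (precursor$role != "precursor") {
    stop_invalid("stimulus role must be 'precursor'")
  }
  rule <- listener$gain_rule
  cap <- min(rule$cap_db, listener$io$gain_db)
  if (rule$mode == "mechanistic") {
    e <- place_excitation(precursor, listener, delta_g = 0)
    clamp(rule$elicitation_slope * (e - rule$elicitation_floor), 0, cap)
  } else {
    cls <- precursor_class(precursor, listener$signal_freq_khz)
    if (!cls %in% names(rule$intercepts) || !cls %in% names(rule$slopes)) {
      stop_invalid(sprintf("empirical gain rule has no coefficients for class '%s'", cls))
    }
    lvl <- if (cls == "bbn") {
      bbn_level_per_erb(precursor$level_db_spl, precursor$band_low_hz,
                        precursor$band_high_hz, listener$signal_freq_khz)
    } else {
      precursor$level_db_spl
    }
    clamp(rule$intercepts[[cls]] + rule$slopes[[cls]] * lvl, 0, cap)
  }
}

#' Precursor class of a stimulus
#'
#' @param stim A [stimulus()].
#' @param signal_freq_khz Signal frequency in kHz.
#' @return `"on_tone"`, `"off_tone"`, `"bbn"` or `"none"`.
#' @export
precursor_class <- function(stim, signal_freq_khz = 4) {
  if (is.null(stim) || stim$kind == "silence") return("none")
  switch(stim$kind,
    broadband_noise = "bbn",
    tone = if (is_on_frequency(stim, signal_freq_khz)) "on_tone" else "off_tone")
}

#' Serialize / deserialize listeners as JSON
#'
#' @param x A [listener()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `listener_to_json()`: a JSON string (invisibly, if written to
#'   file); `listener_from_json()`: a [listener()].
#' @export
listener_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "listener"))
  payload <- list(
    id = x$id, quiet_threshold_db_spl = x$quiet_threshold_db_spl,
    io = unclass(x$io),
    off_freq_attenuation_db = x$off_freq_attenuation_db,
    criterion_smr_db = x$criterion_smr_db,
    psychometric_spread_db = x$psychometric_spread_db,
    run_noise_sd_db = x$run_noise_sd_db,
    gain_rule = Filter(Negate(is.null), unclass(x$gain_rule)),
    signal_freq_khz = x$signal_freq_khz)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname listener_to_json
#' @param json A JSON string or file path produced by [listener_to_json()].
#' @export
listener_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  gr <- do.call(gain_rule, c(list(mode = p$gain_rule$mode),
    p$gain_rule[setdiff(names(p$gain_rule), "mode")]))
  listener(
    id = p$id, quiet_threshold_db_spl = p$quiet_threshold_db_spl,
    io = io_function(p$io$gain_db, p$io$compression, p$io$breakpoint_db),
    off_freq_attenuation_db = p$off_freq_attenuation_db,
    criterion_smr_db = p$criterion_smr_db,
    psychometric_spread_db = p$psychometric_spread_db,
    run_noise_sd_db = p$run_noise_sd_db, gain_rule = gr,
    signal_freq_khz = p$signal_freq_khz)
}
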