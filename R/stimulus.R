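#' Stimulus specification
#'
#' One component of a forward-masking trial: a precursor, masker or signal,
#' which may be a pure tone, a flat-spectrum broadband noise, or silence.
#'
#' @param role One of `"precursor"`, `"masker"`, `"signal"`, `"none"`.
#' @param kind One of `"tone"`, `"broadband_noise"`, `"silence"`.
#' @param frequency_khz Tone frequency in kHz (tones only).
#' @param band_low_hz,band_high_hz Noise band edges in Hz (noise only).
#' @param level_db_spl Presentation level in dB SPL (overall RMS for noise).
#' @param duration_ms Duration in ms; must be positive for non-silence.
#' @return An object of class `stimulus`.
#' @seealso [tone_stimulus()], [noise_stimulus()], [silence_stimulus()]
#' @export
stimulus <- function(role = c("precursor", "masker", "signal", "none"),
                     kind = c("tone", "broadband_noise", "silence"),
                     frequency_khz = NULL, band_low_hz = NULL,
                     band_high_hz = NULL, level_db_spl = NULL,
                     duration_ms = NULL) {
  role <- match.arg(role)
  kind <- match.arg(kind)
  if (kind == "tone") {
    if (is.null(frequency_khz) || !is.finite(frequency_khz) ||
        frequency_khz <= 0) {
      stop_invalid("a tone needs a positive `frequency_khz`")
    }
  }
  if (kind == "broadband_noise") {
    if (is.null(band_low_hz) || is.null(band_high_hz) ||
        band_high_hz <= band_low_hz) {
      stop_invalid("a noise needs band edges with band_low_hz < band_high_hz")
    }
  }
  if (kind != "silence") {
    if (is.null(level_db_spl) || !is.finite(level_db_spl)) {
      stop_invalid("`level_db_spl` must be finite for non-silence stimuli")
    }
    if (is.null(duration_ms) || duration_ms <= 0) {
      stop_invalid("`duration_ms` must be positive for non-silence stimuli")
    }
  }
  structure(
    list(role = role, kind = kind, frequency_khz = frequency_khz,
         band_low_hz = band_low_hz, band_high_hz = band_high_hz,
         level_db_spl = level_db_spl, duration_ms = duration_ms),
    class = "stimulus"
  )
}

#' @rdname stimulus
#' @export
tone_stimulus <- function(role, frequency_khz, level_db_spl,
                          duration_ms = 20) {
  stimulus(role, "tone", frequency_khz = frequency_khz,
           level_db_spl = level_db_spl, duration_ms = duration_ms)
}

#' @rdname stimulus
#' @export
noise_stimulus <- function(role, level_db_spl, band_low_hz = 80,
                           band_high_hz = 10000, duration_ms = 50) {
  stimulus(role, "broadband_noise", band_low_hz = band_low_hz,
           band_high_hz = band_high_hz, level_db_spl = level_db_spl,
           duration_ms = duration_ms)
}

#' @rdname stimulus
#' @export
silence_stimulus <- function(role = "none") {
  stimulus(role, "silence")
}

#' @export
print.stimulus <- function(x, ...) {
  desc <- switch(x$kind,
    tone = sprintf("%.2f-kHz tone at %.1f dB SPL", x$frequency_khz,
                   x$level_db_spl),
    broadband_noise = sprintf("%d-%d Hz noise at %.1f dB SPL overall",
                              x$band_low_hz, x$band_high_hz, x$level_db_spl),
    silence = "silence")
  cat(sprintf("<stimulus> %s: %s\n", x$role, desc))
  invisible(x)
}

#' Is a tone on-frequency relative to a signal place?
#'
#' A tone counts as on-frequency when it lies within one equivalent
#' rectangular bandwidth of the signal frequency; otherwise it is treated as
#' off-frequency and processed linearly at the signal place.
#'
#' @param stim A [stimulus()] of kind `"tone"`.
#' @param signal_freq_khz Signal frequency in kHz.
#' @return Logical.
#' @export
is_on_frequency <- function(stim, signal_freq_khz) {
  stopifnot(inherits(stim, "stimulus"), stim$kind == "tone")
  abs(stim$frequency_khz - signal_freq_khz) * 1000 <=
    erb_bandwidth(signal_freq_khz)
}
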