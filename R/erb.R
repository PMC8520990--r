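#' Equivalent rectangular bandwidth of the auditory filter
#'
#' Glasberg-Moore equivalent rectangular bandwidth (ERB) at centre frequency
#' `f_khz`: `ERB = 24.7 * (4.37 * F + 1)` Hz with `F` in kHz. At 4 kHz the
#' ERB is 456.46 Hz.
#'
#' @param f_khz Centre frequency in kHz. Must be positive.
#' @return Bandwidth in Hz.
#' @examples
#' erb_bandwidth(4) # 456.46
#' @export
erb_bandwidth <- function(f_khz) {
  if (!is.numeric(f_khz) || any(!is.finite(f_khz)) || any(f_khz <= 0)) {
    stop_invalid("`f_khz` must be a positive finite frequency in kHz")
  }
  24.7 * (4.37 * f_khz + 1)
}

#' Spectrum level of a flat-spectrum noise band
#'
#' Converts an overall RMS level to a spectrum level (dB per 1-Hz band) by
#' subtracting `10 * log10(bandwidth)`.
#'
#' @param overall_db Overall level in dB SPL.
#' @param band_low_hz,band_high_hz Band edges in Hz; the band must be
#'   non-empty (`band_low_hz < band_high_hz`).
#' @return Spectrum level in dB.
#' @examples
#' spectrum_level(64, 80, 10000) # 24.03
#' @export
spectrum_level <- function(overall_db, band_low_hz, band_high_hz) {
  if (!is.numeric(overall_db) || any(!is.finite(overall_db))) {
    stop_invalid("`overall_db` must be finite")
  }
  if (any(band_high_hz <= band_low_hz)) {
    stop_invalid("noise band is empty: `band_low_hz` must be < `band_high_hz`")
  }
  overall_db - 10 * log10(band_high_hz - band_low_hz)
}

#' Level per ERB of a flat-spectrum noise
#'
#' The level of the noise falling inside one equivalent rectangular bandwidth:
#' `dB/ERB = SL + 10 * log10(ERB)`. This approximates the level of the sound
#' entering the auditory filter centred at the signal frequency, which is the
#' quantity driving gain-reduction elicitation for broadband precursors.
#'
#' @param sl_db Spectrum level in dB (see [spectrum_level()]).
#' @param erb_hz Filter bandwidth in Hz (see [erb_bandwidth()]). Positive.
#' @return Level in dB/ERB.
#' @examples
#' level_per_erb(spectrum_level(64, 80, 10000), erb_bandwidth(4)) # 50.62
#' @export
level_per_erb <- function(sl_db, erb_hz) {
  if (any(!is.finite(erb_hz)) || any(erb_hz <= 0)) {
    stop_invalid("`erb_hz` must be a positive bandwidth in Hz")
  }
  sl_db + 10 * log10(erb_hz)
}

#' Overall broadband-noise level expressed in dB/ERB at a signal place
#'
#' Convenience chain of [spectrum_level()] and [level_per_erb()] for a
#' flat-spectrum noise, giving the level entering the auditory filter at
#' `signal_freq_khz`.
#'
#' @param overall_db Overall RMS level of the noise in dB SPL.
#' @param band_low_hz,band_high_hz Noise band edges in Hz.
#' @param signal_freq_khz Signal (filter centre) frequency in kHz.
#' @return Level in dB/ERB.
#' @export
bbn_level_per_erb <- function(overall_db, band_low_hz = 80,
                              band_high_hz = 10000, signal_freq_khz = 4) {
  level_per_erb(spectrum_level(overall_db, band_low_hz, band_high_hz),
                erb_bandwidth(signal_freq_khz))
}
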