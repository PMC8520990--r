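# shared fixtures: a deterministic reference listener and stimuli

make_listener <- function(gain = 40, compression = 0.3, breakpoint = 40,
                          quiet = 10, atten = 9, spread = 4, run_noise = 0,
                          s = 0.8, e0 = 45, cap = 25) {
  listener(
    id = "T1", quiet_threshold_db_spl = quiet,
    io = io_function(gain, compression, breakpoint),
    off_freq_attenuation_db = atten, criterion_smr_db = 0,
    psychometric_spread_db = spread, run_noise_sd_db = run_noise,
    gain_rule = gain_rule("mechanistic", elicitation_slope = s,
                          elicitation_floor = e0, cap_db = min(cap, gain)))
}

sig4k <- function(level = 0) tone_stimulus("signal", 4, level, 6)
prec4k <- function(level = 40) tone_stimulus("precursor", 4, level, 50)
prec24k <- function(level = 80) tone_stimulus("precursor", 2.4, level, 50)
masker24k <- function(level = 65) tone_stimulus("masker", 2.4, level)
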