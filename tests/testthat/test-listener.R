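test_that("place excitation routes stimuli through the right path", {
  l <- make_listener(gain = 40, compression = 0.2, breakpoint = 40)
  # off-frequency tone: linear, attenuated, immune to gain reduction
  off <- tone_stimulus("precursor", 2.4, 65, 50)
  expect_equal(place_excitation(off, l), 56)
  expect_equal(place_excitation(off, l, delta_g = 15), 56)
  # on-frequency tone through the compressive curve
  on <- tone_stimulus("precursor", 4, 16, 50)
  expect_equal(place_excitation(on, l), 56)
  # broadband noise enters at its dB/ERB level
  noise <- noise_stimulus("precursor", 64)
  expect_equal(place_excitation(noise, l),
               io_output(bbn_level_per_erb(64), l$io))
  expect_lt(abs(place_excitation(noise, l) - 82.12), 0.01)
  # silence returns the internal-noise floor
  expect_equal(place_excitation(silence_stimulus(), l), l$internal_noise_db)
  # noise band must cover the signal place
  low_noise <- noise_stimulus("precursor", 60, band_low_hz = 80,
                              band_high_hz = 2000)
  expect_error(place_excitation(low_noise, l),
               class = "mocgain_invalid_argument")
})

test_that("off-frequency excitation is invariant to any gain reduction", {
  l <- make_listener()
  off <- tone_stimulus("masker", 2.4, 72)
  set.seed(42)
  for (dg in runif(20, 0, l$io$gain_db)) {
    expect_identical(place_excitation(off, l, delta_g = dg),
                     place_excitation(off, l, delta_g = 0))
  }
})

test_that("internal noise calibration reproduces the quiet threshold", {
  for (q in c(5, 12, 18)) {
    l <- make_listener(quiet = q)
    expect_equal(as.numeric(predicted_threshold(
      trial_condition(sig4k()), l, "gain_reduction")), q)
    expect_equal(as.numeric(predicted_threshold(
      trial_condition(sig4k()), l, "additivity")), q)
  }
})

test_that("mechanistic elicitation clamps at zero and at the cap", {
  l <- make_listener(s = 0.8, e0 = 45, cap = 25)
  expect_identical(elicited_gain_reduction(NULL, l), 0)
  expect_identical(elicited_gain_reduction(silence_stimulus("precursor"), l), 0)
  # far below the elicitation floor
  expect_identical(elicited_gain_reduction(prec4k(-20), l), 0)
  # far above: clamped at the cap
  expect_identical(elicited_gain_reduction(prec24k(95), l), 25)
})

test_that("elicitation level-slopes follow the linear vs compressive paths", {
  l <- make_listener(gain = 40, compression = 0.41, breakpoint = 40,
                     s = 0.8, e0 = 40, cap = 39)
  h <- 0.01
  # off-frequency precursor: linear path, slope s
  s_off <- (elicited_gain_reduction(prec24k(80 + h), l) -
              elicited_gain_reduction(prec24k(80), l)) / h
  expect_equal(s_off, 0.8, tolerance = 1e-6)
  # on-frequency precursor above the breakpoint: compressed, slope s * c
  s_on <- (elicited_gain_reduction(prec4k(60 + h), l) -
             elicited_gain_reduction(prec4k(60), l)) / h
  expect_equal(s_on, 0.8 * 0.41, tolerance = 1e-6)
  expect_equal(s_on / s_off, l$io$compression, tolerance = 1e-6)
})

test_that("empirical gain rules use per-class coefficients and dB/ERB", {
  rule <- gain_rule("empirical",
                    intercepts = c(on_tone = -5, off_tone = -40, bbn = -3),
                    slopes = c(on_tone = 0.33, off_tone = 0.8, bbn = 0.4),
                    cap_db = 30)
  l <- listener("E1", 10, io_function(40, 0.3, 40), 9, gain_rule = rule)
  expect_equal(elicited_gain_reduction(prec4k(60), l), -5 + 0.33 * 60)
  expect_equal(elicited_gain_reduction(prec24k(70), l), -40 + 0.8 * 70)
  noise <- noise_stimulus("precursor", 64)
  expect_equal(elicited_gain_reduction(noise, l),
               -3 + 0.4 * bbn_level_per_erb(64))
  # negative raw values clamp to zero
  expect_identical(elicited_gain_reduction(prec24k(20), l), 0)
})

test_that("listeners serialize to JSON and back without loss", {
  l <- make_listener(gain = 43.5, compression = 0.27, breakpoint = 41.2,
                     quiet = 11.7)
  l2 <- listener_from_json(listener_to_json(l))
  expect_equal(l2$io, l$io)
  expect_equal(l2$internal_noise_db, l$internal_noise_db)
  expect_equal(l2$gain_rule$elicitation_slope, l$gain_rule$elicitation_slope)
  expect_equal(
    elicited_gain_reduction(prec4k(55), l2),
    elicited_gain_reduction(prec4k(55), l))
})
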