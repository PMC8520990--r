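test_that("cohort generation is seeded and respects parameter ranges", {
  c1 <- generate_cohort(5, seed = 9)
  c2 <- generate_cohort(5, seed = 9)
  expect_identical(c1, c2)
  c3 <- generate_cohort(5, seed = 10)
  expect_false(identical(c1, c3))
  for (l in c1) {
    expect_true(l$io$gain_db >= 35 && l$io$gain_db <= 50)
    expect_true(l$io$compression >= 0.2 && l$io$compression <= 0.5)
    expect_lte(l$gain_rule$cap_db, l$io$gain_db)
  }
  single <- generate_cohort(1, seed = 1)
  expect_length(single, 1)
  expect_error(generate_cohort(0), class = "mocgain_invalid_argument")
})

test_that("mechanistic listeners imply the constructed level slopes", {
  h <- 0.01
  for (l in generate_cohort(4, seed = 21)) {
    s <- l$gain_rule$elicitation_slope
    # probe in the unclamped region: raise the floor contribution mid-range
    lev <- io_inverse(l$gain_rule$elicitation_floor + 5, l$io) # on-freq level
    s_on <- (elicited_gain_reduction(prec4k(lev + h), l) -
               elicited_gain_reduction(prec4k(lev), l)) / h
    expected_on <- if (lev + h <= l$io$breakpoint_db) s else
      s * l$io$compression
    expect_equal(s_on, expected_on, tolerance = 1e-4)
    lev_off <- l$gain_rule$elicitation_floor + 5 + l$off_freq_attenuation_db
    s_off <- (elicited_gain_reduction(prec24k(lev_off + h), l) -
                elicited_gain_reduction(prec24k(lev_off), l)) / h
    expect_equal(s_off, s, tolerance = 1e-4)
  }
})

test_that("threshold datasets follow the generative linear predictor", {
  # zero variance everywhere: data sit exactly on the fixed-effect plane
  p0 <- cohort_params_tonal(sd_intercept = 0, sd_class_offset = 0,
                            sd_residual = 0, n_participants = 2)
  d <- generate_threshold_dataset(p0, seed = 4)
  on60 <- d$estimate_db[d$precursor_class == "on_tone" & d$level_db == 60]
  expect_true(all(abs(on60 - 15.48) < 1e-9))
  off95 <- d$estimate_db[d$precursor_class == "off_tone" & d$level_db == 95]
  expect_true(all(abs(off95 - 22.21) < 1e-9))
  # seeded determinism
  expect_identical(generate_threshold_dataset(cohort_params_tonal(), 6),
                   generate_threshold_dataset(cohort_params_tonal(), 6))
})

test_that("broadband levels are carried in both overall dB and dB/ERB", {
  d <- generate_threshold_dataset(cohort_params_bbn(), seed = 2)
  bbn <- d[d$precursor_class == "bbn", ]
  expect_equal(bbn$level_db, bbn_level_per_erb(bbn$level_overall_db))
  tone <- d[d$precursor_class != "bbn", ]
  expect_equal(tone$level_db, tone$level_overall_db)
  expect_error(cohort_params_bbn(levels = list(on_tone = 40,
                                               bbn_overall = 70)),
               class = "mocgain_invalid_argument")
})

test_that("simulated-cohort moments match the configured components", {
  params <- cohort_params_tonal(n_participants = 150, runs_per_condition = 4)
  d <- generate_threshold_dataset(params, seed = 12)
  on <- d[d$precursor_class == "on_tone", ]
  per_part <- tapply(on$estimate_db - (-4.32 + 0.33 * on$level_db),
                     on$participant, mean)
  # between-participant variance of intercepts (residual contributes
  # 11.98 / n_obs to each participant mean)
  n_obs <- nrow(on) / params$n_participants
  expect_equal(var(per_part), 31.23 + 11.98 / n_obs, tolerance = 0.25)
  groups <- paste(on$participant, on$level_db)
  ss <- sum(unlist(tapply(on$estimate_db, groups,
                          function(x) sum((x - mean(x))^2))))
  df <- nrow(on) - length(unique(groups))
  expect_equal(ss / df, 11.98, tolerance = 0.05)
})

test_that("the full simulated experiment is complete and deterministic", {
  cohort <- generate_cohort(2, seed = 31)
  ex <- generate_full_experiment(cohort, seed = 8)
  ex2 <- generate_full_experiment(cohort, seed = 8)
  expect_identical(ex, ex2)
  # every run carries an explicit QC verdict
  expect_false(any(is.na(ex$runs$qc_pass)))
  # both tiers produced for every listener
  expect_setequal(unique(ex$runs$participant), c("S01", "S02"))
  expect_setequal(unique(ex$runs$experiment), c("exp1", "exp2", "exp3"))
  # gain-reduction points exist for all three precursor classes
  expect_setequal(unique(ex$points$precursor_class),
                  c("on_tone", "off_tone", "bbn"))
  # matched-masker conditions came out once per level and precursor state
  matched <- ex$runs[grepl("^matched", ex$runs$condition), ]
  expect_equal(nrow(matched), 2 * 2 * 2 * 2 * 2) # listener x level x side x prec x run
})

test_that("matched-masker shifts favour the off-frequency masker end-to-end", {
  cohort <- generate_cohort(3, seed = 14)
  for (l in cohort) {
    dg <- elicited_gain_reduction(prec4k(40), l)
    tab <- hypothesis_shift_table(l)
    gr <- tab[tab$hypothesis == "gain_reduction", ]
    if (dg > 0) {
      by_level <- split(gr, gr$off_masker_level_db)
      for (sub in by_level) {
        expect_gt(sub$shift_db[sub$masker_side == "off"],
                  sub$shift_db[sub$masker_side == "on"] - 1e-9)
      }
    }
  }
})
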