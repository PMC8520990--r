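test_that("gain-reduction estimates are unclamped differences", {
  expect_equal(gain_reduction_estimate(35, 20), 15)
  expect_equal(gain_reduction_estimate(20, 20), 0)
  expect_equal(gain_reduction_estimate(17, 20), -3)
  expect_error(gain_reduction_estimate(NA, 20),
               class = "mocgain_invalid_argument")
})

test_that("precursor shift pairs matching conditions only", {
  t1 <- load_table1()
  with_p <- t1[t1$participant == "P1" & t1$masker_freq_khz == 2.4 &
                 t1$masker_level_db == 65 & t1$precursor != "none", ]
  alone <- t1[t1$participant == "P1" & t1$masker_freq_khz == 2.4 &
                t1$masker_level_db == 65 & t1$precursor == "none", ]
  expect_equal(precursor_shift(with_p, alone), 9.64)
  on_p <- t1[t1$participant == "P1" & t1$masker_freq_khz == 4 &
               t1$masker_level_db == 16 & t1$precursor != "none", ]
  on_a <- t1[t1$participant == "P1" & t1$masker_freq_khz == 4 &
               t1$masker_level_db == 16 & t1$precursor == "none", ]
  expect_equal(precursor_shift(on_p, on_a), 4.70)
  expect_equal(precursor_shift(alone, alone), 0)
  expect_error(precursor_shift(with_p, on_a),
               class = "mocgain_invalid_pairing")
})

test_that("pooled t from summaries agrees with t.test on raw data", {
  # construct raw samples, summarise them, and compare the two routes
  set.seed(314)
  for (i in 1:10) {
    x <- rnorm(sample(2:6, 1), mean = runif(1, 20, 50), sd = runif(1, 0.5, 5))
    y <- rnorm(sample(2:6, 1), mean = runif(1, 20, 50), sd = runif(1, 0.5, 5))
    ours <- pooled_t_from_summary(mean(x), sd(x), length(x),
                                  mean(y), sd(y), length(y), tail = "two")
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("pooled t handles edge cases per its contract", {
  expect_error(pooled_t_from_summary(1, 0, 1, 2, 0, 2),
               class = "mocgain_invalid_argument")
  expect_error(pooled_t_from_summary(5, 0, 2, 5, 0, 2),
               class = "mocgain_invalid_argument")
  eq <- pooled_t_from_summary(5, 1, 3, 5, 1, 3, tail = "one")
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 0.5)
})

test_that("Holm correction matches step-down enumeration", {
  # direct enumeration of the step-down rule, independent of p.adjust
  holm_enum <- function(p, alpha) {
    o <- order(p)
    reject <- logical(length(p))
    for (k in seq_along(o)) {
      if (p[o[k]] < alpha / (length(p) - k + 1)) reject[o[k]] <- TRUE
      else break
    }
    reject
  }
  expect_equal(holm_bonferroni(c(0.01, 0.04))$reject, c(TRUE, TRUE))
  expect_equal(holm_bonferroni(c(0.03, 0.04))$reject, c(FALSE, FALSE))
  expect_equal(holm_bonferroni(0.03)$p_adjusted, 0.03)
  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    res <- holm_bonferroni(p)
    expect_equal(res$reject, holm_enum(p, 0.05))
    expect_true(all(diff(res$p_adjusted[order(p)]) >= 0))
    # Holm rejects a superset of Bonferroni, subset of unadjusted
    bonf <- p < 0.05 / length(p)
    expect_true(all(res$reject[bonf]))
    expect_true(all(p[res$reject] < 0.05))
  }
  expect_error(holm_bonferroni(c(0.2, 1.3)),
               class = "mocgain_invalid_argument")
})

test_that("floor filter is strict at the boundary and order-invariant", {
  pts <- tibble::tibble(participant = "a",
                        estimate_db = c(4.0, 4.1, -2, 25, 3.99))
  kept <- floor_filter(pts)
  expect_equal(kept$estimate_db, c(4.1, 25))
  shuffled <- pts[c(4, 1, 5, 3, 2), ]
  expect_setequal(floor_filter(shuffled)$estimate_db, kept$estimate_db)
  empty <- floor_filter(pts[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("GOM assembly sorts, pairs series and rejects duplicates", {
  tbl <- tibble::tibble(
    participant = "P9",
    masker_freq_khz = 2.4,
    masker_level_db = c(80, 40, 60, 80, 40, 60, NA, NA),
    precursor = rep(c("none", "tone"), each = 3) |> c("none", "tone"),
    mean_db = c(30, 12, 20, 45, 24, 36, 8, 22),
    sd_db = 1, n_runs = 2L)
  gom <- assemble_gom(tbl)
  with_level <- gom[!is.na(gom$masker_level_db), ]
  expect_equal(with_level$masker_level_db, c(40, 60, 80))
  expect_equal(with_level$shift_db, c(12, 16, 15))
  # masker-absent pair carries the masker-absent gain-reduction estimate
  absent <- gom[is.na(gom$masker_level_db), ]
  expect_equal(absent$shift_db,
               gain_reduction_estimate(22, 8))
  expect_error(assemble_gom(rbind(tbl, tbl[1, ])),
               class = "mocgain_ambiguous_rows")
})
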