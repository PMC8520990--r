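#' Masker-absent gain-reduction estimate
#'
#' Estimated cochlear gain reduction is the elevation of the signal
#' threshold with a precursor (and no masker) over the quiet threshold.
#' Negative values are preserved; removing floor-affected points is the job
#' of [floor_filter()].
#'
#' @param threshold_with_precursor_db Signal threshold with precursor, dB SPL.
#' @param quiet_threshold_db Signal threshold in quiet, dB SPL.
#' @return Estimated gain reduction in dB.
#' @export
gain_reduction_estimate <- function(threshold_with_precursor_db,
                                    quiet_threshold_db) {
  if (any(!is.finite(threshold_with_precursor_db)) ||
      any(!is.finite(quiet_threshold_db))) {
    stop_invalid("thresholds must be finite")
  }
  threshold_with_precursor_db - quiet_threshold_db
}

#' Threshold shift produced by a precursor
#'
#' Difference between the mean masked threshold with a precursor and the
#' mean threshold for the same masker alone. Both rows must describe the
#' same participant and masker condition.
#'
#' @param with_precursor,masker_alone Single rows of a summary-condition
#'   table (see [load_table1()] for the schema): lists or one-row data
#'   frames with `participant`, `masker_freq_khz`, `masker_level_db` and
#'   `mean_db` fields.
#' @return Shift in dB.
#' @export
precursor_shift <- function(with_precursor, masker_alone) {
  w <- as.list(with_precursor)
  a <- as.list(masker_alone)
  same <- identical(as.character(w$participant), as.character(a$participant)) &&
    isTRUE(all.equal(w$masker_freq_khz, a$masker_freq_khz)) &&
    isTRUE(all.equal(w$masker_level_db, a$masker_level_db))
  if (!same) {
    stop_invalid("conditions do not match (participant or masker differ)",
                 class = "mocgain_invalid_pairing")
  }
  w$mean_db - a$mean_db
}

#' Two-sample t-test from summary statistics
#'
#' Student's pooled-variance two-sample t-test computed from group means,
#' SDs and sizes, with `df = n1 + n2 - 2`. The one-tailed p-value is taken
#' from the upper tail of t (testing `mean1 > mean2`).
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param tail `"one"` or `"two"`.
#' @return A list with `t`, `df` and `p`.
#' @examples
#' pooled_t_from_summary(33.17, 0.24, 2, 27.67, 0.94, 2)$t # ~8.02
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                  tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (n1 < 2 || n2 < 2) stop_invalid("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop_invalid("SDs must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (m1 == m2) {
      stop_invalid("t is undefined: zero pooled variance with equal means")
    }
    t_stat <- sign(m1 - m2) * Inf
  } else {
    t_stat <- (m1 - m2) / se
  }
  p <- if (tail == "one") pt(t_stat, df, lower.tail = FALSE) else
    2 * pt(abs(t_stat), df, lower.tail = FALSE)
  list(t = t_stat, df = df, p = p)
}

#' Holm-Bonferroni step-down correction
#'
#' Standard step-down Holm procedure over a family of p-values. Adjusted
#' p-values come from `stats::p.adjust(method = "holm")`; a hypothesis is
#' rejected when its adjusted p-value is below `alpha`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble with `p`, `p_adjusted` and logical `reject`, in the
#'   input order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "holm")
  tibble::tibble(p = p_values, p_adjusted = adj, reject = adj < alpha)
}

#' Remove floor-affected gain-reduction points
#'
#' Keeps only points whose estimated gain reduction is strictly greater
#' than `min_db` (default 4 dB), removing floor effects that would bias the
#' fitted growth slopes.
#'
#' @param points A tibble with an `estimate_db` column (see
#'   [generate_threshold_dataset()] for the full point schema).
#' @param min_db Floor in dB; a point at exactly `min_db` is excluded.
#' @return The filtered tibble.
#' @export
floor_filter <- function(points, min_db = 4) {
  stopifnot(is.data.frame(points), "estimate_db" %in% names(points))
  points[points$estimate_db > min_db, , drop = FALSE]
}

#' Assemble growth-of-masking tables
#'
#' Reshapes a summary-condition table into per-participant growth-of-masking
#' (GOM) series: masked signal threshold against masker level, with the
#' precursor and no-precursor series paired side by side. Masker-absent rows
#' (`masker_level_db` of `NA`) are carried as the quiet / precursor-alone
#' anchor points whose difference is the masker-absent gain-reduction
#' estimate.
#'
#' @param conditions A summary-condition tibble with columns `participant`,
#'   `masker_freq_khz`, `masker_level_db`, `precursor` (`"none"` or a
#'   precursor label), `mean_db`, `sd_db`, `n_runs`.
#' @return A tibble sorted by participant and masker level with columns
#'   `participant`, `masker_freq_khz`, `masker_level_db`,
#'   `threshold_no_precursor_db`, `threshold_with_precursor_db`, `shift_db`.
#' @export
assemble_gom <- function(conditions) {
  req <- c("participant", "masker_freq_khz", "masker_level_db", "precursor",
           "mean_db")
  if (!all(req %in% names(conditions))) {
    stop_invalid(paste("missing columns:",
                       paste(setdiff(req, names(conditions)), collapse = ", ")))
  }
  key <- c("participant", "masker_freq_khz", "masker_level_db", "precursor")
  if (anyDuplicated(conditions[key]) > 0) {
    stop_invalid("duplicate (participant, masker, precursor) rows",
                 class = "mocgain_ambiguous_rows")
  }
  wide <- conditions |>
    dplyr::mutate(series = ifelse(.data$precursor == "none",
                                  "threshold_no_precursor_db",
                                  "threshold_with_precursor_db")) |>
    dplyr::select(dplyr::all_of(c("participant", "masker_freq_khz",
                                  "masker_level_db", "series", "mean_db"))) |>
    tidyr::pivot_wider(names_from = "series", values_from = "mean_db")
  for (col in c("threshold_no_precursor_db", "threshold_with_precursor_db")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide |>
    dplyr::mutate(shift_db = .data$threshold_with_precursor_db -
                    .data$threshold_no_precursor_db) |>
    dplyr::arrange(.data$participant, .data$masker_freq_khz,
                   !is.na(.data$masker_level_db), .data$masker_level_db)
}
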