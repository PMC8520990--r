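# column schemas for the package's tabular interchange formats
.schemas <- list(
  summary_condition = c(participant = "character", pair_level_db = "numeric",
                        masker_freq_khz = "numeric",
                        masker_level_db = "numeric", precursor = "character",
                        mean_db = "numeric", sd_db = "numeric",
                        n_runs = "integer"),
  gain_reduction_point = c(participant = "character",
                           precursor_class = "character",
                           level_db = "numeric",
                           level_overall_db = "numeric", run = "integer",
                           estimate_db = "numeric")
)

#' Read and write schema-validated CSV tables
#'
#' Strict CSV round-tripping for the package's two interchange formats:
#' summary-condition tables (one row per condition with mean, SD and run
#' count) and gain-reduction point tables (one row per run). Unknown or
#' missing columns, and non-numeric cells in numeric columns, raise parse
#' errors naming the offending column.
#'
#' @param path File path.
#' @param schema `"summary_condition"` or `"gain_reduction_point"`.
#' @param allow_extra Keep unknown columns instead of rejecting them.
#' @return A tibble with typed columns in schema order.
#' @export
read_table <- function(path, schema = c("summary_condition",
                                        "gain_reduction_point"),
                       allow_extra = FALSE) {
  schema <- match.arg(schema)
  spec <- .schemas[[schema]]
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(names(spec), names(raw))
  if (length(missing) > 0) {
    stop_invalid(sprintf("missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "mocgain_parse_error")
  }
  extra <- setdiff(names(raw), names(spec))
  if (length(extra) > 0 && !allow_extra) {
    stop_invalid(sprintf("unknown column(s): %s",
                         paste(extra, collapse = ", ")),
                 class = "mocgain_parse_error")
  }
  for (col in names(spec)) {
    target <- spec[[col]]
    if (target %in% c("numeric", "integer")) {
      vals <- raw[[col]]
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(is.na(parsed) & !is.na(vals) &
                     !(trimws(as.character(vals)) %in% c("", "NA")))
      if (length(bad) > 0) {
        stop_invalid(sprintf("non-numeric value in column '%s', row %d",
                             col, bad[1]),
                     class = "mocgain_parse_error")
      }
      raw[[col]] <- if (target == "integer") as.integer(parsed) else parsed
    } else {
      raw[[col]] <- as.character(raw[[col]])
    }
  }
  tibble::as_tibble(raw[, c(names(spec), if (allow_extra) extra)])
}

#' @rdname read_table
#' @param x A data frame conforming to the schema.
#' @export
write_table <- function(x, path, schema = c("summary_condition",
                                            "gain_reduction_point")) {
  schema <- match.arg(schema)
  spec <- .schemas[[schema]]
  missing <- setdiff(names(spec), names(x))
  if (length(missing) > 0) {
    stop_invalid(sprintf("missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "mocgain_parse_error")
  }
  write.csv(x[, names(spec)], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged matched-masker summary data
#'
#' Loads the packaged summary table of the equally-effective-masker
#' experiment: per participant and matched masker-level pair, the mean
#' masked signal threshold (dB SPL), SD and run count for the off-frequency
#' (2.4-kHz) and on-frequency (4-kHz) masker, each with and without the
#' common 40-dB SPL 4-kHz precursor. Run counts are 2 per condition except
#' where noted in the source: 3 for P5's 65-dB off-frequency precursor
#' condition (an extra run was collected), and 4 for P2 (a
#' high-variability listener whose tests were reported with 6 degrees of
#' freedom).
#'
#' @return A summary-condition tibble (see [read_table()]).
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "mocgain",
                      mustWork = TRUE)
  read_table(path, "summary_condition")
}

#' Reproduce the matched-masker t-statistics
#'
#' Recomputes, from a matched-masker summary table, the one-tailed
#' pooled-variance t-tests for the hypothesis that the off-frequency
#' masker condition with a precursor yields a higher signal threshold than
#' the equally effective on-frequency condition with the same precursor:
#' one test per participant and matched level pair, Holm-Bonferroni
#' corrected, plus the group-level test comparing the per-participant
#' average threshold shifts (precursor minus masker-alone, averaged over
#' the two matched levels) between the off- and on-frequency maskers.
#'
#' @param tbl A summary-condition tibble; defaults to [load_table1()].
#' @param alpha Family-wise error rate for the Holm correction.
#' @return A list with `individual` (tibble: participant, pair_level_db,
#'   t, df, p, p_adjusted, reject) and `group` (tibble: t, df, p). The
#'   Holm family comprises all individual tests together with the group
#'   test.
#' @export
reproduce_table1_stats <- function(tbl = load_table1(), alpha = 0.05) {
  stopifnot(is.data.frame(tbl))
  pairs <- unique(tbl[, c("participant", "pair_level_db")])
  ind <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- tbl[tbl$participant == pairs$participant[i] &
                 tbl$pair_level_db == pairs$pair_level_db[i] &
                 tbl$precursor != "none", ]
    off <- sub[sub$masker_freq_khz == 2.4, ]
    on <- sub[sub$masker_freq_khz == 4, ]
    res <- pooled_t_from_summary(off$mean_db, off$sd_db, off$n_runs,
                                 on$mean_db, on$sd_db, on$n_runs,
                                 tail = "one")
    tibble::tibble(participant = pairs$participant[i],
                   pair_level_db = pairs$pair_level_db[i],
                   t = res$t, df = res$df, p = res$p)
  })
  individual <- dplyr::bind_rows(ind)

  shifts <- assemble_gom(tbl |>
      dplyr::mutate(masker_level_db = paste(.data$pair_level_db,
                                            .data$masker_freq_khz))) |>
    dplyr::group_by(.data$participant, .data$masker_freq_khz) |>
    dplyr::summarise(shift_db = mean(.data$shift_db), .groups = "drop")
  off_shifts <- shifts$shift_db[shifts$masker_freq_khz == "2.4"]
  on_shifts <- shifts$shift_db[shifts$masker_freq_khz == "4"]
  g <- pooled_t_from_summary(mean(off_shifts), sd(off_shifts),
                             length(off_shifts), mean(on_shifts),
                             sd(on_shifts), length(on_shifts), tail = "one")
  group <- tibble::tibble(t = g$t, df = g$df, p = g$p)

  holm <- holm_bonferroni(c(individual$p, group$p), alpha = alpha)
  individual$p_adjusted <- holm$p_adjusted[seq_len(nrow(individual))]
  individual$reject <- holm$reject[seq_len(nrow(individual))]
  group$p_adjusted <- holm$p_adjusted[nrow(holm)]
  list(individual = individual, group = group)
}
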