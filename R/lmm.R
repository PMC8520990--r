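#' Mixed-effects model of gain-reduction growth with elicitor level
#'
#' Fits estimated gain reduction against precursor level, precursor class
#' and their interaction, with the on-frequency tone as the reference
#' class, by restricted maximum likelihood (REML). Two random-effect
#' structures are supported:
#' * `"slopes"`: by-participant random intercepts plus random per-class
#'   offsets (used for the two-class tonal design);
#' * `"intercepts"`: by-participant random intercepts only (used for the
#'   three-class design including broadband noise).
#'
#' Levels enter uncentred, in dB SPL for tones and dB/ERB for broadband
#' noise, so the intercept is interpretable at 0 dB. Fixed-effect p-values
#' use the Satterthwaite degrees-of-freedom approximation (via lmerTest).
#' Non-convergence and singular fits are flagged, never silently replaced.
#'
#' @param points A tibble of gain-reduction points with columns
#'   `participant`, `precursor_class` (`on_tone`, `off_tone`, `bbn`),
#'   `level_db` and `estimate_db`, already floor-filtered where desired.
#' @param random_structure `"slopes"` or `"intercepts"`.
#' @return An object of class `lmm_result`: a list with `fixed` (tibble:
#'   term, estimate, se, t, df, p), `varcomp` (tibble of variance
#'   components with SDs and correlations), `sigma`, `converged`,
#'   `singular`, `random_structure` and the fitted `model`.
#' @export
fit_gain_reduction_lmm <- function(points,
                                   random_structure = c("slopes",
                                                        "intercepts")) {
  random_structure <- match.arg(random_structure)
  req <- c("participant", "precursor_class", "level_db", "estimate_db")
  if (!all(req %in% names(points))) {
    stop_invalid(paste("missing columns:",
                       paste(setdiff(req, names(points)), collapse = ", ")))
  }
  d <- as.data.frame(points)
  classes <- intersect(c("on_tone", "off_tone", "bbn"),
                       unique(as.character(d$precursor_class)))
  if (!"on_tone" %in% classes) {
    stop_invalid("the reference class 'on_tone' must be present")
  }
  if (length(classes) < 2) {
    stop_invalid("at least two precursor classes are required")
  }
  d$precursor_class <- factor(d$precursor_class, levels = classes)
  d$participant <- factor(d$participant)
  if (nlevels(d$participant) < 2) {
    stop_invalid("at least two participants are required")
  }

  fml <- if (random_structure == "slopes") {
    estimate_db ~ level_db * precursor_class + (1 + precursor_class | participant)
  } else {
    estimate_db ~ level_db * precursor_class + (1 | participant)
  }

  converged <- TRUE
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = d, REML = TRUE),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  singular <- lme4::isSingular(fit)

  smry <- summary(fit)$coefficients
  fixed <- tibble::tibble(
    term = rownames(smry),
    estimate = smry[, "Estimate"],
    se = smry[, "Std. Error"],
    df = smry[, "df"],
    t = smry[, "t value"],
    p = smry[, "Pr(>|t|)"])

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble::tibble(
    group = vc$grp, term1 = vc$var1, term2 = vc$var2,
    variance = vc$vcov, sd_or_corr = vc$sdcor)

  structure(
    list(fixed = fixed, varcomp = varcomp, sigma = stats::sigma(fit),
         converged = converged, singular = singular,
         random_structure = random_structure, model = fit),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> random structure: %s%s%s\n", x$random_structure,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular fit]" else ""))
  print(as.data.frame(x$fixed), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Extract a named fixed-effect estimate from an LMM result
#'
#' Convenience accessor: `lmm_coef(res, "level_db")` returns the fitted
#' level slope for the reference (on-frequency) class;
#' `"level_db:precursor_classoff_tone"` the off-tone interaction, etc.
#'
#' @param result An [fit_gain_reduction_lmm()] result.
#' @param term Fixed-effect term name.
#' @return The estimate, a single number.
#' @export
lmm_coef <- function(result, term) {
  stopifnot(inherits(result, "lmm_result"))
  i <- match(term, result$fixed$term)
  if (is.na(i)) {
    stop_invalid(sprintf("no fixed-effect term '%s'; available: %s", term,
                         paste(result$fixed$term, collapse = ", ")))
  }
  unname(result$fixed$estimate[i])
}
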