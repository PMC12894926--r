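#' Winsorization specification
#'
#' Percentile bounds for clamping extreme biomarker values. The percentile
#' convention is linear interpolation between order statistics
#' (`stats::quantile` type 7), declared here so downstream cut points are
#' reproducible bit-for-bit.
#'
#' @param lower_percentile,upper_percentile Fractions with
#'   `0 <= lower < upper <= 1`; defaults clamp the bottom and top 1% of
#'   values to the 1st and 99th percentiles.
#' @return An object of class `winsorization_spec`.
#' @export
winsorization_spec <- function(lower_percentile = 0.01,
                               upper_percentile = 0.99) {
  stop_if_not(is.finite(lower_percentile) && is.finite(upper_percentile) &&
                lower_percentile >= 0 && lower_percentile < upper_percentile &&
                upper_percentile <= 1,
              "need 0 <= lower_percentile < upper_percentile <= 1",
              class = "bioagerisk_config_error")
  structure(list(lower_percentile = lower_percentile,
                 upper_percentile = upper_percentile,
                 percentile_rule = "type7"),
            class = "winsorization_spec")
}

#' Winsorize a biomarker vector
#'
#' Clamps values below/above the spec's percentiles to those percentiles.
#' Idempotent; order of unclamped values is preserved. When `cuts` is
#' supplied (a length-2 vector of stored cut points), those are reused
#' instead of re-estimating percentiles, which is how fitted cut points are
#' projected onto new data.
#'
#' @param values Numeric vector with at least 2 finite values (`NA`s pass
#'   through untouched).
#' @param spec A [winsorization_spec()].
#' @param cuts Optional stored cut points `c(lower, upper)`.
#' @return The clamped vector, with the cut points used attached as
#'   `attr(, "cuts")`.
#' @export
winsorize_panel <- function(values, spec = winsorization_spec(), cuts = NULL) {
  stop_if_not(sum(is.finite(values)) >= 2,
              "winsorize_panel needs at least 2 finite values",
              class = "bioagerisk_empty_input_error")
  if (is.null(cuts)) {
    cuts <- panel_quantile(values, c(spec$lower_percentile,
                                     spec$upper_percentile))
  }
  out <- pmin(pmax(values, cuts[1]), cuts[2])
  attr(out, "cuts") <- cuts
  out
}

#' Winsorize the biomarker columns of a cohort
#'
#' Fit-and-apply on the supplied sample (cross-sectional baseline usage);
#' percentiles are computed pooled across sexes unless `by_sex = TRUE`.
#'
#' @param cohort Cohort data.frame.
#' @param biomarkers Columns to winsorize (default the full 14-marker panel
#'   intersected with available columns).
#' @param spec A [winsorization_spec()].
#' @param by_sex Compute percentiles within sex strata instead of pooled.
#' @return List with `cohort` (clamped) and `cuts` (named list of cut-point
#'   pairs; for `by_sex = TRUE`, nested by stratum).
#' @export
winsorize_cohort <- function(cohort, biomarkers = intersect(all_biomarkers(),
                                                            names(cohort)),
                             spec = winsorization_spec(), by_sex = FALSE) {
  assert_cols(cohort, biomarkers)
  cuts <- list()
  if (by_sex) {
    assert_cols(cohort, "sex")
    for (b in biomarkers) {
      cuts[[b]] <- list()
      for (s in levels(factor(cohort$sex))) {
        idx <- cohort$sex == s
        w <- winsorize_panel(cohort[[b]][idx], spec)
        cohort[[b]][idx] <- as.numeric(w)
        cuts[[b]][[s]] <- attr(w, "cuts")
      }
    }
  } else {
    for (b in biomarkers) {
      w <- winsorize_panel(cohort[[b]], spec)
      cohort[[b]] <- as.numeric(w)
      cuts[[b]] <- attr(w, "cuts")
    }
  }
  list(cohort = cohort, cuts = cuts)
}

#' Impute covariates by sex-stratified conditional means
#'
#' Continuous covariate gaps are replaced by the mean among same-sex
#' participants; missing categorical values become an explicit `"unknown"`
#' level. Score biomarkers are deliberately *not* imputed: participants
#' missing any biomarker are excluded upstream by [apply_exclusions()].
#'
#' @param cohort Cohort data.frame with fully observed `sex`.
#' @param covariates Covariate column names to impute.
#' @return The cohort with gaps filled.
#' @export
impute_covariates <- function(cohort, covariates) {
  assert_cols(cohort, c("sex", covariates))
  stop_if_not(!anyNA(cohort$sex), "sex must be fully observed",
              class = "bioagerisk_schema_error")
  for (v in covariates) {
    col <- cohort[[v]]
    if (!anyNA(col)) next
    if (is.numeric(col)) {
      for (s in unique(cohort$sex)) {
        idx <- cohort$sex == s
        m <- mean(col[idx], na.rm = TRUE)
        stop_if_not(is.finite(m),
                    "covariate '", v, "' has no observed values in a sex ",
                    "stratum; stratum mean undefined",
                    class = "bioagerisk_stratum_error")
        col[idx & is.na(col)] <- m
      }
    } else {
      col <- as.character(col)
      col[is.na(col)] <- "unknown"
      col <- factor(col)
    }
    cohort[[v]] <- col
  }
  cohort
}

#' Apply sequential cohort exclusion rules
#'
#' Removes participants failing any active rule and reports per-rule removal
#' counts in application order (biomarkers, then genetics, then baseline
#' vascular history), so a participant failing several rules is counted only
#' under the first -- the sequential-flowchart accounting convention.
#'
#' Rules: `"missing_biomarker"` (any `NA` in the score biomarker panel),
#' `"missing_genetics"` (any `NA` dosage), `"baseline_vascular"` (a logical
#' column of that name flags prevalent vascular disease at or within 30 days
#' of baseline, prepared upstream).
#'
#' @param cohort Cohort data.frame.
#' @param rules Character vector of active rules, in application order.
#' @param biomarkers Biomarker columns checked by `"missing_biomarker"`.
#' @param dosage_cols Dosage columns checked by `"missing_genetics"`
#'   (default: columns matching `"^snp"`).
#' @return List with `cohort` (rows retained) and `report`, a data.frame
#'   `(rule, removed, remaining)` in application order.
#' @export
apply_exclusions <- function(cohort,
                             rules = c("missing_biomarker",
                                       "missing_genetics",
                                       "baseline_vascular"),
                             biomarkers = intersect(all_biomarkers(),
                                                    names(cohort)),
                             dosage_cols = grep("^snp", names(cohort),
                                                value = TRUE)) {
  known <- c("missing_biomarker", "missing_genetics", "baseline_vascular")
  bad <- setdiff(rules, known)
  stop_if_not(length(bad) == 0, "unknown exclusion rule(s): ",
              paste(bad, collapse = ", "),
              class = "bioagerisk_config_error")
  report <- data.frame(rule = character(), removed = integer(),
                       remaining = integer(), stringsAsFactors = FALSE)
  for (rule in rules) {
    flag <- switch(rule,
      missing_biomarker = if (length(biomarkers)) {
        rowSums(is.na(cohort[, biomarkers, drop = FALSE])) > 0
      } else rep(FALSE, nrow(cohort)),
      missing_genetics = if (length(dosage_cols)) {
        rowSums(is.na(cohort[, dosage_cols, drop = FALSE])) > 0
      } else rep(FALSE, nrow(cohort)),
      baseline_vascular = {
        assert_cols(cohort, "baseline_vascular")
        cohort$baseline_vascular %in% TRUE
      })
    cohort <- cohort[!flag, , drop = FALSE]
    report <- rbind(report, data.frame(
      rule = rule, removed = sum(flag), remaining = nrow(cohort),
      stringsAsFactors = FALSE))
  }
  list(cohort = cohort, report = report)
}
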