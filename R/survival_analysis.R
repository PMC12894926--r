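cox_formula <- function(terms, time = "time_years", event = "aaa_event") {
  as.formula(paste0("Surv(", time, ", ", event, ") ~ ",
                    paste(terms, collapse = " + ")))
}

tidy_cox <- function(fit, conf_level = 0.95) {
  s <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    term = rownames(s),
    loghr = s[, "coef"],
    hr = exp(s[, "coef"]),
    lo = exp(s[, "coef"] - z * s[, "se(coef)"]),
    hi = exp(s[, "coef"] + z * s[, "se(coef)"]),
    se = s[, "se(coef)"],
    p = s[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fit an adjusted Cox proportional hazards model
#'
#' Partial-likelihood maximization with the Efron tie approximation;
#' categorical covariates expand against their factor reference levels;
#' Wald confidence intervals on the log hazard ratio scale. The exposure
#' can enter as supplied (`"continuous"` or a binary flag), per standard
#' deviation (`"per_sd"`: the column is divided by its sample SD), or as
#' within-sample quartile indicators (`"quartile"`, reference = quartile 1).
#'
#' @param cohort Cohort data.frame.
#' @param exposure Name of the exposure column.
#' @param covariates Character vector of adjustment covariate columns.
#' @param exposure_type One of `"continuous"`, `"per_sd"`, `"quartile"`,
#'   `"binary"`.
#' @param time,event Follow-up time and event indicator columns.
#' @return Object of class `cox_fit`: list with `fit` (the `coxph` object),
#'   `terms` (tidy data.frame: term, loghr, hr, lo, hi, se, p), `n`,
#'   `events`, `loglik`, and `exposure_terms` (the term labels belonging to
#'   the exposure).
#' @export
fit_cox <- function(cohort, exposure, covariates = character(),
                    exposure_type = c("continuous", "per_sd", "quartile",
                                      "binary"),
                    time = "time_years", event = "aaa_event") {
  exposure_type <- match.arg(exposure_type)
  assert_cols(cohort, c(exposure, covariates, time, event))
  stop_if_not(sum(cohort[[event]]) >= 1, "need at least one event",
              class = "bioagerisk_size_error")
  dat <- cohort
  exp_col <- exposure
  if (exposure_type == "per_sd") {
    exp_col <- paste0(exposure, "_per_sd")
    dat[[exp_col]] <- dat[[exposure]] / sd(dat[[exposure]])
  } else if (exposure_type == "quartile") {
    exp_col <- paste0(exposure, "_q")
    dat[[exp_col]] <- quartile_index(dat[[exposure]], as_factor = TRUE)
  } else if (exposure_type == "binary") {
    dat[[exposure]] <- as.numeric(dat[[exposure]] %in% c(TRUE, 1))
  }
  fml <- cox_formula(c(exp_col, covariates), time, event)
  fit <- coxph(fml, data = dat, ties = "efron", model = TRUE)
  if (!is.null(fit$info) && any(grepl("infinite", fit$info))) {
    warning("possible separation in Cox fit: ", fit$info)
  }
  terms_df <- tidy_cox(fit)
  structure(list(
    fit = fit, terms = terms_df,
    n = fit$n, events = fit$nevent, loglik = fit$loglik[2],
    exposure = exposure,
    exposure_terms = grep(exp_col, terms_df$term, fixed = TRUE,
                          value = TRUE),
    data = dat, formula = fml
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model: n =", x$n, ", events =", x$events, "\n")
  print(x$terms, digits = 3)
  invisible(x)
}

#' Proportional hazards diagnostics (scaled Schoenfeld residuals)
#'
#' Correlation test of the scaled Schoenfeld residuals against transformed
#' time, per term and globally.
#'
#' @param cox_fit A [fit_cox()] result (or a `coxph` fit).
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return data.frame `(term, chisq, df, p)` with the global row last.
#' @export
test_proportional_hazards <- function(cox_fit, transform = "km") {
  fit <- if (inherits(cox_fit, "cox_fit")) cox_fit$fit else cox_fit
  stop_if_not(fit$nevent >= 2,
              "proportional hazards test undefined with fewer than 2 events",
              class = "bioagerisk_degenerate_design_error")
  z <- cox.zph(fit, transform = transform)
  data.frame(term = rownames(z$table),
             chisq = z$table[, "chisq"],
             df = z$table[, "df"],
             p = z$table[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Within-sample quartile index
#'
#' Cuts a continuous exposure at its 25th/50th/75th sample percentiles;
#' values at a boundary go to the lower quartile.
#'
#' @param x Numeric vector.
#' @param as_factor Return a factor (reference = `"Q1"`) instead of the
#'   integer codes 1-4.
#' @return Integer vector in 1..4, or a factor.
#' @export
quartile_index <- function(x, as_factor = FALSE) {
  cuts <- panel_quantile(x, c(0.25, 0.5, 0.75))
  idx <- cut(x, breaks = c(-Inf, cuts, Inf), labels = FALSE, right = TRUE)
  if (as_factor) factor(paste0("Q", idx), levels = paste0("Q", 1:4)) else idx
}

#' Trend test across exposure quartiles
#'
#' Replaces the exposure by its within-sample quartile index coded as the
#' integers 1-4, entered as a single continuous covariate in the Cox model;
#' returns the Wald p-value on its coefficient.
#'
#' @inheritParams fit_cox
#' @return List with `p_trend`, `loghr_per_quartile`, and the underlying
#'   `cox_fit`.
#' @export
quartile_trend_test <- function(cohort, exposure, covariates = character(),
                                time = "time_years", event = "aaa_event") {
  dat <- cohort
  dat$.trend <- quartile_index(dat[[exposure]])
  fit <- fit_cox(dat, ".trend", covariates, "continuous", time, event)
  row <- fit$terms[fit$terms$term == ".trend", ]
  list(p_trend = row$p, loghr_per_quartile = row$loghr, fit = fit)
}

#' Restricted cubic spline basis (Harrell's truncated-power form)
#'
#' For `k` knots `t_1 < ... < t_k` the basis has `k - 1` columns: the
#' identity, plus restricted cubic terms normalized by `(t_k - t_1)^2` so
#' that the function is linear beyond the boundary knots. With the default
#' three knots this is one linear plus one restricted term.
#'
#' @param x Numeric vector.
#' @param knots Knot locations (default: 25th/50th/75th sample percentiles
#'   of `x`), strictly increasing.
#' @return Matrix with `length(knots) - 1` columns and attribute `knots`.
#' @export
rcs_basis <- function(x, knots = panel_quantile(x, c(0.25, 0.5, 0.75))) {
  knots <- sort(as.numeric(knots))
  stop_if_not(length(knots) >= 3 && !any(duplicated(knots)),
              "need at least 3 distinct knots",
              class = "bioagerisk_knot_error")
  k <- length(knots)
  tk <- knots[k]
  tk1 <- knots[k - 1]
  norm2 <- (tk - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pos3(x - knots[j]) -
                       pos3(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                       pos3(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / norm2
  }
  colnames(out) <- paste0("rcs", seq_len(k - 1))
  attr(out, "knots") <- knots
  out
}

#' Restricted cubic spline dose-response curve
#'
#' Fits a Cox model with a 3-knot restricted cubic spline in the exposure
#' (knots at the 25th/50th/75th sample percentiles) plus covariates, and
#' returns the hazard ratio curve `HR(x) = exp(f(x) - f(ref))` with Wald
#' confidence bands, relative to the reference exposure value (the sample
#' median by default), where `HR = 1` exactly. The non-linearity p-value is
#' the Wald test on the restricted cubic term; the overall p-value the
#' 2-df Wald test on both spline terms.
#'
#' @inheritParams fit_cox
#' @param grid Exposure values at which to evaluate the curve (default: 100
#'   points spanning the 1st-99th percentiles).
#' @param ref Reference exposure value (default: median).
#' @param conf_level Confidence level for the band.
#' @return Object of class `dose_response_curve`: list with `knots`, `ref`,
#'   `curve` (data.frame: exposure, loghr, hr, lo, hi), `p_overall`,
#'   `p_nonlinear`, and the `coxph` fit.
#' @export
rcs_dose_response <- function(cohort, exposure, covariates = character(),
                              grid = NULL, ref = NULL, conf_level = 0.95,
                              time = "time_years", event = "aaa_event") {
  assert_cols(cohort, c(exposure, covariates, time, event))
  xv <- cohort[[exposure]]
  basis <- rcs_basis(xv)
  knots <- attr(basis, "knots")
  dat <- cbind(cohort, basis)
  fml <- cox_formula(c(colnames(basis), covariates), time, event)
  fit <- coxph(fml, data = dat, ties = "efron", model = TRUE)
  beta <- coef(fit)[colnames(basis)]
  v <- vcov(fit)[colnames(basis), colnames(basis)]

  if (is.null(ref)) ref <- median(xv)
  if (is.null(grid)) {
    grid <- seq(panel_quantile(xv, 0.01), panel_quantile(xv, 0.99),
                length.out = 100)
  }
  bg <- rcs_basis(grid, knots)
  br <- rcs_basis(ref, knots)
  d <- sweep(bg, 2, as.vector(br))      # contrast f(x) - f(ref)
  loghr <- as.vector(d %*% beta)
  se <- sqrt(rowSums((d %*% v) * d))
  z <- qnorm(1 - (1 - conf_level) / 2)

  wald <- function(idx) {
    b <- beta[idx]
    as.numeric(pchisq(t(b) %*% solve(v[idx, idx, drop = FALSE]) %*% b,
                      df = length(idx), lower.tail = FALSE))
  }
  structure(list(
    knots = knots, ref = ref,
    curve = data.frame(exposure = grid, loghr = loghr, hr = exp(loghr),
                       lo = exp(loghr - z * se), hi = exp(loghr + z * se)),
    p_overall = wald(seq_along(beta)),
    p_nonlinear = wald(seq_along(beta)[-1]),
    fit = fit
  ), class = "dose_response_curve")
}

#' Fine-Gray subdistribution hazard model
#'
#' Regression on the subdistribution hazard of the event of interest,
#' treating death as a competing event, via the censoring-weighted partial
#' likelihood ([survival::finegray()] with Kaplan-Meier censoring weights,
#' then a weighted Cox fit). With zero competing deaths this coincides with
#' the cause-specific Cox model.
#'
#' @inheritParams fit_cox
#' @param death Death indicator column.
#' @return A `cox_fit`-shaped object (subdistribution scale).
#' @export
fit_fine_gray <- function(cohort, exposure, covariates = character(),
                          exposure_type = c("continuous", "per_sd",
                                            "quartile", "binary"),
                          time = "time_years", event = "aaa_event",
                          death = "death_event") {
  exposure_type <- match.arg(exposure_type)
  assert_cols(cohort, c(exposure, covariates, time, event, death))
  stop_if_not(sum(cohort[[event]]) >= 1,
              "no events of interest; subdistribution fit undefined",
              class = "bioagerisk_size_error")
  dat <- cohort
  exp_col <- exposure
  if (exposure_type == "per_sd") {
    exp_col <- paste0(exposure, "_per_sd")
    dat[[exp_col]] <- dat[[exposure]] / sd(dat[[exposure]])
  } else if (exposure_type == "quartile") {
    exp_col <- paste0(exposure, "_q")
    dat[[exp_col]] <- quartile_index(dat[[exposure]], as_factor = TRUE)
  } else if (exposure_type == "binary") {
    dat[[exposure]] <- as.numeric(dat[[exposure]] %in% c(TRUE, 1))
  }
  dat$.status <- factor(ifelse(dat[[event]] == 1, "event",
                               ifelse(dat[[death]] == 1, "death", "censor")),
                        levels = c("censor", "event", "death"))
  fg <- finegray(as.formula(paste0("Surv(", time, ", .status) ~ .")),
                 data = dat[, c(time, ".status", exp_col, covariates)],
                 etype = "event")
  fml <- as.formula(paste0("Surv(fgstart, fgstop, fgstatus) ~ ",
                           paste(c(exp_col, covariates), collapse = " + ")))
  fit <- coxph(fml, data = fg, weights = fg$fgwt, ties = "efron", model = TRUE)
  terms_df <- tidy_cox(fit)
  structure(list(
    fit = fit, terms = terms_df, n = nrow(dat),
    events = sum(dat[[event]]), loglik = fit$loglik[2],
    exposure = exposure,
    exposure_terms = grep(exp_col, terms_df$term, fixed = TRUE, value = TRUE)
  ), class = "cox_fit")
}

#' Landmark filtering for reverse-causation sensitivity analysis
#'
#' Moves the start of follow-up to `landmark_years` after baseline:
#' participants whose event or censoring occurred at or before the landmark
#' are removed, and remaining follow-up times are shifted down by the
#' landmark.
#'
#' @param cohort Cohort data.frame.
#' @param landmark_years Landmark, years (default 2; 0 is the identity).
#' @param time Follow-up time column.
#' @return Filtered cohort with shifted times.
#' @export
landmark_filter <- function(cohort, landmark_years = 2,
                            time = "time_years") {
  assert_cols(cohort, time)
  if (landmark_years == 0) return(cohort)
  keep <- cohort[[time]] > landmark_years
  if (!any(keep)) {
    warning("landmark filter removed every participant")
  }
  out <- cohort[keep, , drop = FALSE]
  out[[time]] <- out[[time]] - landmark_years
  out
}
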