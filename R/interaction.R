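#' Joint exposure-by-genetic-risk classification
#'
#' Cross-classifies the accelerated-ageing flag with the three genetic risk
#' groups into a 6-level factor, reference = non-accelerated & low risk
#' (the comparator of joint-association hazard ratio tables), levels
#' ordered low/intermediate/high within non-accelerated then accelerated.
#'
#' @param accelerated Logical (or 0/1) accelerated-ageing flag.
#' @param risk_group Factor with levels `low`, `intermediate`, `high`.
#' @return 6-level factor.
#' @export
build_joint_groups <- function(accelerated, risk_group) {
  acc <- factor(ifelse(accelerated %in% c(TRUE, 1), "accel", "nonaccel"),
                levels = c("nonaccel", "accel"))
  risk_group <- factor(risk_group, levels = c("low", "intermediate", "high"))
  stop_if_not(!anyNA(acc) && !anyNA(risk_group),
              "accelerated and risk_group must be complete",
              class = "bioagerisk_schema_error")
  lev <- as.vector(outer(c("low", "intermediate", "high"),
                         c("nonaccel", "accel"),
                         function(r, a) paste(a, r, sep = ".")))
  factor(paste(acc, risk_group, sep = "."), levels = lev)
}

#' @rdname build_joint_groups
#' @param quartile Factor/integer exposure quartile (1-4 or `"Q1"`..`"Q4"`);
#'   the 12-level variant's reference is quartile 1 & low risk.
#' @export
build_joint_quartile_groups <- function(quartile, risk_group) {
  q <- if (is.numeric(quartile)) paste0("Q", quartile) else as.character(quartile)
  q <- factor(q, levels = paste0("Q", 1:4))
  risk_group <- factor(risk_group, levels = c("low", "intermediate", "high"))
  stop_if_not(!anyNA(q) && !anyNA(risk_group),
              "quartile and risk_group must be complete",
              class = "bioagerisk_schema_error")
  lev <- as.vector(outer(c("low", "intermediate", "high"), paste0("Q", 1:4),
                         function(r, a) paste(a, r, sep = ".")))
  factor(paste(q, risk_group, sep = "."), levels = lev)
}

#' RERI and attributable proportion from component hazard ratios
#'
#' The formula layer of additive-interaction analysis on the hazard ratio
#' scale: given the hazard ratios of the singly exposed (`hr10`, `hr01`) and
#' doubly exposed (`hr11`) groups relative to the doubly unexposed
#' reference, the relative excess risk due to interaction is
#' `RERI = HR11 - HR10 - HR01 + 1` and the attributable proportion
#' `AP = RERI / HR11`.
#'
#' @param hr10,hr01,hr11 Component hazard ratios.
#' @return List with `reri` and `ap`.
#' @export
reri_ap <- function(hr10, hr01, hr11) {
  reri <- hr11 - hr10 - hr01 + 1
  list(reri = reri, ap = attributable_proportion(reri, hr11))
}

#' @rdname reri_ap
#' @param reri Relative excess risk due to interaction.
#' @param hr11 Hazard ratio of the doubly exposed group.
#' @export
attributable_proportion <- function(reri, hr11) {
  reri / hr11
}

interaction_components <- function(cohort, exposure, risk, covariates,
                                   time, event) {
  dat <- cohort
  dat$.cell <- factor(
    paste0("e", as.integer(dat[[exposure]] %in% c(TRUE, 1)),
           "g", as.integer(dat[[risk]] %in% c(TRUE, 1))),
    levels = c("e0g0", "e1g0", "e0g1", "e1g1"))
  ev <- tapply(dat[[event]], dat$.cell, sum)
  ev[is.na(ev)] <- 0
  if (any(ev == 0)) {
    stop_if_not(FALSE, "no events in cross-class cell(s): ",
                paste(names(ev)[ev == 0], collapse = ", "),
                class = "bioagerisk_estimation_error")
  }
  fit <- coxph(cox_formula(c(".cell", covariates), time, event),
               data = dat, ties = "efron", model = TRUE)
  hr <- exp(coef(fit)[c(".celle1g0", ".celle0g1", ".celle1g1")])
  list(fit = fit, hr10 = unname(hr[1]), hr01 = unname(hr[2]),
       hr11 = unname(hr[3]))
}

#' Additive interaction on the hazard ratio scale (RERI / AP)
#'
#' Fits a Cox model with the four-level cross-classification of a binary
#' exposure and a binary high-risk flag (reference: both absent), computes
#' RERI and AP from the component hazard ratios, and attaches percentile
#' bootstrap confidence intervals from individual-level resampling. Zero
#' outside the RERI (or AP) interval indicates additive interaction.
#'
#' @param cohort Cohort data.frame.
#' @param exposure,risk Names of binary (logical/0-1) columns.
#' @param covariates Adjustment covariates.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level.
#' @inheritParams fit_cox
#' @return Object of class `interaction_result`: `reri`, `ap`, their
#'   percentile CIs, component hazard ratios (`hr10`, `hr01`, `hr11`),
#'   `n_boot_ok` (replicates that produced estimable cells), and the fit.
#' @export
estimate_additive_interaction <- function(cohort, exposure, risk,
                                          covariates = character(),
                                          n_boot = 1000, seed = 1,
                                          conf_level = 0.95,
                                          time = "time_years",
                                          event = "aaa_event") {
  assert_cols(cohort, c(exposure, risk, covariates, time, event))
  point <- interaction_components(cohort, exposure, risk, covariates,
                                  time, event)
  est <- reri_ap(point$hr10, point$hr01, point$hr11)

  boot <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("reri", "ap")))
  if (n_boot > 0) {
    set.seed(seed)
    n <- nrow(cohort)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      rep <- tryCatch(
        interaction_components(cohort[idx, , drop = FALSE], exposure, risk,
                               covariates, time, event),
        error = function(e) NULL)
      if (is.null(rep)) next
      r <- reri_ap(rep$hr10, rep$hr01, rep$hr11)
      boot[b, ] <- c(r$reri, r$ap)
    }
  }
  ok <- sum(!is.na(boot[, 1]))
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- function(col) {
    if (ok == 0) c(NA_real_, NA_real_) else panel_quantile(boot[, col], probs)
  }
  reri_ci <- ci("reri")
  ap_ci <- ci("ap")
  if (ok > 0 && (est$reri < reri_ci[1] || est$reri > reri_ci[2])) {
    warning("point RERI lies outside its bootstrap interval")
  }
  structure(list(
    reri = est$reri, ap = est$ap,
    reri_ci = reri_ci, ap_ci = ap_ci,
    hr10 = point$hr10, hr01 = point$hr01, hr11 = point$hr11,
    n_boot = n_boot, n_boot_ok = ok, fit = point$fit
  ), class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("RERI %.3f (%.3f, %.3f); AP %.3f (%.3f, %.3f)\n",
              x$reri, x$reri_ci[1], x$reri_ci[2],
              x$ap, x$ap_ci[1], x$ap_ci[2]))
  cat(sprintf("component HRs: HR10 %.3f, HR01 %.3f, HR11 %.3f; %d/%d boots\n",
              x$hr10, x$hr01, x$hr11, x$n_boot_ok, x$n_boot))
  invisible(x)
}

#' Multiplicative interaction (likelihood ratio test)
#'
#' Compares Cox models with and without the exposure-by-risk product term:
#' `2 * delta log-likelihood` against chi-square with degrees of freedom
#' equal to the number of product terms.
#'
#' @inheritParams estimate_additive_interaction
#' @return List with `p`, `lrt`, `df`, and both fits.
#' @export
test_multiplicative_interaction <- function(cohort, exposure, risk,
                                            covariates = character(),
                                            time = "time_years",
                                            event = "aaa_event") {
  assert_cols(cohort, c(exposure, risk, covariates, time, event))
  f0 <- coxph(cox_formula(c(exposure, risk, covariates), time, event),
              data = cohort, ties = "efron", model = TRUE)
  f1 <- coxph(cox_formula(c(paste0(exposure, " * ", risk), covariates),
                          time, event),
              data = cohort, ties = "efron", model = TRUE)
  df <- sum(!is.na(coef(f1))) - sum(!is.na(coef(f0)))
  lrt <- max(0, 2 * (f1$loglik[2] - f0$loglik[2]))
  p <- if (df == 0) 1 else pchisq(lrt, df = df, lower.tail = FALSE)
  list(p = p, lrt = lrt, df = df, fit_null = f0, fit_interaction = f1)
}
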