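#' Fit a Klemera-Doubal biological age model for one sex stratum
#'
#' For each biomarker, an ordinary least squares regression of the biomarker
#' on chronological age yields the intercept `q_i`, slope `k_i` and residual
#' root mean square error `s_i`. `s_BA^2` is the sample variance of the
#' fitted values from a multiple OLS of chronological age on all nine
#' biomarkers -- the variance in age explained by the biomarker set. Models
#' are fitted separately for men and women.
#'
#' @param training Cohort data.frame with `chronological_age`, `sex` and the
#'   KDM biomarker columns.
#' @param sex `"male"` or `"female"`: the stratum to fit.
#' @param biomarkers Biomarker columns (default [kdm_biomarkers()]).
#' @return An object of class `kdm_model`: list with `sex`, `biomarkers`,
#'   `q`, `k`, `s` (named vectors) and `s_ba` (years).
#' @export
fit_kdm_model <- function(training, sex,
                          biomarkers = kdm_biomarkers()) {
  sex <- match.arg(sex, c("male", "female"))
  assert_cols(training, c("chronological_age", "sex", biomarkers))
  dat <- training[training$sex == sex, , drop = FALSE]
  dat <- dat[complete.cases(dat[, c("chronological_age", biomarkers)]), ,
             drop = FALSE]
  stop_if_not(nrow(dat) >= 3,
              "need at least 3 complete participants of sex ", sex,
              class = "bioagerisk_size_error")
  ca <- dat$chronological_age
  stop_if_not(var(ca) > 0, "chronological age has zero variance",
              class = "bioagerisk_degenerate_design_error")

  q <- k <- s <- setNames(numeric(length(biomarkers)), biomarkers)
  for (b in biomarkers) {
    fit <- lm(dat[[b]] ~ ca)
    q[b] <- coef(fit)[1]
    k[b] <- coef(fit)[2]
    s[b] <- summary(fit)$sigma
    if (k[b] == 0) {
      warning("biomarker '", b, "' has exactly zero age slope (uninformative)")
    }
  }
  multi <- lm(ca ~ ., data = dat[, biomarkers, drop = FALSE])
  s_ba2 <- var(fitted(multi))
  stop_if_not(s_ba2 > 0, "biomarkers explain no variance in age",
              class = "bioagerisk_degenerate_design_error")
  structure(list(sex = sex, biomarkers = biomarkers,
                 q = q, k = k, s = s, s_ba = sqrt(s_ba2)),
            class = "kdm_model")
}

#' @export
print.kdm_model <- function(x, ...) {
  cat("Klemera-Doubal model (", x$sex, "), ", length(x$biomarkers),
      " biomarkers, s_BA = ", format(x$s_ba, digits = 4), " years\n",
      sep = "")
  print(data.frame(q = x$q, k = x$k, s = x$s))
  invisible(x)
}

#' Predict Klemera-Doubal biological age
#'
#' Evaluates the KDM estimator
#' \deqn{KDMAge = \frac{\sum_i (x_i - q_i) k_i / s_i^2 + CA / s_{BA}^2}
#'                     {\sum_i (k_i / s_i)^2 + 1 / s_{BA}^2}}
#' a precision-weighted average of the per-biomarker age predictions and
#' chronological age.
#'
#' @param model A fitted [fit_kdm_model()].
#' @param biomarkers Named numeric vector, or a data.frame/matrix with one
#'   row per participant, covering all model biomarkers. Missing values are
#'   an error: no silent imputation.
#' @param ca Chronological age(s), years.
#' @return Numeric vector of biological ages (years).
#' @export
predict_kdm_age <- function(model, biomarkers, ca) {
  stop_if_not(inherits(model, "kdm_model"), "model must be a kdm_model")
  if (is.null(dim(biomarkers))) {
    biomarkers <- matrix(biomarkers, nrow = 1,
                         dimnames = list(NULL, names(biomarkers)))
  }
  x <- as.matrix(as.data.frame(biomarkers)[, model$biomarkers, drop = FALSE])
  stop_if_not(all(is.finite(x)) && all(is.finite(ca)),
              "all biomarkers and chronological age must be finite ",
              "(no silent imputation)",
              class = "bioagerisk_incomplete_input_error")
  num <- sweep(x, 2, model$q) %*% (model$k / model$s^2) + ca / model$s_ba^2
  den <- sum((model$k / model$s)^2) + 1 / model$s_ba^2
  as.vector(num) / den
}

#' Fit KDM models for both sexes and score a cohort
#'
#' Convenience wrapper: fits [fit_kdm_model()] per sex on `training`
#' (default: the cohort itself, the cross-sectional calibration used at
#' baseline) and returns per-participant KDM ages.
#'
#' @param cohort Cohort data.frame.
#' @param training Training data (defaults to `cohort`).
#' @param biomarkers Biomarker columns.
#' @return List with `models` (named list `male`/`female`) and `kdm_age`
#'   (numeric vector aligned with `cohort` rows).
#' @export
kdm_age <- function(cohort, training = cohort,
                    biomarkers = kdm_biomarkers()) {
  models <- list(
    female = fit_kdm_model(training, "female", biomarkers),
    male = fit_kdm_model(training, "male", biomarkers)
  )
  out <- rep(NA_real_, nrow(cohort))
  for (s in names(models)) {
    idx <- which(cohort$sex == s)
    if (length(idx)) {
      out[idx] <- predict_kdm_age(models[[s]],
                                  cohort[idx, biomarkers, drop = FALSE],
                                  cohort$chronological_age[idx])
    }
  }
  list(models = models, kdm_age = out)
}

#' Fixed coefficients of the phenotypic age model
#'
#' The published constants of the phenotypic age closed form: the linear
#' predictor `xb` over nine blood-chemistry biomarkers plus chronological
#' age, and the Gompertz constants mapping `xb` to 10-year mortality risk
#' and then to an age-denominated score. Immutable defaults; override only
#' deliberately via the arguments.
#'
#' @param xb Named coefficient vector for the linear predictor (C-reactive
#'   protein enters as its natural log).
#' @param gompertz Named constants of the risk and age transforms.
#' @return Object of class `phenoage_coefficients`.
#' @export
phenoage_coefficients <- function(
    xb = c(intercept = -19.907, albumin = -0.0336, creatinine = 0.0095,
           glucose = 0.1953, log_crp = 0.0954, lymph_pct = -0.0120,
           mcv = 0.0268, rdw = 0.3306, alp = 0.00188, wbc = 0.0554,
           chronological_age = 0.0804),
    gompertz = c(age_intercept = 141.50, age_rate = 0.09165,
                 g_scale = 0.00553, risk_num = 1.51714,
                 risk_den = 0.0076927)) {
  structure(list(xb = xb, gompertz = gompertz),
            class = "phenoage_coefficients")
}

#' Compute phenotypic age
#'
#' Evaluates the phenotypic age closed form:
#' `mortality_risk = 1 - exp(-risk_num * exp(xb) / risk_den)` and
#' `phenoage = 141.50 + ln(-0.00553 * ln(1 - mortality_risk)) / 0.09165`,
#' with `xb` the published linear predictor (C-reactive protein, mg/dL,
#' entered as its natural log and floored at `crp_floor` first).
#'
#' @param biomarkers Named vector or data.frame with columns
#'   [phenoage_biomarkers()].
#' @param ca Chronological age(s), years.
#' @param coeffs A [phenoage_coefficients()].
#' @param crp_floor Floor applied to C-reactive protein before the log;
#'   set to `NULL` to disable (then `crp <= 0` is a domain error).
#' @return data.frame with columns `xb`, `mortality_risk`, `phenoage`.
#' @export
compute_phenoage <- function(biomarkers, ca,
                             coeffs = phenoage_coefficients(),
                             crp_floor = 0.01) {
  if (is.null(dim(biomarkers))) {
    biomarkers <- as.data.frame(as.list(biomarkers))
  }
  assert_cols(biomarkers, phenoage_biomarkers(), "biomarker input")
  b <- biomarkers
  crp <- b$crp
  if (!is.null(crp_floor)) crp <- pmax(crp, crp_floor)
  stop_if_not(all(crp > 0),
              "C-reactive protein must be positive before the log",
              class = "bioagerisk_domain_error")
  stop_if_not(all(is.finite(ca)) &&
                all(is.finite(as.matrix(b[, phenoage_biomarkers()]))),
              "all phenotypic age inputs must be finite",
              class = "bioagerisk_incomplete_input_error")
  cx <- coeffs$xb
  xb <- cx["intercept"] + cx["albumin"] * b$albumin +
    cx["creatinine"] * b$creatinine + cx["glucose"] * b$glucose +
    cx["log_crp"] * log(crp) + cx["lymph_pct"] * b$lymph_pct +
    cx["mcv"] * b$mcv + cx["rdw"] * b$rdw + cx["alp"] * b$alp +
    cx["wbc"] * b$wbc + cx["chronological_age"] * ca
  g <- coeffs$gompertz
  z <- g["risk_num"] * exp(xb) / g["risk_den"]   # -ln(1 - risk), exactly
  bad <- !is.finite(z) | z == 0
  if (any(bad)) {
    stop_if_not(FALSE, "mortality risk numerically 0 or 1 at xb = ",
                paste(signif(xb[bad][1], 6)),
                class = "bioagerisk_overflow_error")
  }
  risk <- -expm1(-z)
  # evaluate ln(-g_scale * ln(1 - risk)) as ln(g_scale * z): identical in
  # exact arithmetic, but stable when risk rounds to 1 in doubles
  phenoage <- g["age_intercept"] +
    (log(g["g_scale"]) + log(z)) / g["age_rate"]
  data.frame(xb = as.numeric(xb), mortality_risk = as.numeric(risk),
             phenoage = as.numeric(phenoage))
}

#' Biological age acceleration residuals
#'
#' Regresses biological age on chronological age over the supplied sample
#' (ordinary least squares, pooled across sexes by default) and returns the
#' residuals as age acceleration. Accelerated ageing is a strictly positive
#' residual; a residual of zero or less is non-accelerated.
#'
#' @param bioages Biological ages, years.
#' @param cas Chronological ages, years (same length).
#' @param by Optional stratification factor (e.g. sex) for the residual
#'   regression; default `NULL` fits one pooled regression.
#' @return data.frame with `bioage`, `acceleration` (years) and
#'   `accelerated` (logical).
#' @export
compute_acceleration <- function(bioages, cas, by = NULL) {
  stop_if_not(length(bioages) == length(cas),
              "bioages and cas must have equal length",
              class = "bioagerisk_shape_error")
  stop_if_not(length(cas) >= 3, "need at least 3 pairs",
              class = "bioagerisk_size_error")
  resid_of <- function(ba, ca) {
    stop_if_not(var(ca) > 0, "chronological age has zero variance",
                class = "bioagerisk_degenerate_design_error")
    residuals(lm(ba ~ ca))
  }
  if (is.null(by)) {
    accel <- resid_of(bioages, cas)
  } else {
    accel <- numeric(length(bioages))
    for (lev in unique(by)) {
      idx <- which(by == lev)
      accel[idx] <- resid_of(bioages[idx], cas[idx])
    }
  }
  # snap solver noise to zero so an exact on-the-line fit classifies as
  # non-accelerated (residual of zero or less)
  tol <- 1e-10 * max(1, sd(bioages))
  accel[abs(accel) < tol] <- 0
  data.frame(bioage = bioages, acceleration = as.numeric(accel),
             accelerated = as.numeric(accel) > 0)
}
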