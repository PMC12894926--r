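#' Biomarker panels used by the biological age measures
#'
#' `kdm_biomarkers()` returns the nine markers entering the Klemera-Doubal
#' biological age (forced expiratory volume in 1 s, systolic blood pressure
#' and seven blood-chemistry metrics); `phenoage_biomarkers()` the nine
#' blood-chemistry markers of phenotypic age; `all_biomarkers()` their
#' 14-marker union, which is the panel a cohort table must carry.
#'
#' Units follow the published phenotypic age model where the panels overlap:
#' albumin g/L, creatinine umol/L, glucose mmol/L, C-reactive protein mg/dL
#' (log-transformed inside the score), lymphocyte percent, mean cell volume
#' fL, red cell distribution width percent, alkaline phosphatase U/L, white
#' cell count 10^9/L; and for the KDM-only markers: FEV1 L, systolic blood
#' pressure mmHg, blood urea nitrogen mmol/L, glycated haemoglobin mmol/mol,
#' total cholesterol mmol/L.
#'
#' @return Character vector of column names.
#' @export
kdm_biomarkers <- function() {
  c("fev1", "sbp", "albumin", "alp", "bun", "creatinine",
    "crp", "hba1c", "totchol")
}

#' @rdname kdm_biomarkers
#' @export
phenoage_biomarkers <- function() {
  c("albumin", "creatinine", "glucose", "crp", "lymph_pct",
    "mcv", "rdw", "alp", "wbc")
}

#' @rdname kdm_biomarkers
#' @export
all_biomarkers <- function() {
  union(kdm_biomarkers(), phenoage_biomarkers())
}

#' Default generating parameters for the 14-biomarker panel
#'
#' One row per biomarker: intercept `q` (value at age 0), age slope `k`
#' (units/year), additive offset for males `sex_offset`, residual noise
#' standard deviation `s`, and `smoking_slope` (units per pack-year of
#' smoking). Values are plausibility choices for a middle-aged European
#' cohort in the units of [kdm_biomarkers()]; they define the synthetic
#' cohort's ground truth and are fully overridable via
#' [simulation_config()].
#'
#' @return A data.frame with columns `biomarker`, `q`, `k`, `sex_offset`,
#'   `s`, `smoking_slope`.
#' @export
default_biomarker_specs <- function() {
  specs <- data.frame(
    biomarker = c("fev1", "sbp", "albumin", "alp", "bun", "creatinine",
                  "crp", "hba1c", "totchol", "glucose", "lymph_pct",
                  "mcv", "rdw", "wbc"),
    q = c(4.68, 109.8, 48.3, 66.0, 3.72, 65.3,
          0.052, 27.1, 5.03, 4.16, 32.4, 88.8, 12.6, 6.52),
    k = c(-0.030, 0.45, -0.05, 0.25, 0.030, 0.12,
          0.003, 0.15, 0.012, 0.015, -0.06, 0.04, 0.015, 0.005),
    sex_offset = c(0.7, 5, 1.0, 3, 0.6, 12,
                   -0.02, 0.5, -0.3, 0.1, -1.0, 0.5, -0.1, -0.2),
    s = c(0.45, 15, 2.5, 20, 1.2, 12,
          0.05, 4.5, 1.0, 0.7, 7, 4, 0.9, 1.7),
    smoking_slope = c(-0.010, 0.05, -0.010, 0.15, 0.005, 0.02,
                      0.0015, 0.04, 0.004, 0.006, 0.02, 0.03, 0.008, 0.025),
    stringsAsFactors = FALSE
  )
  rownames(specs) <- specs$biomarker
  specs
}
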