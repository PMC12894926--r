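SCHEMA_VERSION <- "1.0"

#' Pipeline configuration
#'
#' Collects the switches, seeds and covariate lists of [run_pipeline()].
#' Paths are optional: the pipeline can equally be handed an in-memory
#' cohort.
#'
#' @param cohort_path,weights_path Optional TSV paths ([read_cohort()],
#'   [read_prs_weights()]).
#' @param output_dir Optional directory; when set, result tables are
#'   written there as TSV/JSON.
#' @param winsorization A [winsorization_spec()].
#' @param winsorize_by_sex Compute winsorization percentiles within sex.
#' @param accel_by_sex Stratify the acceleration residual regression by sex
#'   (default pooled).
#' @param covariates Adjustment covariates for the main Cox models.
#' @param genetic_covariates Extra covariates for genetic analyses
#'   (principal components, genotyping batch).
#' @param landmark_years Landmark sensitivity analysis; `NULL` disables.
#' @param complete_case Drop rows with any missing covariate instead of
#'   imputing.
#' @param fine_gray Also fit Fine-Gray competing-risk models.
#' @param run_interaction,run_mediation Stage switches.
#' @param n_boot Bootstrap replicates for the additive interaction.
#' @param n_sims Bootstrap replicates for mediation (0 = point estimates
#'   only).
#' @param seed Integer seed for all resampling.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL, weights_path = NULL,
                            output_dir = NULL,
                            winsorization = winsorization_spec(),
                            winsorize_by_sex = FALSE,
                            accel_by_sex = FALSE,
                            covariates = c("chronological_age", "sex",
                                           "bmi", "pack_years"),
                            genetic_covariates = c(paste0("pc", 1:10),
                                                   "batch"),
                            landmark_years = NULL,
                            complete_case = FALSE,
                            fine_gray = FALSE,
                            run_interaction = TRUE,
                            run_mediation = FALSE,
                            n_boot = 1000, n_sims = 0, seed = 1L) {
  stop_if_not(seed == as.integer(seed), "seed must be an integer",
              class = "bioagerisk_config_error")
  for (p in c(cohort_path, weights_path)) {
    stop_if_not(is.null(p) || file.exists(p),
                "configured path does not exist: ", p,
                class = "bioagerisk_config_error")
  }
  structure(list(
    cohort_path = cohort_path, weights_path = weights_path,
    output_dir = output_dir, winsorization = winsorization,
    winsorize_by_sex = winsorize_by_sex, accel_by_sex = accel_by_sex,
    covariates = covariates, genetic_covariates = genetic_covariates,
    landmark_years = landmark_years, complete_case = complete_case,
    fine_gray = fine_gray, run_interaction = run_interaction,
    run_mediation = run_mediation, n_boot = n_boot, n_sims = n_sims,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read / write a cohort table
#'
#' Tab-separated cohort files with strict type checking: `sex` must be
#' `female`/`male`, dosage columns (matching `^snp`) must lie in `[0, 2]`,
#' event flags in `{0, 1}`, follow-up non-negative. Factor levels
#' (including the `"unknown"` category created by imputation) round-trip.
#'
#' @param path File path.
#' @return `read_cohort`: the validated data.frame.
#' @export
read_cohort <- function(path) {
  dat <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(dat, c("participant_id", "chronological_age", "sex",
                     "time_years", "aaa_event"))
  bad_sex <- which(!dat$sex %in% c("female", "male"))
  stop_if_not(length(bad_sex) == 0,
              "malformed sex level in row(s): ",
              paste(head(bad_sex, 5), collapse = ", "),
              class = "bioagerisk_schema_error")
  dat$sex <- factor(dat$sex, levels = c("female", "male"))
  for (col in c("smoking_status", "batch")) {
    if (col %in% names(dat)) dat[[col]] <- factor(dat[[col]])
  }
  snps <- grep("^snp", names(dat), value = TRUE)
  for (s in snps) {
    stop_if_not(all(is.na(dat[[s]]) | (dat[[s]] >= 0 & dat[[s]] <= 2)),
                "dosage outside [0, 2] in column ", s,
                class = "bioagerisk_schema_error")
  }
  stop_if_not(all(dat$time_years >= 0), "negative follow-up time",
              class = "bioagerisk_schema_error")
  stop_if_not(all(dat$aaa_event %in% c(0, 1)),
              "aaa_event must be 0/1", class = "bioagerisk_schema_error")
  if ("death_event" %in% names(dat)) {
    stop_if_not(all(dat$death_event %in% c(0, 1)) &&
                  all(dat$aaa_event + dat$death_event <= 1),
                "death_event must be 0/1 and exclusive of aaa_event",
                class = "bioagerisk_schema_error")
  }
  dat
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  attr(out, "truth") <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result bundle
#'
#' Serializes model summaries as JSON (with a `schema_version` field) and,
#' for tabular members, TSV companions.
#'
#' @param results Named list (e.g. a [run_pipeline()] bundle member).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  payload <- c(list(schema_version = SCHEMA_VERSION),
               strip_fits(results))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

strip_fits <- function(x) {
  if (inherits(x, c("coxph", "lm"))) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    x <- x[!vapply(x, inherits, TRUE,
                   what = c("coxph", "lm", "cox_fit", "formula", "terms"))]
    return(lapply(x, strip_fits))
  }
  x
}

stage_log <- function(log, stage, n, events) {
  rbind(log, data.frame(stage = stage, n = n, events = events,
                        stringsAsFactors = FALSE))
}

clock_analyses <- function(cohort, accel_col, flag_col, covariates,
                           fine_gray, landmark_years) {
  out <- list(
    binary = fit_cox(cohort, flag_col, covariates, "binary"),
    per_sd = fit_cox(cohort, accel_col, covariates, "per_sd"),
    quartile = fit_cox(cohort, accel_col, covariates, "quartile"),
    trend = quartile_trend_test(cohort, accel_col, covariates),
    rcs = rcs_dose_response(cohort, accel_col, covariates)
  )
  if (fine_gray) {
    out$fine_gray <- fit_fine_gray(cohort, flag_col, covariates, "binary")
  }
  if (!is.null(landmark_years)) {
    lm_cohort <- landmark_filter(cohort, landmark_years)
    out$landmark <- fit_cox(lm_cohort, flag_col, covariates, "binary")
  }
  out
}

#' Run the full biological-ageing / genetic-risk analysis pipeline
#'
#' Orchestrates the stages in their methodological order: exclusions,
#' biomarker winsorization, covariate imputation (or complete-case
#' filtering), KDM and phenotypic age scoring, acceleration residuals and
#' accelerated-ageing flags, weighted PRS and tertile risk groups, adjusted
#' Cox models (binary flag, per-SD continuous, quartiles, trend, restricted
#' cubic spline), joint classification with additive and multiplicative
#' interaction, optional smoking mediation, and the sensitivity toggles
#' (landmark, Fine-Gray). Deterministic given the config seed.
#'
#' @param cohort Cohort data.frame (e.g. from [simulate_cohort()] or
#'   [read_cohort()]); if `NULL`, read from `config$cohort_path`.
#' @param config A [pipeline_config()].
#' @param weights PRS weight table; if `NULL`, read from
#'   `config$weights_path` when set, else [synthetic_prs_weights()].
#' @return A result bundle (list): `log` (per-stage row/event counts),
#'   `scores` (per-participant id, kdm_age, phenoage, accelerations,
#'   flags, prs, genetic risk group), `kdm_models`, `exclusions`, `kdm` and
#'   `phenoage` model sets, `prs` models, `interaction`, `mediation`, and
#'   `config`. When `config$output_dir` is set, score and result tables are
#'   also written there.
#' @export
run_pipeline <- function(cohort = NULL, config = pipeline_config(),
                         weights = NULL) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config",
              class = "bioagerisk_config_error")
  if (is.null(cohort)) {
    stop_if_not(!is.null(config$cohort_path),
                "no cohort given and no cohort_path configured",
                class = "bioagerisk_config_error")
    cohort <- read_cohort(config$cohort_path)
  }
  if (is.null(weights)) {
    weights <- if (!is.null(config$weights_path)) {
      read_prs_weights(config$weights_path)
    } else {
      synthetic_prs_weights(length(grep("^snp", names(cohort))))
    }
  }
  log <- stage_log(NULL, "input", nrow(cohort), sum(cohort$aaa_event))

  excl <- apply_exclusions(cohort, rules = c("missing_biomarker",
                                             "missing_genetics"))
  cohort <- excl$cohort
  log <- stage_log(log, "exclusions", nrow(cohort), sum(cohort$aaa_event))

  wins <- winsorize_cohort(cohort, spec = config$winsorization,
                           by_sex = config$winsorize_by_sex)
  cohort <- wins$cohort

  if (config$complete_case) {
    cohort <- cohort[complete.cases(cohort[, config$covariates,
                                           drop = FALSE]), , drop = FALSE]
  } else {
    cohort <- impute_covariates(cohort, config$covariates)
  }
  log <- stage_log(log, "covariates", nrow(cohort), sum(cohort$aaa_event))

  kdm <- kdm_age(cohort)
  ph <- compute_phenoage(cohort, cohort$chronological_age)
  by <- if (config$accel_by_sex) cohort$sex else NULL
  acc_k <- compute_acceleration(kdm$kdm_age, cohort$chronological_age, by)
  acc_p <- compute_acceleration(ph$phenoage, cohort$chronological_age, by)
  cohort$kdm_age <- kdm$kdm_age
  cohort$phenoage <- ph$phenoage
  cohort$kdm_accel <- acc_k$acceleration
  cohort$kdm_accelerated <- acc_k$accelerated
  cohort$phenoage_accel <- acc_p$acceleration
  cohort$phenoage_accelerated <- acc_p$accelerated
  log <- stage_log(log, "bioage", nrow(cohort), sum(cohort$aaa_event))

  dosage_cols <- grep("^snp", names(cohort), value = TRUE)
  genetic <- length(dosage_cols) == nrow(weights) && nrow(weights) > 0
  if (genetic) {
    dos <- impute_missing_dosage(cohort[, dosage_cols, drop = FALSE])
    cohort$prs <- compute_weighted_prs(weights, dos)
    cohort$genetic_risk <- assign_genetic_risk_groups(cohort$prs)
    cohort$high_genetic_risk <- cohort$genetic_risk == "high"
  }

  results <- list(log = NULL, config = config)
  results$exclusions <- excl$report
  results$kdm_models <- kdm$models
  results$winsor_cuts <- wins$cuts

  results$kdm <- clock_analyses(cohort, "kdm_accel", "kdm_accelerated",
                                config$covariates, config$fine_gray,
                                config$landmark_years)
  results$phenoage <- clock_analyses(cohort, "phenoage_accel",
                                     "phenoage_accelerated",
                                     config$covariates, config$fine_gray,
                                     config$landmark_years)

  if (genetic) {
    gcov <- c(config$covariates,
              intersect(config$genetic_covariates, names(cohort)))
    results$prs <- list(
      per_sd = fit_cox(cohort, "prs", gcov, "per_sd"),
      tertile = fit_cox(cohort, "genetic_risk", gcov, "continuous")
    )
    if (config$run_interaction) {
      results$interaction <- list()
      for (clock in c("kdm", "phenoage")) {
        flag <- paste0(clock, "_accelerated")
        joint <- cohort
        joint$joint_group <- build_joint_groups(joint[[flag]],
                                                joint$genetic_risk)
        results$interaction[[clock]] <- list(
          joint = fit_cox(joint, "joint_group", gcov, "continuous"),
          additive = estimate_additive_interaction(
            cohort, flag, "high_genetic_risk", gcov,
            n_boot = config$n_boot, seed = config$seed),
          multiplicative = test_multiplicative_interaction(
            cohort, flag, "high_genetic_risk", gcov)
        )
      }
    }
  }

  if (config$run_mediation) {
    med_cov <- setdiff(config$covariates, "pack_years")
    results$mediation <- list(
      kdm = run_mediation(cohort, "pack_years", "kdm_accel", med_cov,
                          n_sims = config$n_sims, seed = config$seed),
      phenoage = run_mediation(cohort, "pack_years", "phenoage_accel",
                               med_cov, n_sims = config$n_sims,
                               seed = config$seed)
    )
  }

  results$log <- log
  score_cols <- c("participant_id", "kdm_age", "phenoage", "kdm_accel",
                  "phenoage_accel", "kdm_accelerated",
                  "phenoage_accelerated",
                  intersect(c("prs", "genetic_risk"), names(cohort)))
  results$scores <- cohort[, score_cols]

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(results$scores,
                file.path(config$output_dir, "scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(results$log, file.path(config$output_dir, "stages.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (clock in c("kdm", "phenoage")) {
      tab <- do.call(rbind, lapply(
        names(results[[clock]]), function(nm) {
          obj <- results[[clock]][[nm]]
          if (inherits(obj, "cox_fit")) cbind(model = nm, obj$terms)
          else NULL
        }))
      write.table(tab, file.path(config$output_dir,
                                 paste0(clock, "_models.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_results(list(exclusions = results$exclusions,
                       log = results$log),
                  file.path(config$output_dir, "pipeline.json"))
  }
  results
}
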