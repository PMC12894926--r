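#' Synthetic variant weight table for the polygenic risk score
#'
#' A fixed 31-variant table (identifiers, effect alleles, per-allele log
#' odds ratios) with the shape of a published GWAS-derived weight file. The
#' values are synthetic stand-ins spanning a plausible effect-size range for
#' common risk variants of a complex vascular disease; the same table is
#' shipped as plain text at
#' `system.file("extdata", "prs_weights_synthetic.tsv", package =
#' "bioagerisk")`.
#'
#' @param n_snps Number of variants (default 31).
#' @return data.frame with columns `snp_id`, `effect_allele`, `beta`.
#' @export
synthetic_prs_weights <- function(n_snps = 31L) {
  data.frame(
    snp_id = sprintf("snp%02d", seq_len(n_snps)),
    effect_allele = rep(c("A", "C", "G", "T"), length.out = n_snps),
    beta = round(seq(0.04, 0.28, length.out = n_snps), 3),
    stringsAsFactors = FALSE
  )
}

#' Read / write a PRS weight table
#'
#' Tab-separated with columns `snp_id`, `effect_allele`, `beta` (per-allele
#' log odds ratio).
#'
#' @param path File path.
#' @return `read_prs_weights`: the validated weights data.frame.
#' @export
read_prs_weights <- function(path) {
  w <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(w, c("snp_id", "effect_allele", "beta"), "weights table")
  stop_if_not(all(is.finite(w$beta)), "betas must be finite numbers",
              class = "bioagerisk_schema_error")
  w
}

#' @rdname read_prs_weights
#' @param weights Weights data.frame.
#' @export
write_prs_weights <- function(weights, path) {
  write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Weighted polygenic risk score
#'
#' `score_j = sum_i beta_i * dosage_ij * N / sum_i beta_i`, the weighted
#' allele-count score normalized so that its scale is comparable to a simple
#' risk-allele count (`N` = number of variants). Higher scores indicate
#' higher modelled genetic predisposition.
#'
#' @param weights Weights data.frame (see [read_prs_weights()]).
#' @param dosages Matrix or data.frame of per-SNP dosages in `[0, 2]`,
#'   participants in rows; columns matched to `weights$snp_id` by name when
#'   named, else positionally.
#' @return Numeric score vector.
#' @export
compute_weighted_prs <- function(weights, dosages) {
  d <- as.matrix(dosages)
  if (!is.null(colnames(d))) {
    assert_cols(as.data.frame(d), weights$snp_id, "dosage matrix")
    d <- d[, weights$snp_id, drop = FALSE]
  }
  stop_if_not(ncol(d) == nrow(weights),
              "dosage columns must match the weight table",
              class = "bioagerisk_shape_error")
  stop_if_not(all(is.na(d) | (d >= 0 & d <= 2)),
              "dosages must lie in [0, 2]",
              class = "bioagerisk_domain_error")
  sum_beta <- sum(weights$beta)
  stop_if_not(sum_beta != 0, "sum of betas is zero; score undefined",
              class = "bioagerisk_normalization_error")
  as.vector(d %*% weights$beta) * nrow(weights) / sum_beta
}

#' Tertile-based genetic risk groups
#'
#' Cut points at the 1/3 and 2/3 sample quantiles (linear-interpolation
#' convention); scores at or below a cut point go to the lower group, so the
#' assignment is deterministic under ties.
#'
#' @param scores Numeric PRS vector with at least 3 distinct values (fewer
#'   triggers a degeneracy warning and a single group).
#' @return Factor with levels `low`, `intermediate`, `high` and attribute
#'   `cuts` (the two cut points).
#' @export
assign_genetic_risk_groups <- function(scores) {
  cuts <- panel_quantile(scores, c(1 / 3, 2 / 3))
  if (length(unique(scores[is.finite(scores)])) < 3 ||
      cuts[1] == cuts[2]) {
    labels <- factor(rep("low", length(scores)),
                     levels = c("low", "intermediate", "high"))
    sizes <- table(labels)
    warning("tertile cut points are degenerate (ties); realized group ",
            "sizes: ", paste(names(sizes), sizes, sep = "=", collapse = ", "))
    attr(labels, "cuts") <- cuts
    return(labels)
  }
  labels <- cut(scores, breaks = c(-Inf, cuts, Inf),
                labels = c("low", "intermediate", "high"), right = TRUE)
  sizes <- table(labels)
  if (max(sizes) - min(sizes) > max(1, 0.1 * length(scores))) {
    warning("heavy ties span a tertile cut point; realized group sizes: ",
            paste(names(sizes), sizes, sep = "=", collapse = ", "))
  }
  attr(labels, "cuts") <- cuts
  labels
}

#' Impute missing genotype dosages
#'
#' Missing entries for a variant are replaced by the cohort mean dosage
#' among observed carriers, i.e. twice the observed effect-allele frequency.
#'
#' @param dosages Matrix/data.frame of dosages (participants x SNPs).
#' @return Completed matrix.
#' @export
impute_missing_dosage <- function(dosages) {
  d <- as.matrix(dosages)
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (!any(miss)) next
    stop_if_not(!all(miss),
                "all dosages missing for SNP '",
                colnames(d)[j] %||% j, "'; allele frequency undefined",
                class = "bioagerisk_empty_input_error")
    d[miss, j] <- mean(d[!miss, j])
  }
  d
}
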