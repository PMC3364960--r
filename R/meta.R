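# Meta-analysis: inverse-variance fixed effects, DerSimonian-Laird random
# effects, SE recovery from printed confidence intervals, the SNP-presence
# rule, significance tiers, and the lean-vs-obese heterogeneity z-test.

#' Recover a log-OR and its SE from a printed OR and 95% CI
#'
#' `beta = ln(OR)`, `se = (ln(hi) - ln(lo)) / (2 * 1.959964)`. Printed
#' tables are rounded, so the point estimate may fall slightly outside the
#' printed interval; a 2% relative tolerance is allowed before the input is
#' rejected.
#'
#' @param or_point odds ratio point estimate (> 0).
#' @param ci_low,ci_high 95% confidence bounds (0 < low < high).
#' @param tol relative tolerance for the point estimate lying inside the CI.
#' @return A list with `beta` and `se`.
#' @examples
#' se_from_ci(1.22, 1.12, 1.30)
#' @export
se_from_ci <- function(or_point, ci_low, ci_high, tol = 0.02) {
  if (!(ci_low > 0 && ci_high > ci_low)) {
    stop_bmistrat("require 0 < ci_low < ci_high",
                  "bmistrat_validation_error")
  }
  if (or_point < ci_low * (1 - tol) || or_point > ci_high * (1 + tol)) {
    stop_bmistrat("or_point lies outside [ci_low, ci_high] beyond tolerance",
                  "bmistrat_validation_error")
  }
  list(beta = log(or_point), se = (log(ci_high) - log(ci_low)) / (2 * Z975))
}

validate_estimates <- function(estimates, min_k = 1L) {
  if (!is.data.frame(estimates) || nrow(estimates) < min_k) {
    stop_bmistrat(sprintf("need at least %d study estimate(s)", min_k),
                  "bmistrat_validation_error")
  }
  if (!all(c("beta", "se") %in% names(estimates))) {
    stop_bmistrat("estimates need columns beta and se",
                  "bmistrat_validation_error")
  }
  if (any(!is.finite(estimates$beta)) || any(estimates$se <= 0)) {
    stop_bmistrat("beta must be finite and se > 0",
                  "bmistrat_validation_error")
  }
  estimates
}

directions_string <- function(beta) {
  paste(ifelse(is.na(beta), "?", ifelse(beta > 0, "+",
               ifelse(beta < 0, "-", "?"))), collapse = "")
}

meta_record <- function(variant_id, beta, se, k, Q, tau2, dirs, model) {
  z <- beta / se
  data.frame(
    variant_id = variant_id, beta_fe = beta, se_fe = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), k = k, Q = Q, tau2 = tau2,
    directions = dirs, model = model, stringsAsFactors = FALSE
  )
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools study estimates with weights `w_i = 1/se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`, with Cochran's
#' `Q = sum(w (b - beta)^2)` as the heterogeneity statistic and a
#' directions string summarising per-study effect signs.
#'
#' @param estimates data frame with columns `beta` and `se` (> 0), one row
#'   per study; optional `variant_id` (must be unique to one variant).
#' @return A one-row `meta_record` data frame with columns `variant_id`,
#'   `beta_fe`, `se_fe`, `z`, `p`, `k`, `Q`, `tau2` (0 for fixed effects),
#'   `directions` and `model`.
#' @export
fixed_effect_meta <- function(estimates) {
  validate_estimates(estimates, 1L)
  w <- 1 / estimates$se^2
  beta <- sum(w * estimates$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (estimates$beta - beta)^2)
  id <- unique(estimates$variant_id %||% NA_character_)
  stopifnot(length(id) == 1L)
  meta_record(id, beta, se, k = nrow(estimates), Q = Q, tau2 = 0,
              dirs = directions_string(estimates$beta), model = "fixed")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Estimates the between-study variance by the method of moments,
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with the
#' fixed-effect weights `w = 1/se^2`, then re-pools with weights
#' `1/(se^2 + tau2)`. When the estimates are homogeneous (`Q <= k - 1`)
#' the truncation gives `tau2 = 0` and the result equals the fixed-effect
#' pool.
#'
#' @inheritParams fixed_effect_meta
#' @return A one-row `meta_record` data frame with `model = "random"`.
#' @export
random_effects_meta <- function(estimates) {
  validate_estimates(estimates, 2L)
  fe <- fixed_effect_meta(estimates)
  w <- 1 / estimates$se^2
  k <- nrow(estimates)
  tau2 <- max(0, (fe$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (estimates$se^2 + tau2)
  beta <- sum(wr * estimates$beta) / sum(wr)
  se <- 1 / sqrt(sum(wr))
  meta_record(fe$variant_id, beta, se, k = k, Q = fe$Q, tau2 = tau2,
              dirs = fe$directions, model = "random")
}

#' Harmonize study summary statistics to a reference allele orientation
#'
#' Aligns each study's records to the reference panel's effect/other
#' alleles: records whose effect allele is the reference other allele have
#' their `beta` (and `z`) sign flipped and `eaf` replaced by `1 - eaf`;
#' records whose allele pair does not match the reference at all are
#' dropped, with the dropped IDs in the `"dropped"` attribute.
#'
#' @param records summary-statistics data frame.
#' @param reference data frame with `variant_id`, `effect_allele`,
#'   `other_allele` giving the target orientation.
#' @return Harmonized records (attribute `"dropped"` lists removed IDs).
#' @export
harmonize_alleles <- function(records, reference) {
  m <- match(records$variant_id, reference$variant_id)
  ref_ea <- reference$effect_allele[m]
  ref_oa <- reference$other_allele[m]
  same <- !is.na(m) & records$effect_allele == ref_ea &
    records$other_allele == ref_oa
  flip <- !is.na(m) & records$effect_allele == ref_oa &
    records$other_allele == ref_ea
  drop <- !(same | flip)
  if (any(flip)) {
    records$beta[flip] <- -records$beta[flip]
    records$z[flip] <- -records$z[flip]
    records$eaf[flip] <- 1 - records$eaf[flip]
    tmp <- records$effect_allele[flip]
    records$effect_allele[flip] <- records$other_allele[flip]
    records$other_allele[flip] <- tmp
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- records$variant_id[drop]
  out
}

#' SNP-presence rule for meta-analysis inclusion
#'
#' A variant is retained if it is present in at least half of the `k_total`
#' contributing studies; "present in less than half" means exclusion. The
#' comparison `2 * count >= k_total` is exact in integers, so odd `k_total`
#' cannot produce floating-point ties.
#'
#' @param per_study_tables list of per-study summary-statistic data frames
#'   (each with a `variant_id` column).
#' @param k_total total number of studies in the meta-analysis.
#' @return Character vector of retained variant IDs.
#' @export
filter_snp_presence <- function(per_study_tables, k_total) {
  stopifnot(k_total >= 1)
  ids <- unlist(lapply(per_study_tables, function(t) unique(t$variant_id)))
  counts <- table(ids)
  names(counts)[2L * as.integer(counts) >= k_total]
}

#' Assign significance tiers to meta-analysis records
#'
#' Genome-wide: `p < genome_wide` (strict); suggestive:
#' `genome_wide <= p < suggestive` (strict). The default genome-wide
#' threshold 2.5e-8 halves the conventional 5e-8 to account for running
#' two stratified scans.
#'
#' @param meta_records data frame with a `p` column.
#' @param genome_wide,suggestive p-value thresholds.
#' @return The records with an added `tier` column
#'   (`"genome-wide"`, `"suggestive"`, or `"none"`).
#' @export
declare_significance <- function(meta_records, genome_wide = 2.5e-8,
                                 suggestive = 5e-7) {
  p <- meta_records$p
  meta_records$tier <- ifelse(p < genome_wide, "genome-wide",
                              ifelse(p < suggestive, "suggestive", "none"))
  meta_records
}

#' Lean-versus-obese stratum heterogeneity z-test
#'
#' Tests equality of two stratum log-ORs with
#' `z = (beta_lean - beta_obese) / sqrt(se_lean^2 + se_obese^2)` and a
#' two-sided normal p-value. Note that when the two strata share a control
#' pool the estimates are positively correlated and this test is
#' anti-conservative; prefer the case-only scan
#' ([case_only_bmi_scan()]) or a case-vs-case model
#' ([score_case_vs_case()]) for inference in that design.
#'
#' @param beta_lean,se_lean lean-stratum log-OR and SE.
#' @param beta_obese,se_obese obese-stratum log-OR and SE.
#' @return An object of class `het_test`: list with `beta_diff`,
#'   `se_diff`, `z_het`, `p_het`.
#' @export
stratum_heterogeneity_test <- function(beta_lean, se_lean,
                                       beta_obese, se_obese) {
  if (!(se_lean > 0 && se_obese > 0)) {
    stop_bmistrat("standard errors must be positive",
                  "bmistrat_validation_error")
  }
  beta_diff <- beta_lean - beta_obese
  se_diff <- sqrt(se_lean^2 + se_obese^2)
  z <- beta_diff / se_diff
  structure(
    list(beta_diff = beta_diff, se_diff = se_diff, z_het = z,
         p_het = 2 * stats::pnorm(-abs(z))),
    class = "het_test"
  )
}

#' @export
print.het_test <- function(x, ...) {
  cat(sprintf("<het_test> beta_diff = %.4f (se %.4f), z = %.3f, p = %.4g\n",
              x$beta_diff, x$se_diff, x$z_het, x$p_het))
  invisible(x)
}

#' Per-variant meta-analysis across studies
#'
#' Convenience wrapper: harmonizes each study table to the reference
#' orientation, applies the presence rule, and pools each retained variant
#' with [fixed_effect_meta()] or [random_effects_meta()].
#'
#' @param per_study_tables list of per-study summary-statistic data frames.
#' @param reference allele-orientation reference (panel or first study).
#' @param model `"fixed"` or `"random"`.
#' @param k_total total study count for the presence rule (defaults to
#'   `length(per_study_tables)`).
#' @return Data frame of meta records, one row per retained variant.
#' @export
meta_analyse_studies <- function(per_study_tables, reference = NULL,
                                 model = c("fixed", "random"),
                                 k_total = length(per_study_tables)) {
  model <- match.arg(model)
  if (!is.null(reference)) {
    per_study_tables <- lapply(per_study_tables, harmonize_alleles,
                               reference = reference)
  }
  keep <- filter_snp_presence(per_study_tables, k_total)
  pool_one <- function(id) {
    rows <- do.call(rbind, lapply(per_study_tables, function(t) {
      t[t$variant_id == id, c("variant_id", "beta", "se"), drop = FALSE]
    }))
    rows <- rows[stats::complete.cases(rows), , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    if (model == "random" && nrow(rows) >= 2L) {
      random_effects_meta(rows)
    } else {
      fixed_effect_meta(rows)
    }
  }
  out <- do.call(rbind, Filter(Negate(is.null), lapply(keep, pool_one)))
  if (is.null(out)) {
    out <- meta_record(character(0), numeric(0), numeric(0), integer(0),
                       numeric(0), numeric(0), character(0), character(0))
  }
  rownames(out) <- NULL
  out
}
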