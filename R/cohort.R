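# Synthetic cohort generator.
#
# Generative model (per individual i, variant j):
#   g_ij ~ Binomial(2, f_j)                        (HWE genotypes)
#   b_i  = mu + sum_j a_j g_ij + Normal(0, sigma^2) (BMI, kg/m^2)
#   z_i  = (b_i - mu) / sigma                       (standardised BMI)
#   logit P(D_i = 1) = alpha + sum_j (beta_j + delta_j z_i) g_ij + gamma z_i
#
# delta_j < 0 makes the per-allele log-odds larger at low BMI, which is the
# mechanism by which lean cases become enriched for risk alleles; a_j models
# loci whose primary effect is on BMI itself (FTO/MC4R-like). The intercept
# alpha is calibrated by bisection so the simulated prevalence matches a
# target.

PANEL_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta_base", "delta",
                   "bmi_effect", "info")

#' Validate a variant panel
#'
#' A variant panel is a data frame with one row per simulated locus and
#' columns `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf` (effect allele frequency, in (0,1)), `beta_base` (log-odds per
#' effect allele at mean BMI), `delta` (change in the per-allele log-odds per
#' 1 SD of centred BMI; negative values give larger effects in lean
#' individuals), `bmi_effect` (kg/m^2 per effect allele) and `info`
#' (imputation quality in \[0,1\]).
#'
#' @param panel data frame to validate.
#' @return The panel, invisibly, after validation.
#' @export
validate_panel <- function(panel) {
  if (!is.data.frame(panel)) {
    stop_bmistrat("panel must be a data frame", "bmistrat_validation_error")
  }
  missing <- setdiff(PANEL_COLUMNS, names(panel))
  if (length(missing)) {
    stop_bmistrat(paste0("panel is missing columns: ",
                         paste(missing, collapse = ", ")),
                  "bmistrat_validation_error")
  }
  if (nrow(panel)) {
    num <- c("eaf", "beta_base", "delta", "bmi_effect", "info")
    if (!all(vapply(panel[num], function(x) all(is.finite(x)), logical(1)))) {
      stop_bmistrat("panel numeric fields must be finite",
                    "bmistrat_validation_error")
    }
    if (any(panel$eaf <= 0 | panel$eaf >= 1)) {
      stop_bmistrat("eaf must lie strictly in (0, 1)",
                    "bmistrat_validation_error")
    }
    if (any(panel$effect_allele == panel$other_allele)) {
      stop_bmistrat("effect_allele and other_allele must differ",
                    "bmistrat_validation_error")
    }
    if (any(panel$info < 0 | panel$info > 1)) {
      stop_bmistrat("info scores must lie in [0, 1]",
                    "bmistrat_validation_error")
    }
    if (anyDuplicated(panel$variant_id)) {
      stop_bmistrat("variant_id values must be unique",
                    "bmistrat_validation_error")
    }
  }
  invisible(panel)
}

#' Simulate a panel of independent variants
#'
#' Draws `n_snps` loci with effect allele frequencies uniform on
#' `[eaf_low, eaf_high]` and all effects zero. Rows of `effect_specs`
#' override the drawn values for selected loci, which is how risk loci with
#' non-zero `beta_base`, BMI effect modification (`delta`) or primary BMI
#' effects are introduced.
#'
#' @param n_snps number of loci (may be 0).
#' @param eaf_low,eaf_high bounds of the uniform EAF draw, 0 < low < high < 1.
#' @param effect_specs optional data frame with a column `index` (1-based row
#'   in the panel) and any of `eaf`, `beta_base`, `delta`, `bmi_effect`,
#'   `info`; non-`NA` entries replace the defaults.
#' @param seed integer seed; identical seeds give identical panels.
#' @return A variant panel data frame (see [validate_panel()]).
#' @examples
#' simulate_variants(3, seed = 1)
#' @export
simulate_variants <- function(n_snps, eaf_low = 0.05, eaf_high = 0.95,
                              effect_specs = NULL, seed = 1) {
  if (!(eaf_low > 0 && eaf_low < eaf_high && eaf_high < 1)) {
    stop_bmistrat("require 0 < eaf_low < eaf_high < 1",
                  "bmistrat_validation_error")
  }
  stopifnot(n_snps >= 0)
  n_snps <- as.integer(n_snps)
  eaf <- with_substream(seed, "variants", stats::runif(n_snps, eaf_low, eaf_high))
  panel <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(n_snps)),
    chrom = rep("1", n_snps),
    pos = 10000L * seq_len(n_snps),
    effect_allele = rep("A", n_snps),
    other_allele = rep("G", n_snps),
    eaf = eaf,
    beta_base = numeric(n_snps),
    delta = numeric(n_snps),
    bmi_effect = numeric(n_snps),
    info = rep(1, n_snps),
    stringsAsFactors = FALSE
  )
  if (!is.null(effect_specs) && nrow(effect_specs)) {
    if (is.null(effect_specs$index) ||
        any(effect_specs$index < 1 | effect_specs$index > n_snps)) {
      stop_bmistrat("effect_specs$index must index panel rows",
                    "bmistrat_validation_error")
    }
    for (col in intersect(names(effect_specs),
                          c("eaf", "beta_base", "delta", "bmi_effect", "info"))) {
      ok <- !is.na(effect_specs[[col]])
      panel[[col]][effect_specs$index[ok]] <- effect_specs[[col]][ok]
    }
  }
  validate_panel(panel)
  panel
}

#' Cohort configuration
#'
#' Nuisance parameters of the disease and BMI model. `target_prevalence` is
#' matched by calibrating the logistic intercept; `bmi_gamma` is the
#' log-odds of disease per 1 SD of BMI (obesity as a risk factor). Defaults
#' `bmi_mean = 27`, `bmi_sd = 4.5` keep both the lean (< 25) and obese
#' (>= 30) tails well populated.
#'
#' @param n_individuals cohort size (>= 1).
#' @param target_prevalence disease prevalence to calibrate to, in (0, 0.5).
#' @param bmi_mean,bmi_sd BMI population mean and SD, kg/m^2 (`bmi_sd` > 0).
#' @param bmi_gamma log-odds of disease per 1 SD of centred BMI.
#' @param seed master seed; all simulation substreams derive from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals, target_prevalence = 0.10,
                          bmi_mean = 27, bmi_sd = 4.5, bmi_gamma = 0.3,
                          seed = 1) {
  if (!(target_prevalence > 0 && target_prevalence < 0.5)) {
    stop_bmistrat("target_prevalence must lie in (0, 0.5)",
                  "bmistrat_validation_error")
  }
  if (!(bmi_sd > 0)) {
    stop_bmistrat("bmi_sd must be positive", "bmistrat_validation_error")
  }
  if (n_individuals < 1) {
    stop_bmistrat("n_individuals must be >= 1", "bmistrat_validation_error")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         target_prevalence = target_prevalence,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_gamma = bmi_gamma,
         seed = seed),
    class = "cohort_config"
  )
}

# Draw genotypes (true dosages) for `n` individuals under HWE.
draw_genotypes <- function(panel, n) {
  J <- nrow(panel)
  g <- matrix(stats::rbinom(n * J, size = 2L,
                            prob = rep(panel$eaf, each = n)),
              nrow = n, ncol = J)
  colnames(g) <- panel$variant_id
  g
}

# Linear predictor without the intercept, given true genotypes and
# standardised BMI z.
disease_eta <- function(panel, g, z, gamma) {
  eta <- as.numeric(g %*% panel$beta_base) +
    z * as.numeric(g %*% panel$delta) + gamma * z
  eta
}

#' Calibrate the disease-model intercept to a target prevalence
#'
#' Finds, by bisection, the logistic intercept alpha at which the expected
#' disease prevalence under the cohort's generative model equals
#' `target_prevalence`. The expectation is taken over `n_mc` Monte-Carlo
#' draws of genotypes and BMI from a fixed substream of the config seed, so
#' the returned alpha is deterministic for a given config.
#'
#' @param panel variant panel (see [simulate_variants()]).
#' @param config a [cohort_config()].
#' @param n_mc number of Monte-Carlo individuals used for the expectation.
#' @param max_iter maximum bisection steps.
#' @param tol convergence tolerance on prevalence (absolute; 0.002 = 0.2
#'   percentage points).
#' @return The intercept alpha (log-odds scale).
#' @export
calibrate_intercept <- function(panel, config, n_mc = 200000L,
                                max_iter = 60L, tol = 0.002) {
  validate_panel(panel)
  # only variants with a non-zero disease or BMI effect move the linear
  # predictor; restricting the Monte-Carlo draw to them keeps calibration
  # cheap for large null panels
  active <- panel[panel$beta_base != 0 | panel$delta != 0 |
                    panel$bmi_effect != 0, , drop = FALSE]
  eta <- with_substream(config$seed, "calibrate", {
    g <- draw_genotypes(active, n_mc)
    bmi <- config$bmi_mean + as.numeric(g %*% active$bmi_effect) +
      stats::rnorm(n_mc, 0, config$bmi_sd)
    z <- (bmi - config$bmi_mean) / config$bmi_sd
    disease_eta(active, g, z, config$bmi_gamma)
  })
  target <- config$target_prevalence
  lo <- -40; hi <- 40
  alpha <- 0; prev <- mean(stats::plogis(alpha + eta))
  for (i in seq_len(max_iter)) {
    alpha <- (lo + hi) / 2
    prev <- mean(stats::plogis(alpha + eta))
    if (prev > target) hi <- alpha else lo <- alpha
    if (abs(prev - target) <= tol && (hi - lo) < 1e-6) break
  }
  if (abs(prev - target) > tol) {
    stop_bmistrat(
      sprintf("intercept calibration did not converge (prevalence %.4f vs target %.4f)",
              prev, target),
      "bmistrat_numeric_error"
    )
  }
  alpha
}

#' Simulate a cohort
#'
#' Generates genotypes, BMI and disease status under the model described in
#' the package vignette. When a variant's `info` score is below 1, the
#' stored dosage is the true genotype plus Gaussian noise of variance
#' `(1 - info) * 2 f (1 - f)` (the standard variance-ratio convention for
#' imputation quality), truncated to \[0, 2\]; disease and BMI are always
#' generated from the true genotypes, so low-info variants show attenuated
#' association, as in real imputed data.
#'
#' @param panel variant panel.
#' @param config a [cohort_config()].
#' @param alpha optional pre-computed intercept (from
#'   [calibrate_intercept()]); computed internally when `NULL`.
#' @return An object of class `cohort`: a list with elements `panel`,
#'   `genotypes` (n x J dosage matrix), `bmi`, `status` (0/1), `info`
#'   (per-variant quality scores) and `alpha`.
#' @export
simulate_cohort <- function(panel, config, alpha = NULL) {
  validate_panel(panel)
  if (is.null(alpha)) alpha <- calibrate_intercept(panel, config)
  n <- config$n_individuals
  g <- with_substream(config$seed, "genotypes", draw_genotypes(panel, n))
  bmi <- with_substream(config$seed, "bmi",
    config$bmi_mean + as.numeric(g %*% panel$bmi_effect) +
      stats::rnorm(n, 0, config$bmi_sd))
  z <- (bmi - config$bmi_mean) / config$bmi_sd
  eta <- alpha + disease_eta(panel, g, z, config$bmi_gamma)
  status <- with_substream(config$seed, "status",
    stats::rbinom(n, 1L, stats::plogis(eta)))
  dosages <- g
  noisy <- which(panel$info < 1)
  if (length(noisy)) {
    dosages[, noisy] <- with_substream(config$seed, "dosage_noise", {
      x <- g[, noisy, drop = FALSE]
      sds <- sqrt((1 - panel$info[noisy]) *
                    2 * panel$eaf[noisy] * (1 - panel$eaf[noisy]))
      x + matrix(stats::rnorm(n * length(noisy), 0, rep(sds, each = n)),
                 nrow = n)
    })
    dosages[, noisy] <- pmin(pmax(dosages[, noisy, drop = FALSE], 0), 2)
  }
  structure(
    list(panel = panel, genotypes = dosages, bmi = bmi,
         status = as.integer(status), info = stats::setNames(panel$info, panel$variant_id),
         alpha = alpha, config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individuals, %d variants, prevalence %.3f\n",
              length(x$status), nrow(x$panel), mean(x$status)))
  invisible(x)
}

#' Ascertain a BMI-stratified case-control study from a cohort
#'
#' Draws, without replacement, lean cases (disease and BMI < `lean_max`),
#' obese cases (disease and BMI >= `obese_min`) and controls (no disease).
#' By default controls are *not* screened on BMI and the same control set
#' serves both strata, mirroring designs that use one unstratified control
#' pool; `stratify_controls = TRUE` instead draws separate control sets with
#' BMI < `lean_max` and BMI >= `obese_min` (the sensitivity design).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param n_lean_cases,n_obese_cases,n_controls requested counts.
#' @param seed integer seed for the ascertainment draw.
#' @param stratify_controls restrict controls by BMI per stratum?
#' @param lean_max,obese_min BMI cut-offs, kg/m^2.
#' @param study_id label carried into downstream summary statistics.
#' @return An object of class `study_dataset` holding index vectors
#'   `case_ids_lean`, `case_ids_obese` and either `control_ids` (shared) or
#'   `control_ids_lean`/`control_ids_obese` (stratified).
#' @export
ascertain_study <- function(cohort, n_lean_cases, n_obese_cases, n_controls,
                            seed = 1, stratify_controls = FALSE,
                            lean_max = 25, obese_min = 30,
                            study_id = "study1") {
  stopifnot(inherits(cohort, "cohort"))
  lean_pool <- which(cohort$status == 1L & cohort$bmi < lean_max)
  obese_pool <- which(cohort$status == 1L & cohort$bmi >= obese_min)
  ctrl_pool <- which(cohort$status == 0L)
  need <- function(pool, n, what) {
    if (length(pool) < n) {
      stop_bmistrat(
        sprintf("cohort has only %d %s but %d were requested",
                length(pool), what, n),
        "bmistrat_ascertainment_error"
      )
    }
  }
  need(lean_pool, n_lean_cases, "lean cases")
  need(obese_pool, n_obese_cases, "obese cases")
  out <- with_substream(seed, "ascertainment", {
    lean <- sort(sample(lean_pool, n_lean_cases))
    obese <- sort(sample(obese_pool, n_obese_cases))
    if (stratify_controls) {
      pool_l <- ctrl_pool[cohort$bmi[ctrl_pool] < lean_max]
      pool_o <- ctrl_pool[cohort$bmi[ctrl_pool] >= obese_min]
      need(pool_l, n_controls, "controls (lean stratum)")
      need(pool_o, n_controls, "controls (obese stratum)")
      list(lean = lean, obese = obese,
           ctrl_l = sort(sample(pool_l, n_controls)),
           ctrl_o = sort(sample(pool_o, n_controls)))
    } else {
      need(ctrl_pool, n_controls, "controls")
      ctrl <- sort(sample(ctrl_pool, n_controls))
      list(lean = lean, obese = obese, ctrl_l = ctrl, ctrl_o = ctrl)
    }
  })
  structure(
    list(study_id = study_id,
         case_ids_lean = out$lean, case_ids_obese = out$obese,
         control_ids = if (stratify_controls) NULL else out$ctrl_l,
         control_ids_lean = out$ctrl_l, control_ids_obese = out$ctrl_o,
         bmi_cutoff_lean = lean_max, bmi_cutoff_obese = obese_min,
         stratified_controls = stratify_controls),
    class = "study_dataset"
  )
}

# Control indices serving a given stratum of a study.
controls_for <- function(study, stratum = c("lean", "obese", "all")) {
  stratum <- match.arg(stratum)
  switch(stratum,
         lean = study$control_ids_lean,
         obese = study$control_ids_obese,
         all = sort(unique(c(study$control_ids_lean, study$control_ids_obese))))
}

# Case indices for a stratum ("all" = both strata pooled).
cases_for <- function(study, stratum = c("lean", "obese", "all")) {
  stratum <- match.arg(stratum)
  switch(stratum,
         lean = study$case_ids_lean,
         obese = study$case_ids_obese,
         all = sort(unique(c(study$case_ids_lean, study$case_ids_obese))))
}
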