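# Per-study association testing: additive logistic scans within a BMI
# stratum, QC filters (imputation quality, MAF), genomic control, and the
# case-only genotype -> BMI scan.

STATS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "z", "p", "chi2",
                   "info", "n_cases", "n_controls", "analysis_tag",
                   "gc_applied", "exclusion_reason")

#' Additive logistic association fit for one variant
#'
#' Maximum-likelihood logistic regression of case status on allele dosage
#' (the additive genetic model), with Wald standard error and two-sided
#' p-value computed from the standard normal.
#'
#' @param dosages numeric vector of allele dosages in \[0, 2\].
#' @param status 0/1 case status vector of the same length.
#' @param covariates optional numeric matrix of adjustment covariates.
#' @return A list with `beta` (log-OR per effect allele), `se`, `z`, `p`
#'   and `chi2` (= z^2).
#' @examples
#' d <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
#' y <- c(rep(1, 100), rep(0, 100))
#' fit_additive_logistic(d, y)$beta  # ln((30*90)/(70*10))
#' @export
fit_additive_logistic <- function(dosages, status, covariates = NULL) {
  if (length(dosages) != length(status)) {
    stop_bmistrat("dosages and status must have equal length",
                  "bmistrat_validation_error")
  }
  if (anyNA(dosages) || anyNA(status)) {
    stop_bmistrat("missing values must be handled by the caller",
                  "bmistrat_validation_error")
  }
  if (length(unique(status)) < 2L) {
    stop_bmistrat("only one outcome class present",
                  "bmistrat_fit_error")
  }
  if (length(unique(dosages)) < 2L) {
    stop_bmistrat("dosage has no variance", "bmistrat_fit_error")
  }
  dat <- data.frame(status = status, dosage = dosages)
  form <- status ~ dosage
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c("dosage", colnames(covariates)),
                               response = "status")
  }
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  )
  beta <- unname(stats::coef(fit)["dosage"])
  se <- sqrt(stats::vcov(fit)["dosage", "dosage"])
  if (!fit$converged || !is.finite(beta) || !is.finite(se) || se > 100) {
    stop_bmistrat("logistic fit unstable (separation or non-convergence)",
                  "bmistrat_fit_error")
  }
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       chi2 = z^2)
}

# One row of the summary-statistics table.
assoc_record <- function(panel_row, eaf, fit, n_cases, n_controls, tag) {
  data.frame(
    variant_id = panel_row$variant_id, chrom = panel_row$chrom,
    pos = panel_row$pos, effect_allele = panel_row$effect_allele,
    other_allele = panel_row$other_allele, eaf = eaf,
    beta = fit$beta, se = fit$se, z = fit$z, p = fit$p, chi2 = fit$chi2,
    info = panel_row$info, n_cases = n_cases, n_controls = n_controls,
    analysis_tag = tag, gc_applied = 0L, exclusion_reason = "",
    stringsAsFactors = FALSE
  )
}

na_fit <- list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
               chi2 = NA_real_)

#' Stratified case-control association scan
#'
#' Runs the additive logistic fit for every panel variant in one BMI
#' stratum of a study (stratum cases versus that stratum's controls; with
#' an unstratified design the control set is shared between strata).
#' Variants are included only if their imputation quality exceeds
#' `info_min` and their minor allele frequency, computed in the analysis
#' sample, exceeds `maf_min`; excluded variants are recorded with a reason
#' (`"info"` or `"maf"`) in the `"exclusions"` attribute. Per-variant fit
#' failures (e.g. separation) yield a record with `NA` estimates rather
#' than aborting the scan.
#'
#' @param study a [ascertain_study()] result.
#' @param cohort the cohort the study indexes into.
#' @param stratum `"lean"`, `"obese"`, or `"all"` (both case strata pooled).
#' @param info_min imputation-quality inclusion threshold (strict >).
#' @param maf_min minor-allele-frequency inclusion threshold (strict >).
#' @return A data frame of summary statistics (one row per included
#'   variant) with attribute `"exclusions"`, a data frame of
#'   `variant_id`/`reason` pairs.
#' @export
run_stratified_gwas <- function(study, cohort,
                                stratum = c("lean", "obese", "all"),
                                info_min = 0.5, maf_min = 0.01) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(study, "study_dataset"), inherits(cohort, "cohort"))
  case_idx <- cases_for(study, stratum)
  ctrl_idx <- controls_for(study, stratum)
  if (!length(case_idx) || !length(ctrl_idx)) {
    stop_bmistrat("stratum cases and controls must be non-empty",
                  "bmistrat_validation_error")
  }
  idx <- c(case_idx, ctrl_idx)
  y <- c(rep(1L, length(case_idx)), rep(0L, length(ctrl_idx)))
  panel <- cohort$panel
  records <- vector("list", nrow(panel))
  excl <- list()
  for (j in seq_len(nrow(panel))) {
    d <- cohort$genotypes[idx, j]
    keep <- !is.na(d)
    d <- d[keep]; yk <- y[keep]
    eaf <- mean(d) / 2
    maf <- min(eaf, 1 - eaf)
    info <- panel$info[j]
    if (!(info > info_min)) {
      excl[[length(excl) + 1L]] <- data.frame(
        variant_id = panel$variant_id[j], reason = "info",
        stringsAsFactors = FALSE)
      next
    }
    if (!(maf > maf_min)) {
      excl[[length(excl) + 1L]] <- data.frame(
        variant_id = panel$variant_id[j], reason = "maf",
        stringsAsFactors = FALSE)
      next
    }
    fit <- tryCatch(fit_additive_logistic(d, yk), error = function(e) na_fit)
    records[[j]] <- assoc_record(panel[j, ], eaf, fit,
                                 n_cases = sum(yk), n_controls = sum(!yk),
                                 tag = stratum)
  }
  out <- do.call(rbind, records[!vapply(records, is.null, logical(1))])
  if (is.null(out)) {
    warning("no variants passed the info/MAF filters")
    out <- empty_stats()
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) {
    do.call(rbind, excl)
  } else {
    data.frame(variant_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  out
}

empty_stats <- function() {
  out <- data.frame(
    variant_id = character(0), chrom = character(0), pos = integer(0),
    effect_allele = character(0), other_allele = character(0),
    eaf = numeric(0), beta = numeric(0), se = numeric(0), z = numeric(0),
    p = numeric(0), chi2 = numeric(0), info = numeric(0),
    n_cases = integer(0), n_controls = integer(0),
    analysis_tag = character(0), gc_applied = integer(0),
    exclusion_reason = character(0), stringsAsFactors = FALSE
  )
  out
}

#' Case-only genotype-to-BMI scan
#'
#' Regresses BMI (as a quantitative trait) on allele dosage among disease
#' cases only, one variant at a time, by ordinary least squares. Under a
#' multiplicative disease model with rare disease and no effect
#' modification, the slope is null; a non-zero slope indicates that the
#' variant's disease effect varies with BMI (a risk allele with a stronger
#' effect in lean cases shows a negative slope).
#'
#' @param genotypes dosage matrix for the cases (columns named by variant).
#' @param bmi BMI vector for the same cases.
#' @param panel optional variant panel supplying alleles/positions for the
#'   output records (matched by `variant_id`); minimal metadata is invented
#'   otherwise.
#' @return A data frame of summary statistics with
#'   `analysis_tag = "case_only_bmi"` and `n_controls = 0`; `beta` is in
#'   kg/m^2 per effect allele. Zero-variance variants get `NA` estimates.
#' @export
case_only_bmi_scan <- function(genotypes, bmi, panel = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (n < 10L) {
    stop_bmistrat("case-only scan requires at least 10 cases",
                  "bmistrat_validation_error")
  }
  if (anyNA(bmi) || any(!is.finite(bmi))) {
    stop_bmistrat("BMI must be finite", "bmistrat_validation_error")
  }
  ids <- colnames(genotypes) %||% sprintf("snp%05d", seq_len(ncol(genotypes)))
  records <- vector("list", ncol(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    d <- genotypes[, j]
    keep <- !is.na(d)
    dk <- d[keep]; bk <- bmi[keep]
    fit <- if (length(unique(dk)) < 2L) {
      na_fit
    } else {
      m <- stats::lm.fit(cbind(1, dk), bk)
      rss <- sum(m$residuals^2)
      sxx <- sum((dk - mean(dk))^2)
      beta <- unname(m$coefficients[2L])
      se <- sqrt(rss / (length(dk) - 2L) / sxx)
      z <- beta / se
      list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
           chi2 = z^2)
    }
    prow <- panel_row_for(panel, ids[j])
    records[[j]] <- assoc_record(prow, eaf = mean(dk) / 2, fit,
                                 n_cases = length(dk), n_controls = 0L,
                                 tag = "case_only_bmi")
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

panel_row_for <- function(panel, id) {
  if (!is.null(panel) && id %in% panel$variant_id) {
    panel[match(id, panel$variant_id), ]
  } else {
    data.frame(variant_id = id, chrom = "NA", pos = 0L,
               effect_allele = "A", other_allele = "G", info = 1,
               stringsAsFactors = FALSE)
  }
}

#' Genomic-control inflation factor
#'
#' lambda = median(chi2) / 0.4549364 (the median of the 1-df chi-square
#' distribution). Values near 1 indicate well-calibrated test statistics;
#' values above 1 indicate inflation, e.g. from population structure.
#'
#' @param chi2_values non-empty vector of 1-df chi-square statistics
#'   (`NA`s, e.g. from failed fits, are dropped).
#' @return An object of class `gc_result`: list with `lambda` and
#'   `n_snps_used`.
#' @export
genomic_lambda <- function(chi2_values) {
  chi2_values <- chi2_values[!is.na(chi2_values)]
  if (!length(chi2_values)) {
    stop_bmistrat("no chi-square values supplied",
                  "bmistrat_validation_error")
  }
  if (any(chi2_values < 0)) {
    stop_bmistrat("chi-square values must be non-negative",
                  "bmistrat_validation_error")
  }
  structure(
    list(lambda = stats::median(chi2_values) / CHISQ1_MEDIAN,
         n_snps_used = length(chi2_values)),
    class = "gc_result"
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("<gc_result> lambda = %.4f (n = %d)\n", x$lambda, x$n_snps_used))
  invisible(x)
}

#' Apply genomic control to a set of summary statistics
#'
#' Divides each chi-square statistic by `max(lambda, 1)`, inflates the
#' standard errors by `sqrt(max(lambda, 1))` and recomputes p-values from
#' the adjusted 1-df chi-square; effect estimates are unchanged. Deflation
#' with lambda < 1 is never applied (the usual genomic-control convention),
#' and a record set that has already been adjusted is refused, so the
#' correction cannot be applied twice.
#'
#' @param records summary-statistics data frame (dialect of
#'   [run_stratified_gwas()]).
#' @param gc a [genomic_lambda()] result.
#' @return The adjusted records, with `gc_applied = 1`.
#' @export
apply_genomic_control <- function(records, gc) {
  stopifnot(inherits(gc, "gc_result"))
  if (any(records$gc_applied == 1L)) {
    stop_bmistrat("genomic control has already been applied to these records",
                  "bmistrat_validation_error")
  }
  lam <- max(gc$lambda, 1)
  records$chi2 <- records$chi2 / lam
  records$se <- records$se * sqrt(lam)
  records$z <- sign(records$z) * sqrt(records$chi2)
  records$p <- stats::pchisq(records$chi2, df = 1, lower.tail = FALSE)
  records$gc_applied <- 1L
  records
}
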