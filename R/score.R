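# Known-locus analyses: binomial sign enrichment of lean vs obese effect
# sizes, weighted genetic risk scores, per-weighted-allele odds ratios, and
# per-quintile odds ratios.

#' Binomial sign-enrichment test of lean versus obese effect sizes
#'
#' Counts, across independent risk loci, how often the lean-stratum odds
#' ratio exceeds the obese-stratum odds ratio, and tests the count against
#' the null of no systematic difference (each locus a fair coin) with the
#' exact binomial tail. Ties at full input precision are excluded and
#' reported. The one-sided p-value is the tail in the pre-specified
#' direction (lean larger); the two-sided value doubles the smaller tail.
#'
#' @param pairs data frame with columns `or_lean` and `or_obese` (both
#'   positive), one row per locus; or pass two numeric vectors via
#'   `or_lean`/`or_obese`.
#' @param or_lean,or_obese alternative vector interface.
#' @return An object of class `sign_test`: list with `n_compared`,
#'   `n_lean_larger`, `n_ties_excluded`, `p_one_sided`, `p_two_sided`.
#' @examples
#' sign_enrichment_test(or_lean = c(1.2, 1.3, 1.1), or_obese = c(1.1, 1.2, 1.15))
#' @export
sign_enrichment_test <- function(pairs = NULL, or_lean = NULL,
                                 or_obese = NULL) {
  if (!is.null(pairs)) {
    or_lean <- pairs$or_lean
    or_obese <- pairs$or_obese
  }
  if (length(or_lean) != length(or_obese)) {
    stop_bmistrat("or_lean and or_obese must have equal length",
                  "bmistrat_validation_error")
  }
  if (any(or_lean <= 0) || any(or_obese <= 0)) {
    stop_bmistrat("odds ratios must be positive",
                  "bmistrat_validation_error")
  }
  ties <- or_lean == or_obese
  n_ties <- sum(ties)
  n <- sum(!ties)
  if (n < 1L) {
    stop_bmistrat("no comparable pairs remain after excluding ties",
                  "bmistrat_validation_error")
  }
  k <- sum(or_lean[!ties] > or_obese[!ties])
  p_up <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)  # P(X >= k)
  p_down <- stats::pbinom(k, n, 0.5)                        # P(X <= k)
  structure(
    list(n_compared = n, n_lean_larger = k, n_ties_excluded = n_ties,
         p_one_sided = p_up, p_two_sided = min(1, 2 * min(p_up, p_down))),
    class = "sign_test"
  )
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf(
    "<sign_test> %d/%d loci lean-larger (%d ties excluded); one-sided p = %.3g, two-sided p = %.3g\n",
    x$n_lean_larger, x$n_compared, x$n_ties_excluded,
    x$p_one_sided, x$p_two_sided))
  invisible(x)
}

#' Weighted risk-allele score
#'
#' Per-individual score `S_i = sum_j w_j g_ij`, where `g_ij` counts copies
#' of the weight's effect allele. Genotype columns whose counted allele is
#' the weight's *other* allele are flipped (`g -> 2 - g`) before summing;
#' missing dosages are imputed by `2 * eaf` (the expected dosage).
#'
#' @param genotypes dosage matrix with variant IDs as column names.
#' @param weights data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `weight` (log-OR units) and `eaf` (used for
#'   missing-dosage imputation).
#' @param panel optional data frame (`variant_id`, `effect_allele`,
#'   `other_allele`) giving the allele counted by each genotype column;
#'   when `NULL` the genotypes are assumed already aligned to the weights.
#' @return Numeric vector of per-individual scores.
#' @export
weighted_allele_score <- function(genotypes, weights, panel = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!nrow(weights)) {
    stop_bmistrat("weights must contain at least one variant",
                  "bmistrat_validation_error")
  }
  if (any(!is.finite(weights$weight))) {
    stop_bmistrat("weights must be finite", "bmistrat_validation_error")
  }
  missing_ids <- setdiff(weights$variant_id, colnames(genotypes))
  if (length(missing_ids)) {
    stop_bmistrat(paste0("weight variants absent from genotypes: ",
                         paste(missing_ids, collapse = ", ")),
                  "bmistrat_validation_error")
  }
  g <- genotypes[, weights$variant_id, drop = FALSE]
  if (!is.null(panel)) {
    m <- match(weights$variant_id, panel$variant_id)
    if (anyNA(m)) {
      stop_bmistrat(paste0("weight variants absent from panel: ",
                           paste(weights$variant_id[is.na(m)], collapse = ", ")),
                    "bmistrat_validation_error")
    }
    counted <- panel$effect_allele[m]
    other <- panel$other_allele[m]
    same <- counted == weights$effect_allele & other == weights$other_allele
    flip <- counted == weights$other_allele & other == weights$effect_allele
    if (any(!(same | flip))) {
      bad <- weights$variant_id[!(same | flip)]
      stop_bmistrat(paste0("allele pair mismatch for: ",
                           paste(bad, collapse = ", ")),
                    "bmistrat_validation_error")
    }
    if (any(flip)) g[, flip] <- 2 - g[, flip, drop = FALSE]
  }
  if (anyNA(g)) {
    imp <- matrix(rep(2 * weights$eaf, each = nrow(g)), nrow = nrow(g))
    g[is.na(g)] <- imp[is.na(g)]
  }
  as.numeric(g %*% weights$weight)
}

#' Fit the weighted-score logistic model
#'
#' Logistic regression of case status on the score rescaled by the mean
#' weight, so that the reported odds ratio is per "average-effect risk
#' allele": a unit change in the rescaled score corresponds to carrying one
#' extra risk allele of average effect size. The fit is invariant to
#' rescaling all weights by a common factor.
#'
#' @param scores per-individual weighted scores ([weighted_allele_score()]).
#' @param status 0/1 case status.
#' @param weights the weight set used to build the scores (data frame with
#'   a `weight` column, or a numeric vector).
#' @return An object of class `score_result`: list with `beta`, `se`,
#'   `or`, `ci_low`, `ci_high`, `p` (per average-weighted allele),
#'   `mean_weight`, `n_cases`, `n_controls`.
#' @export
fit_score_model <- function(scores, status, weights) {
  w <- if (is.data.frame(weights)) weights$weight else as.numeric(weights)
  mw <- mean(w)
  if (!is.finite(mw) || mw == 0) {
    stop_bmistrat("mean weight must be non-zero", "bmistrat_validation_error")
  }
  if (stats::var(scores) == 0) {
    stop_bmistrat("score has no variance", "bmistrat_validation_error")
  }
  if (length(unique(status)) < 2L) {
    stop_bmistrat("both outcome classes must be present",
                  "bmistrat_validation_error")
  }
  fit <- fit_additive_logistic(scores / mw, status)
  structure(
    list(beta = fit$beta, se = fit$se,
         or = exp(fit$beta),
         ci_low = exp(fit$beta - Z975 * fit$se),
         ci_high = exp(fit$beta + Z975 * fit$se),
         p = fit$p, mean_weight = mw,
         n_cases = sum(status == 1), n_controls = sum(status == 0)),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf(
    "<score_result> per-weighted-allele OR = %.3f [%.3f-%.3f], p = %.3g (%d cases / %d controls)\n",
    x$or, x$ci_low, x$ci_high, x$p, x$n_cases, x$n_controls))
  invisible(x)
}

#' Per-quintile odds ratios of a risk score
#'
#' Ranks the pooled case-control sample by score (ties broken by stable
#' input order), splits it into `n_bins` bins whose sizes differ by at most
#' one, and computes each bin's odds ratio against the middle (reference)
#' bin from the 2x2 case/control table, with Woolf (log-scale normal)
#' confidence intervals. Bins with an empty case or control cell get an
#' `NA` odds ratio and are flagged rather than causing an error; no
#' continuity correction is applied.
#'
#' @param scores per-individual scores (cases and controls pooled).
#' @param status 0/1 case status.
#' @param n_bins number of score bins (default 5, i.e. quintiles).
#' @return An object of class `quintile_result`: data frame with one row
#'   per bin (`bin`, `n`, `n_cases`, `n_controls`, `or`, `ci_low`,
#'   `ci_high`, `degenerate`), reference bin attribute `"reference"`.
#' @export
quintile_ors <- function(scores, status, n_bins = 5L) {
  n <- length(scores)
  stopifnot(length(status) == n)
  if (n < 50L) {
    stop_bmistrat("need at least 50 pooled individuals",
                  "bmistrat_validation_error")
  }
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(scores)  # radix sort: stable for ties
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  ref <- as.integer(ceiling(n_bins / 2))
  a_ref <- sum(status[bin == ref] == 1)
  c_ref <- sum(status[bin == ref] == 0)
  rows <- lapply(seq_len(n_bins), function(b) {
    a <- sum(status[bin == b] == 1)
    c <- sum(status[bin == b] == 0)
    if (b == ref) {
      data.frame(bin = b, n = a + c, n_cases = a, n_controls = c,
                 or = 1, ci_low = 1, ci_high = 1, degenerate = FALSE)
    } else if (a == 0 || c == 0 || a_ref == 0 || c_ref == 0) {
      data.frame(bin = b, n = a + c, n_cases = a, n_controls = c,
                 or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 degenerate = TRUE)
    } else {
      or <- (a / c) / (a_ref / c_ref)
      se <- sqrt(1 / a + 1 / c + 1 / a_ref + 1 / c_ref)
      data.frame(bin = b, n = a + c, n_cases = a, n_controls = c,
                 or = or, ci_low = exp(log(or) - Z975 * se),
                 ci_high = exp(log(or) + Z975 * se), degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- ref
  attr(out, "bin_assignments") <- bin
  class(out) <- c("quintile_result", "data.frame")
  out
}

#' Compare lean and obese weighted-score fits
#'
#' Applies the stratum heterogeneity z-test to two [fit_score_model()]
#' results (per-weighted-allele log-ORs).
#'
#' @param lean,obese `score_result` objects.
#' @return A `het_test` object (see [stratum_heterogeneity_test()]).
#' @export
compare_stratum_scores <- function(lean, obese) {
  stopifnot(inherits(lean, "score_result"), inherits(obese, "score_result"))
  stratum_heterogeneity_test(lean$beta, lean$se, obese$beta, obese$se)
}

#' Case-versus-case score model
#'
#' Drops the controls entirely and regresses lean-versus-obese case status
#' on the (rescaled) risk score: a positive coefficient means lean cases
#' carry higher weighted risk-allele loads than obese cases. This design
#' avoids the shared-control correlation that makes the naive two-stratum
#' comparison anti-conservative.
#'
#' @param scores per-case weighted scores (lean and obese cases only).
#' @param is_lean logical/0-1 vector, `TRUE` for lean cases.
#' @param weights weight set used for the scores (for per-average-allele
#'   scaling).
#' @return A `score_result` whose `or` is the odds of being a lean (rather
#'   than obese) case per average-weighted risk allele.
#' @export
score_case_vs_case <- function(scores, is_lean, weights) {
  fit_score_model(scores, as.integer(as.logical(is_lean)), weights)
}

#' Published lean/obese odds-ratio pairs for 36 known type 2 diabetes loci
#'
#' Loads the table of 36 established European type 2 diabetes risk loci
#' shipped with the package, with the published lean-stratum and
#' obese-stratum odds ratios (and 95% CIs and p-values) from BMI-stratified
#' case-control meta-analyses (2,112 lean cases / 4,123 obese cases versus
#' shared unstratified controls). This is the input for
#' [sign_enrichment_test()].
#'
#' @return Data frame with columns `variant_id`, `gene`, `chrom`,
#'   `risk_allele`, `or_lean`, `ci_low_lean`, `ci_high_lean`, `p_lean`,
#'   `or_obese`, `ci_low_obese`, `ci_high_obese`, `p_obese`.
#' @export
known_t2d_loci <- function() {
  path <- system.file("extdata", "known_t2d_loci_lean_obese.tsv",
                      package = "bmistrat", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}
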