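# Sign enrichment, weighted risk scores, quintile odds ratios.

test_that("sign test handles the published 36-locus table and extremes", {
  loci <- known_t2d_loci()
  st <- sign_enrichment_test(loci)
  expect_equal(st$n_compared, 36L)
  expect_equal(st$n_lean_larger, 29L)
  expect_equal(st$n_ties_excluded, 0L)
  expect_equal(st$p_one_sided, pbinom(28, 36, 0.5, lower.tail = FALSE))

  all_lean <- sign_enrichment_test(or_lean = rep(1.2, 36),
                                   or_obese = rep(1.1, 36))
  expect_equal(all_lean$p_one_sided, 2^-36, tolerance = 1e-15)

  expect_error(sign_enrichment_test(or_lean = rep(1.1, 3),
                                    or_obese = rep(1.1, 3)),
               class = "bmistrat_validation_error")
})

test_that("sign test equals exhaustive enumeration for n <= 10", {
  for (n in c(1, 3, 6, 10)) {
    patterns <- as.matrix(expand.grid(rep(list(0:1), n)))
    for (k in 1:n) {
      st <- sign_enrichment_test(
        or_lean = c(rep(1.2, k), rep(1.0, n - k)),
        or_obese = c(rep(1.1, k), rep(1.1, n - k)))
      brute_one <- mean(rowSums(patterns) >= k)
      brute_two <- min(1, 2 * min(brute_one, mean(rowSums(patterns) <= k)))
      expect_equal(st$n_lean_larger, k)
      expect_equal(st$p_one_sided, brute_one, tolerance = 1e-12)
      expect_equal(st$p_two_sided, brute_two, tolerance = 1e-12)
    }
  }
})

test_that("sign test tails agree with binom.test", {
  st <- sign_enrichment_test(or_lean = c(rep(1.3, 22), rep(1.0, 8)),
                             or_obese = rep(1.1, 30))
  bt <- binom.test(22, 30, 0.5, alternative = "greater")
  expect_equal(st$p_one_sided, bt$p.value, tolerance = 1e-12)
  expect_equal(st$n_ties_excluded, 0L)
})

test_that("weighted score sums, imputes and harmonizes dosages", {
  w <- data.frame(variant_id = c("v1", "v2", "v3"),
                  effect_allele = c("A", "A", "A"),
                  other_allele = c("G", "G", "G"),
                  weight = c(1, 1, 1), eaf = c(0.3, 0.3, 0.3))
  g <- matrix(c(0, 1, 2), nrow = 1, dimnames = list(NULL, c("v1", "v2", "v3")))
  expect_equal(weighted_allele_score(g, w), 3)

  # missing genotype imputed by 2 * eaf
  w1 <- data.frame(variant_id = "v1", effect_allele = "A", other_allele = "G",
                   weight = 0.1, eaf = 0.3)
  gna <- matrix(NA_real_, nrow = 1, dimnames = list(NULL, "v1"))
  expect_equal(weighted_allele_score(gna, w1), 0.06)

  # genotype counts the other allele: g = 2 contributes w * (2 - 2) = 0
  panel <- data.frame(variant_id = "v1", effect_allele = "G",
                      other_allele = "A")
  g2 <- matrix(2, nrow = 1, dimnames = list(NULL, "v1"))
  expect_equal(weighted_allele_score(g2, w1, panel = panel), 0)

  # unknown variant and allele mismatch raise informative errors
  expect_error(weighted_allele_score(g, w1[0, ]),
               class = "bmistrat_validation_error")
  wmiss <- data.frame(variant_id = "v9", effect_allele = "A",
                      other_allele = "G", weight = 1, eaf = 0.5)
  expect_error(weighted_allele_score(g, wmiss), "v9",
               class = "bmistrat_validation_error")
  badpanel <- data.frame(variant_id = "v1", effect_allele = "C",
                         other_allele = "T")
  expect_error(weighted_allele_score(g2, w1, panel = badpanel), "v1",
               class = "bmistrat_validation_error")
})

test_that("score is linear in concatenated weight sets", {
  withr::with_seed(5, {
    g <- matrix(rbinom(200, 2, 0.4), nrow = 20,
                dimnames = list(NULL, sprintf("v%d", 1:10)))
    mk <- function(ids, w) data.frame(variant_id = ids, effect_allele = "A",
                                      other_allele = "G", weight = w,
                                      eaf = 0.4)
    wa <- mk(sprintf("v%d", 1:4), c(0.1, 0.2, 0.3, 0.4))
    wb <- mk(sprintf("v%d", 5:10), rep(0.15, 6))
    expect_equal(weighted_allele_score(g, rbind(wa, wb)),
                 weighted_allele_score(g, wa) + weighted_allele_score(g, wb))
  })
})

test_that("score model is scale invariant and rejects degenerate input", {
  withr::with_seed(9, {
    w <- data.frame(variant_id = sprintf("v%d", 1:5),
                    effect_allele = "A", other_allele = "G",
                    weight = runif(5, 0.05, 0.3), eaf = runif(5, 0.2, 0.8))
    g <- matrix(rbinom(5 * 400, 2, 0.4), ncol = 5,
                dimnames = list(NULL, w$variant_id))
    s <- weighted_allele_score(g, w)
    y <- rbinom(400, 1, plogis(-1 + s))
    fit1 <- fit_score_model(s, y, w)
    w10 <- w; w10$weight <- w$weight * 10
    fit10 <- fit_score_model(weighted_allele_score(g, w10), y, w10)
    expect_equal(fit1$beta, fit10$beta, tolerance = 1e-9)
    expect_error(fit_score_model(rep(1, 10), rep(0:1, 5), w),
                 class = "bmistrat_validation_error")
    expect_error(fit_score_model(s, rep(1, 400), w),
                 class = "bmistrat_validation_error")
  })
})

test_that("per-average-allele OR covers its theoretical value", {
  # 36 loci with true per-allele ORs ~ 1.05-1.3; under the generative
  # logistic model the per-average-weighted-allele log-OR is mean(beta_j)
  withr::with_seed(123, {
    betas <- log(runif(36, 1.05, 1.3))
    specs <- data.frame(index = 1:36, beta_base = betas)
    panel <- simulate_variants(36, seed = 301, effect_specs = specs)
    w <- data.frame(variant_id = panel$variant_id,
                    effect_allele = panel$effect_allele,
                    other_allele = panel$other_allele,
                    weight = betas, eaf = panel$eaf)
    cfg <- cohort_config(22000, target_prevalence = 0.12, bmi_gamma = 0,
                         seed = 1)
    alpha <- calibrate_intercept(panel, cfg)
    target <- exp(mean(betas))
    covered <- vapply(1:100, function(r) {
      cfg$seed <- 9000 + r
      cohort <- simulate_cohort(panel, cfg, alpha = alpha)
      cases <- sample(which(cohort$status == 1), 2000)
      ctrls <- sample(which(cohort$status == 0), 4000)
      idx <- c(cases, ctrls)
      s <- weighted_allele_score(cohort$genotypes[idx, ], w, panel = panel)
      fit <- fit_score_model(s, rep(1:0, c(2000, 4000)), w)
      fit$ci_low <= target && target <= fit$ci_high
    }, logical(1))
    expect_gte(sum(covered), 90)
  })
})

test_that("quintile bins are balanced with a unit reference", {
  withr::with_seed(31, {
    s <- rnorm(10003)
    y <- rbinom(10003, 1, 0.5)
    q <- quintile_ors(s, y)
    expect_equal(nrow(q), 5L)
    expect_lte(diff(range(q$n)), 1)
    expect_equal(attr(q, "reference"), 3L)
    expect_equal(q$or[3], 1)
    # score independent of status: every OR near 1 at this n
    expect_true(all(q$or[!is.na(q$or)] >= 0.85 & q$or[!is.na(q$or)] <= 1.18))
  })
})

test_that("quintile ORs flag degenerate bins instead of failing", {
  # perfectly separating score: top fifth all cases, bottom fifth all controls
  s <- seq_len(100)
  y <- c(rep(0, 80), rep(1, 20))
  q <- quintile_ors(s, y)
  expect_true(q$degenerate[5])
  expect_true(is.na(q$or[5]))
  expect_error(quintile_ors(s[1:20], y[1:20]),
               class = "bmistrat_validation_error")
})

test_that("stratum score comparison reproduces the het test and the
          case-vs-case model detects lean enrichment", {
  lean <- structure(list(beta = log(1.13),
                         se = (log(1.17) - log(1.09)) / (2 * qnorm(0.975))),
                    class = "score_result")
  obese <- structure(list(beta = log(1.08),
                          se = (log(1.10) - log(1.05)) / (2 * qnorm(0.975))),
                     class = "score_result")
  h <- compare_stratum_scores(lean, obese)
  expect_equal(round(h$p_het, 3), 0.036)

  same <- compare_stratum_scores(lean, lean)
  expect_equal(same$p_het, 1)

  # lean cases carry higher weighted loads when delta < 0
  specs <- data.frame(index = 1:5, beta_base = log(1.2), delta = -0.2)
  panel <- simulate_variants(5, seed = 401, effect_specs = specs)
  w <- data.frame(variant_id = panel$variant_id,
                  effect_allele = panel$effect_allele,
                  other_allele = panel$other_allele,
                  weight = panel$beta_base, eaf = panel$eaf)
  cfg <- cohort_config(60000, target_prevalence = 0.1, seed = 55)
  cohort <- simulate_cohort(panel, cfg)
  st <- ascertain_study(cohort, 400, 400, 100, seed = 2)
  idx <- c(st$case_ids_lean, st$case_ids_obese)
  s <- weighted_allele_score(cohort$genotypes[idx, ], w, panel = panel)
  cvc <- score_case_vs_case(s, rep(c(1, 0), each = 400), w)
  expect_gt(cvc$beta, 0)
  expect_lt(cvc$p, 0.05)
})
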