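# Fixed/random-effects meta-analysis, CI <-> SE recovery, presence rule,
# significance tiers, stratum heterogeneity.

test_that("se_from_ci recovers beta and se from printed tables", {
  est <- se_from_ci(1.22, 1.12, 1.30)
  expect_equal(est$beta, 0.19885, tolerance = 1e-4)
  expect_equal(est$se, 0.03802, tolerance = 1e-4)

  est0 <- se_from_ci(1.00, 0.90, 1.1111)
  expect_equal(est0$beta, 0)

  expect_error(se_from_ci(1.10, 1.20, 1.05), class = "bmistrat_validation_error")
  expect_error(se_from_ci(1.50, 1.10, 1.20), class = "bmistrat_validation_error")
})

test_that("fixed-effect pooling matches hand formulas and edge cases", {
  # two identical studies: same beta, se / sqrt(2)
  est <- data.frame(beta = c(0.2, 0.2), se = c(0.1, 0.1))
  fe <- fixed_effect_meta(est)
  expect_equal(fe$beta_fe, 0.2)
  expect_equal(fe$se_fe, 0.1 / sqrt(2))
  expect_equal(fe$directions, "++")

  # single study: identity, Q = 0
  one <- fixed_effect_meta(data.frame(beta = 0.3, se = 0.05))
  expect_equal(one$beta_fe, 0.3)
  expect_equal(one$se_fe, 0.05)
  expect_equal(one$Q, 0)
  expect_equal(one$k, 1L)

  expect_error(fixed_effect_meta(data.frame(beta = numeric(0), se = numeric(0))),
               class = "bmistrat_validation_error")
  expect_error(fixed_effect_meta(data.frame(beta = 0.1, se = -1)),
               class = "bmistrat_validation_error")
})

test_that("fixed and random effects agree with metafor", {
  est <- data.frame(beta = c(0.12, 0.30, -0.05, 0.22),
                    se = c(0.08, 0.15, 0.11, 0.05))
  fe <- fixed_effect_meta(est)
  re <- random_effects_meta(est)
  mf_fe <- metafor::rma(yi = est$beta, sei = est$se, method = "FE")
  mf_re <- metafor::rma(yi = est$beta, sei = est$se, method = "DL")
  expect_equal(fe$beta_fe, as.numeric(mf_fe$beta), tolerance = 1e-10)
  expect_equal(fe$se_fe, mf_fe$se, tolerance = 1e-10)
  expect_equal(fe$Q, mf_fe$QE, tolerance = 1e-10)
  expect_equal(re$tau2, mf_re$tau2, tolerance = 1e-10)
  expect_equal(re$beta_fe, as.numeric(mf_re$beta), tolerance = 1e-10)
  expect_equal(re$se_fe, mf_re$se, tolerance = 1e-10)
})

test_that("DerSimonian-Laird behaves at its boundary cases", {
  # hand-computed: Q = 8, tau2 = 0.07, pooled 0.2 with se 0.2
  est <- data.frame(beta = c(0, 0.4), se = c(0.1, 0.1))
  re <- random_effects_meta(est)
  expect_equal(re$Q, 8)
  expect_equal(re$tau2, 0.07)
  expect_equal(re$beta_fe, 0.2)
  expect_equal(re$se_fe, 0.2)

  # homogeneous inputs truncate tau2 to 0 and collapse to fixed effects
  hom <- data.frame(beta = c(0.20, 0.21), se = c(0.1, 0.1))
  expect_equal(random_effects_meta(hom)$tau2, 0)
  expect_equal(random_effects_meta(hom)$beta_fe,
               fixed_effect_meta(hom)$beta_fe)

  # permutation invariance
  perm <- est[2:1, , drop = FALSE]
  expect_equal(random_effects_meta(perm)$beta_fe, re$beta_fe)
  expect_equal(random_effects_meta(perm)$se_fe, re$se_fe)

  expect_error(random_effects_meta(data.frame(beta = 0.1, se = 0.1)),
               class = "bmistrat_validation_error")
})

test_that("pooling invariants hold across random study sets", {
  withr::with_seed(77, {
    for (i in 1:50) {
      k <- sample(2:8, 1)
      est <- data.frame(beta = rnorm(k, 0, 0.3), se = runif(k, 0.02, 0.3))
      fe <- fixed_effect_meta(est)
      re <- random_effects_meta(est)
      expect_gte(fe$beta_fe, min(est$beta))
      expect_lte(fe$beta_fe, max(est$beta))
      expect_lt(fe$se_fe, min(est$se))
      expect_gte(re$se_fe, fe$se_fe)
      expect_gte(re$tau2, 0)
    }
  })
})

test_that("SNP presence rule keeps variants in at least half the studies", {
  tabs <- c(replicate(5, data.frame(variant_id = c("a", "b")),
                      simplify = FALSE),
            replicate(5, data.frame(variant_id = c("a", "c")),
                      simplify = FALSE))
  # a in 10/10, b in 5/10 (kept: not less than half), c in 5/10
  kept <- filter_snp_presence(tabs, 10)
  expect_setequal(kept, c("a", "b", "c"))
  kept4 <- filter_snp_presence(tabs[c(1, 2, 3, 4, 5, 6)][1:5], 10)
  expect_false("c" %in% kept4)  # c present in 0 of these 5
  b4 <- filter_snp_presence(tabs[1:4], 10)  # b in 4/10 -> excluded
  expect_false("b" %in% b4)
  expect_equal(filter_snp_presence(list(data.frame(variant_id = "x")), 1), "x")
})

test_that("significance tiers use strict thresholds", {
  rec <- data.frame(p = c(2.4e-8, 1e-7, 2.5e-8, 5e-7, 0.01))
  tiers <- declare_significance(rec)$tier
  expect_equal(tiers, c("genome-wide", "suggestive", "suggestive",
                        "none", "none"))
})

test_that("stratum heterogeneity test is symmetric and calibrated at zero", {
  h0 <- stratum_heterogeneity_test(0.1, 0.05, 0.1, 0.08)
  expect_equal(h0$z_het, 0)
  expect_equal(h0$p_het, 1)

  h1 <- stratum_heterogeneity_test(0.15, 0.05, 0.05, 0.04)
  h2 <- stratum_heterogeneity_test(0.05, 0.04, 0.15, 0.05)
  expect_equal(h1$z_het, -h2$z_het)
  expect_equal(h1$p_het, h2$p_het)
  expect_error(stratum_heterogeneity_test(0.1, 0, 0.1, 0.1),
               class = "bmistrat_validation_error")
})

test_that("allele harmonization flips and drops as required", {
  ref <- data.frame(variant_id = c("v1", "v2", "v3"),
                    effect_allele = c("A", "C", "G"),
                    other_allele = c("G", "T", "T"))
  rec <- toy_stats(3)
  rec$variant_id <- c("v1", "v2", "v3")
  rec$effect_allele <- c("A", "T", "A")  # v1 aligned, v2 flipped, v3 mismatched
  rec$other_allele <- c("G", "C", "C")
  out <- harmonize_alleles(rec, ref)
  expect_equal(out$variant_id, c("v1", "v2"))
  expect_equal(attr(out, "dropped"), "v3")
  expect_equal(out$beta[1], rec$beta[1])
  expect_equal(out$beta[2], -rec$beta[2])
  expect_equal(out$eaf[2], 1 - rec$eaf[2])
  expect_equal(out$effect_allele[2], "C")
})

test_that("shared controls correlate the stratum estimates, so the naive
          het test is mis-calibrated relative to independent controls", {
  panel <- one_snp_panel(eaf = 0.3, beta = log(1.3))
  cfg <- cohort_config(20000, 0.1, seed = 71)
  alpha <- calibrate_intercept(panel, cfg)
  nrep <- 150
  z_shared <- z_indep <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg$seed <- 5000 + r
    cohort <- simulate_cohort(panel, cfg, alpha = alpha)
    st <- ascertain_study(cohort, 300, 300, 1600, seed = r)
    fit_on <- function(cases, ctrls) {
      fit_additive_logistic(
        cohort$genotypes[c(cases, ctrls), 1],
        rep(1:0, c(length(cases), length(ctrls))))
    }
    ctrl <- st$control_ids
    fl <- fit_on(st$case_ids_lean, ctrl[1:800])
    fo_shared <- fit_on(st$case_ids_obese, ctrl[1:800])
    fo_indep <- fit_on(st$case_ids_obese, ctrl[801:1600])
    z_shared[r] <- stratum_heterogeneity_test(fl$beta, fl$se,
                                              fo_shared$beta, fo_shared$se)$z_het
    z_indep[r] <- stratum_heterogeneity_test(fl$beta, fl$se,
                                             fo_indep$beta, fo_indep$se)$z_het
  }
  # positive covariance from the shared pool shrinks the variance of the
  # naive z below its nominal unit value
  expect_lt(var(z_shared), var(z_indep))
  expect_lt(var(z_shared), 1)
})
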