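# Shared builders for simulation-based tests.

# Panel of one locus with given effects.
one_snp_panel <- function(eaf = 0.3, beta = 0, delta = 0, bmi_effect = 0,
                          info = 1, seed = 11) {
  simulate_variants(
    1, seed = seed,
    effect_specs = data.frame(index = 1, eaf = eaf, beta_base = beta,
                              delta = delta, bmi_effect = bmi_effect,
                              info = info))
}

# Small cohort + study pair for scan tests.
small_study <- function(panel, n = 20000, prevalence = 0.1,
                        n_lean = 200, n_obese = 300, n_ctrl = 2000,
                        seed = 5, alpha = NULL) {
  cfg <- cohort_config(n, prevalence, seed = seed)
  cohort <- simulate_cohort(panel, cfg, alpha = alpha)
  study <- ascertain_study(cohort, n_lean, n_obese, n_ctrl, seed = seed)
  list(cohort = cohort, study = study, config = cfg)
}

# Closed-form 2x2 log-OR and Woolf SE from exposed/unexposed counts.
oracle_2x2 <- function(a_case, b_case, a_ctrl, b_ctrl) {
  list(beta = log((a_case * b_ctrl) / (b_case * a_ctrl)),
       se = sqrt(1 / a_case + 1 / b_case + 1 / a_ctrl + 1 / b_ctrl))
}

# A valid minimal summary-statistics record set for IO tests.
toy_stats <- function(n = 5, seed = 1) {
  withr::with_seed(seed, {
    z <- stats::rnorm(n)
    data.frame(
      variant_id = sprintf("rs%d", seq_len(n)), chrom = "1",
      pos = seq_len(n) * 100L, effect_allele = "A", other_allele = "G",
      eaf = stats::runif(n, 0.05, 0.95),
      beta = z * 0.05, se = rep(0.05, n), z = z,
      p = 2 * stats::pnorm(-abs(z)), chi2 = z^2, info = rep(1, n),
      n_cases = 100L, n_controls = 200L, analysis_tag = "lean",
      gc_applied = 0L, exclusion_reason = "",
      stringsAsFactors = FALSE)
  })
}
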