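# Demonstration configuration: two simulated studies totalling 2,000 lean
# cases, 4,000 obese cases and 20,000 shared unstratified controls, with a
# 50-variant panel: 10 known risk loci (per-allele ORs 1.10-1.28 at mean
# BMI — varied, as published risk loci are, so the weighted score takes
# many distinct values — each with effect modification delta = -0.05 per
# SD of BMI, so effects are larger in lean cases), 3 low-quality variants
# (info 0.45, excluded by the info
# filter), 2 rare variants (EAF 0.005, excluded by the MAF filter) and 35
# null background variants. The negative deltas accumulate into an
# effective BMI main effect of about -0.5 per SD (sum of delta * mean
# dosage); bmi_gamma is set to 0.8 so the net BMI-disease gradient is the
# conventional +0.3 per SD and both case strata stay well populated.
seed: 42
lean_max: 25
obese_min: 30
info_min: 0.5
maf_min: 0.01
genome_wide: 2.5e-8
suggestive: 5.0e-7
model: fixed
gc: true
stratify_controls: false
simulate:
  n_studies: 2
  n_individuals: 85000
  n_snps: 50
  n_known: 10
  # per-locus log-ORs, ln(1.10) .. ln(1.28)
  known_beta: [0.0953, 0.1133, 0.1310, 0.1484, 0.1655, 0.1823, 0.1989, 0.2151, 0.2311, 0.2469]
  known_delta: -0.05
  prevalence: 0.10
  bmi_mean: 27.0
  bmi_sd: 4.5
  bmi_gamma: 0.8
  n_lean_cases: 1000
  n_obese_cases: 2000
  n_controls: 10000
  low_info_index: [11, 12, 13]
  low_info_value: 0.45
  rare_index: [14, 15]
  rare_eaf: 0.005
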