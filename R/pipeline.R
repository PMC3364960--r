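# End-to-end workflow: simulate (or ingest) study data, run the two
# BMI-stratified scans with genomic control, meta-analyse per stratum,
# tier the hits, run the case-only BMI scan, the sign-enrichment test on
# the known risk loci, and the weighted genetic risk score analyses.

#' Build and validate a pipeline configuration
#'
#' Configuration may come from a YAML file (`key: value`, with nested
#' `simulate:` section) or an R list; unspecified keys take the defaults
#' below. Stratum cut-offs, QC thresholds and significance thresholds are
#' all overridable but default to the conventional values (lean < 25,
#' obese >= 30 kg/m^2; info > 0.5; MAF > 1%; genome-wide 2.5e-8,
#' suggestive 5e-7).
#'
#' @param config list of settings, or a path to a YAML file.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L,
    lean_max = 25, obese_min = 30,
    info_min = 0.5, maf_min = 0.01,
    genome_wide = 2.5e-8, suggestive = 5e-7,
    model = "fixed", gc = TRUE, stratify_controls = FALSE,
    simulate = list(
      n_studies = 1L, n_individuals = 50000L, n_snps = 20L,
      n_known = 5L, known_beta = log(1.2), known_delta = -0.1,
      prevalence = 0.10, bmi_mean = 27, bmi_sd = 4.5, bmi_gamma = 0.3,
      n_lean_cases = 500L, n_obese_cases = 1000L, n_controls = 5000L
    )
  )
  cfg <- utils::modifyList(defaults, config)
  if (!(cfg$lean_max <= cfg$obese_min)) {
    stop_bmistrat("lean_max must not exceed obese_min",
                  "bmistrat_validation_error")
  }
  for (k in c("info_min", "maf_min", "genome_wide", "suggestive")) {
    if (!(cfg[[k]] > 0 && cfg[[k]] < 1)) {
      stop_bmistrat(sprintf("%s must lie in (0, 1)", k),
                    "bmistrat_validation_error")
    }
  }
  cfg$model <- match.arg(cfg$model, c("fixed", "random"))
  structure(cfg, class = "pipeline_config")
}

#' Run the full BMI-stratified analysis pipeline
#'
#' Simulates `n_studies` cohorts (each a study with lean cases, obese
#' cases and a shared unstratified control pool), then runs, per study and
#' stratum: QC-filtered additive logistic scans, genomic control; across
#' studies: the presence rule and per-variant meta-analysis; then
#' significance tiers, per-variant lean-vs-obese heterogeneity tests, a
#' meta-analysed case-only BMI scan, the sign-enrichment test over the
#' known risk loci (panel variants with non-zero `beta_base`), and the
#' weighted risk-score analyses (per-stratum score model, quintile ORs,
#' stratum comparison and the case-vs-case model) on the first study.
#'
#' All outputs are written under `out_dir`: `meta_lean.tsv`,
#' `meta_obese.tsv`, `het_test.tsv`, `case_only_meta.tsv`, `sign_test.json`,
#' `grs.json` and `run_log.yaml` (resolved configuration, seed, package
#' version). Results are deterministic given the configuration seed.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$simulate

  # --- panel: known risk loci first, then null background -------------
  specs <- data.frame(index = seq_len(sim$n_known),
                      eaf = NA_real_,
                      beta_base = sim$known_beta,
                      delta = sim$known_delta)
  panel <- simulate_variants(sim$n_snps, effect_specs = specs,
                             seed = substream_seed(cfg$seed, "panel"))
  if (!is.null(sim$low_info_index)) {
    panel$info[sim$low_info_index] <- sim$low_info_value %||% 0.4
  }
  if (!is.null(sim$rare_index)) {
    panel$eaf[sim$rare_index] <- sim$rare_eaf %||% 0.005
  }
  known_ids <- panel$variant_id[panel$beta_base != 0]

  # --- simulate studies -----------------------------------------------
  base_cfg <- cohort_config(sim$n_individuals,
                            target_prevalence = sim$prevalence,
                            bmi_mean = sim$bmi_mean, bmi_sd = sim$bmi_sd,
                            bmi_gamma = sim$bmi_gamma, seed = cfg$seed)
  alpha <- calibrate_intercept(panel, base_cfg)
  studies <- lapply(seq_len(sim$n_studies), function(s) {
    ccfg <- base_cfg
    ccfg$seed <- substream_seed(cfg$seed, paste0("study", s))
    cohort <- simulate_cohort(panel, ccfg, alpha = alpha)
    study <- ascertain_study(cohort, sim$n_lean_cases, sim$n_obese_cases,
                             sim$n_controls,
                             seed = substream_seed(cfg$seed, paste0("ascertain", s)),
                             stratify_controls = cfg$stratify_controls,
                             lean_max = cfg$lean_max, obese_min = cfg$obese_min,
                             study_id = paste0("study", s))
    list(cohort = cohort, study = study)
  })

  # --- per-study stratified scans + genomic control -------------------
  scan_stratum <- function(stratum) {
    lapply(studies, function(st) {
      rec <- run_stratified_gwas(st$study, st$cohort, stratum = stratum,
                                 info_min = cfg$info_min, maf_min = cfg$maf_min)
      if (cfg$gc && nrow(rec)) {
        rec <- apply_genomic_control(rec, genomic_lambda(rec$chi2))
      }
      rec
    })
  }
  lean_tables <- scan_stratum("lean")
  obese_tables <- scan_stratum("obese")

  # --- meta per stratum, tiers ----------------------------------------
  meta_for <- function(tables) {
    declare_significance(
      meta_analyse_studies(tables, reference = panel, model = cfg$model,
                           k_total = sim$n_studies),
      genome_wide = cfg$genome_wide, suggestive = cfg$suggestive)
  }
  meta_lean <- meta_for(lean_tables)
  meta_obese <- meta_for(obese_tables)

  # --- per-variant lean vs obese heterogeneity ------------------------
  shared <- intersect(meta_lean$variant_id, meta_obese$variant_id)
  het <- do.call(rbind, lapply(shared, function(id) {
    l <- meta_lean[meta_lean$variant_id == id, ]
    o <- meta_obese[meta_obese$variant_id == id, ]
    h <- stratum_heterogeneity_test(l$beta_fe, l$se_fe, o$beta_fe, o$se_fe)
    data.frame(variant_id = id, beta_lean = l$beta_fe, beta_obese = o$beta_fe,
               beta_diff = h$beta_diff, se_diff = h$se_diff,
               z_het = h$z_het, p_het = h$p_het, stringsAsFactors = FALSE)
  }))

  # --- case-only BMI scan (all cases), meta-analysed ------------------
  caseonly_tables <- lapply(studies, function(st) {
    idx <- cases_for(st$study, "all")
    rec <- case_only_bmi_scan(st$cohort$genotypes[idx, , drop = FALSE],
                              st$cohort$bmi[idx], panel = st$cohort$panel)
    if (cfg$gc) {
      ok <- !is.na(rec$chi2)
      if (any(ok)) rec <- apply_genomic_control(rec, genomic_lambda(rec$chi2))
    }
    rec
  })
  meta_caseonly <- meta_analyse_studies(caseonly_tables, reference = panel,
                                        model = "fixed",
                                        k_total = sim$n_studies)

  # --- sign-enrichment over known loci --------------------------------
  known_in <- intersect(known_ids, shared)
  sign_test <- NULL
  if (length(known_in)) {
    ors <- data.frame(
      or_lean = exp(meta_lean$beta_fe[match(known_in, meta_lean$variant_id)]),
      or_obese = exp(meta_obese$beta_fe[match(known_in, meta_obese$variant_id)]))
    sign_test <- sign_enrichment_test(ors)
  }

  # --- weighted genetic risk score on study 1 -------------------------
  weights <- data.frame(
    variant_id = known_ids,
    effect_allele = panel$effect_allele[match(known_ids, panel$variant_id)],
    other_allele = panel$other_allele[match(known_ids, panel$variant_id)],
    weight = panel$beta_base[match(known_ids, panel$variant_id)],
    eaf = panel$eaf[match(known_ids, panel$variant_id)],
    stringsAsFactors = FALSE)
  grs <- NULL
  if (nrow(weights)) {
    st1 <- studies[[1L]]
    grs_stratum <- function(stratum) {
      cases <- cases_for(st1$study, stratum)
      ctrls <- controls_for(st1$study, stratum)
      idx <- c(cases, ctrls)
      sc <- weighted_allele_score(st1$cohort$genotypes[idx, , drop = FALSE],
                                  weights, panel = panel)
      y <- c(rep(1L, length(cases)), rep(0L, length(ctrls)))
      list(fit = fit_score_model(sc, y, weights),
           quintiles = quintile_ors(sc, y))
    }
    g_lean <- grs_stratum("lean")
    g_obese <- grs_stratum("obese")
    cases_l <- cases_for(st1$study, "lean")
    cases_o <- cases_for(st1$study, "obese")
    cvc_idx <- c(cases_l, cases_o)
    cvc <- score_case_vs_case(
      weighted_allele_score(st1$cohort$genotypes[cvc_idx, , drop = FALSE],
                            weights, panel = panel),
      c(rep(1L, length(cases_l)), rep(0L, length(cases_o))), weights)
    grs <- list(lean = g_lean, obese = g_obese,
                het = compare_stratum_scores(g_lean$fit, g_obese$fit),
                case_vs_case = cvc)
  }

  # --- write outputs ---------------------------------------------------
  paths <- list(
    meta_lean = file.path(out_dir, "meta_lean.tsv"),
    meta_obese = file.path(out_dir, "meta_obese.tsv"),
    het = file.path(out_dir, "het_test.tsv"),
    caseonly = file.path(out_dir, "case_only_meta.tsv"),
    sign = file.path(out_dir, "sign_test.json"),
    grs = file.path(out_dir, "grs.json"),
    log = file.path(out_dir, "run_log.yaml")
  )
  data.table::fwrite(meta_lean, paths$meta_lean, sep = "\t")
  data.table::fwrite(meta_obese, paths$meta_obese, sep = "\t")
  if (!is.null(het)) data.table::fwrite(het, paths$het, sep = "\t")
  data.table::fwrite(meta_caseonly, paths$caseonly, sep = "\t")
  if (!is.null(sign_test)) {
    jsonlite::write_json(unclass(sign_test), paths$sign, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(grs)) {
    jsonlite::write_json(
      list(lean = c(unclass(g_lean$fit),
                    list(quintiles = as.data.frame(g_lean$quintiles))),
           obese = c(unclass(g_obese$fit),
                     list(quintiles = as.data.frame(g_obese$quintiles))),
           heterogeneity = unclass(grs$het),
           case_vs_case = unclass(grs$case_vs_case)),
      paths$grs, auto_unbox = TRUE, digits = NA)
  }
  yaml::write_yaml(
    list(package_version = as.character(utils::packageVersion("bmistrat")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = cfg$seed,
         config = unclass(cfg),
         alpha = alpha),
    paths$log)

  invisible(list(config = cfg, panel = panel, alpha = alpha,
                 meta_lean = meta_lean, meta_obese = meta_obese,
                 het = het, case_only = meta_caseonly,
                 sign_test = sign_test, grs = grs, paths = paths))
}
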