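#' Run the full diagnostic pipeline end to end
#'
#' Simulates a variant cohort, a validation paired-call table and a
#' hybridization batch from the given seed (or consumes tables supplied in
#' `config`), then chains annotation, fusion calling, concordance and
#' stratification, writing every artifact plus a provenance manifest into
#' `out_dir`. Any stage error aborts with the stage name.
#'
#' @param config Named list (or path to a YAML file) with optional
#'   entries: `seed` (default 1), `n_samples` (default 200, simulated
#'   cohort size), `rules_file`, `panel_file`, `probe_file`,
#'   `thresholds` (list for [caller_thresholds()]),
#'   `exclude_out_of_scope` (default TRUE), `kras_in_actionable`
#'   (default TRUE), `t790m_actionable` (default TRUE).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  probe_file <- config$probe_file
  probes <- stage("load-probes", {
    if (is.null(probe_file)) default_probe_set() else read_probe_table(probe_file)
  })
  rules <- stage("load-rules", {
    read_actionability_rules(config$rules_file)
  })
  panel <- stage("load-panel", read_panel(config$panel_file))
  thresholds <- stage("load-thresholds", {
    do.call(caller_thresholds, config$thresholds %||% list())
  })

  sim <- stage("simulate", {
    cohort <- generate_variant_cohort(
      cohort_spec(config$n_samples %||% 200L, seed = seed))
    batch <- generate_nanostring_batch(
      prospective_fusion_batch_spec(seed = seed), probes)
    paired <- generate_paired_calls(validation_paired_call_spec(seed = seed))
    list(cohort = cohort, batch = batch, paired = paired)
  })

  annotated <- stage("annotate", {
    annotate_variants(sim$cohort$variants, rules = rules, panel = panel,
                      t790m_actionable = config$t790m_actionable %||% TRUE)
  })
  fusion <- stage("call-fusions", {
    call_batch(sim$batch$profiles, probes, thresholds)
  })
  concordance <- stage("concordance", {
    list(all = evaluate_concordance(sim$paired),
         in_scope = evaluate_concordance(
           sim$paired,
           exclude_out_of_scope = config$exclude_out_of_scope %||% TRUE),
         by_gene = tabulate_by_gene(sim$paired))
  })
  strat <- stage("stratify", {
    stratify(sim$cohort$samples, annotated, fusions = NULL,
             kras_in_actionable = config$kras_in_actionable %||% TRUE)
  })

  stage("write-outputs", {
    write_variant_table(annotated, file.path(out_dir, "variants_annotated.tsv"),
                        seed = seed)
    write_paired_call_table(sim$paired, file.path(out_dir, "paired_calls.tsv"),
                            seed = seed)
    write_count_matrix(profiles_to_matrix(sim$batch$profiles),
                       file.path(out_dir, "counts.csv"), seed = seed)
    readr::write_tsv(sim$batch$truth, file.path(out_dir, "batch_truth.tsv"))
    readr::write_tsv(sim$cohort$truth, file.path(out_dir, "cohort_truth.tsv"))
    readr::write_tsv(fusion$calls, file.path(out_dir, "fusion_calls.tsv"))
    write_report_json(fusion$summary, file.path(out_dir, "fusion_summary.json"))
    write_report_json(concordance, file.path(out_dir, "concordance.json"))
    write_report_json(strat[c("groups", "eligibility", "variant_histogram",
                              "gene_distribution")],
                      file.path(out_dir, "stratification.json"))
  })

  manifest <- list(package = "lungdx",
                   version = as.character(packageVersion("lungdx")),
                   seed = seed,
                   config_hash = rlang::hash(config),
                   n_samples = nrow(sim$cohort$samples),
                   n_profiles = length(sim$batch$profiles))
  write_report_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(sim = sim, annotated = annotated, fusion = fusion,
                 concordance = concordance, stratification = strat,
                 manifest = manifest))
}
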