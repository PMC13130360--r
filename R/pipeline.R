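#' Build a validated run configuration
#'
#' @param input a [cohort_spec()], a preset name (`"paper-like"`, `"null"`,
#'   `"high-heterogeneity"`), or a directory containing the cohort CSVs.
#' @param seed run seed (overrides the seed in a preset/spec).
#' @param harmonize logical: apply ComBat per measure class (default TRUE).
#' @param match list: `enable` (default FALSE — preset cohorts emulate an
#'   already-matched sample), `treated_groups`, `control_group`, `ratio`,
#'   `caliper`.
#' @param outlier_policy `"per-measure"` (default) or `"listwise"`.
#' @param zscore_ref `"pooled"` (default) or `"within-group"`.
#' @param fdr_family `"per-measure"` (default) or `"per-variable"`.
#' @param patient_groups groups analysed in the clinical-correlation stage.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = "paper-like", seed = 1L, harmonize = TRUE,
                       match = list(enable = FALSE),
                       outlier_policy = c("per-measure", "listwise"),
                       zscore_ref = c("pooled", "within-group"),
                       fdr_family = c("per-measure", "per-variable"),
                       patient_groups = c("recent", "chronic"),
                       out_dir = NULL) {
  structure(list(
    input = input, seed = as.integer(seed), harmonize = isTRUE(harmonize),
    match = utils::modifyList(list(enable = FALSE, control_group = "HC",
                                   ratio = 1L, caliper = Inf), match),
    outlier_policy = match.arg(outlier_policy),
    zscore_ref = match.arg(zscore_ref),
    fdr_family = match.arg(fdr_family),
    patient_groups = patient_groups,
    out_dir = out_dir), class = "run_config")
}

#' Run the full PBSI analysis pipeline
#'
#' Stage order: load/simulate -> harmonise -> match -> raw PBSI -> outlier
#' exclusion -> z-score/aggregate -> group comparison -> clinical
#' correlation -> write results. Every stage logs its input/output subject
#' counts; the manifest records the config, its hash, the seed and per-file
#' checksums. Deterministic given config + seed.
#'
#' @param config a [run_config()] (a bare preset name is accepted).
#' @param quiet suppress per-stage log messages.
#' @return list of class `pbsi_run`: `scores`, `comparison`, `correlations`,
#'   `demographics`, `cohort`, `harmonization`, `stages` (log), `config`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (is.character(config)) config <- run_config(input = config)
  stopifnot(inherits(config, "run_config"))
  stages <- list()
  note <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1L]] <<- list(stage = stage, n_in = n_in,
                                           n_out = n_out)
    if (!quiet) message(sprintf("[pbsi] %-18s in=%d out=%d", stage, n_in,
                                n_out))
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # -- load / simulate
  cohort <- tryCatch({
    inp <- config$input
    if (inherits(inp, "cohort_spec")) {
      inp$seed <- config$seed
      simulate_cohort(inp)
    } else if (is.character(inp) && dir.exists(inp)) {
      read_cohort(inp)
    } else if (is.character(inp)) {
      simulate_cohort(spec_presets(inp, seed = config$seed))
    } else stop("unrecognised input")
  }, error = function(e) fail("load", e))
  n0 <- nrow(cohort$meta)
  note("load/simulate", n0, n0)

  tables <- cohort$tables
  harmonization <- NULL
  if (config$harmonize) {
    harmonization <- tryCatch(suppressWarnings(harmonize_tables(tables)),
                              error = function(e) fail("harmonize", e))
    tables <- harmonization$tables
    note("harmonize", n0, n0)
  }

  meta <- cohort$meta
  if (isTRUE(config$match$enable)) {
    keep <- tryCatch(match_groups(
      meta,
      treated_groups = config$match$treated_groups %||% config$patient_groups,
      control_group = config$match$control_group,
      ratio = config$match$ratio, caliper = config$match$caliper,
      seed = config$seed), error = function(e) fail("match", e))
    tables <- lapply(tables, subset_subjects, subject_ids = keep)
    meta <- meta[meta$subject_id %in% keep, , drop = FALSE]
    note("match", n0, nrow(meta))
  }

  raw <- tryCatch(raw_pbsi_table(tables),
                  error = function(e) fail("pbsi_raw", e))
  note("pbsi_raw", nrow(meta), nrow(raw))

  filtered <- tryCatch(apply_outlier_policy(raw, config$outlier_policy),
                       error = function(e) fail("outliers", e))
  note("outliers", nrow(raw),
       nrow(raw) - sum(attr(filtered, "n_flagged") > 0))

  scores <- tryCatch(aggregate_pbsi(filtered, reference = config$zscore_ref),
                     error = function(e) fail("zscore", e))
  note("zscore/aggregate", nrow(filtered), nrow(scores))

  comparison <- tryCatch(compare_groups(scores, meta),
                         error = function(e) fail("compare", e))
  note("compare", nrow(scores), nrow(comparison$anova))

  correlations <- demographics <- NULL
  if (!is.null(cohort$clinical)) {
    correlations <- tryCatch(run_clinical_analysis(
      scores, cohort$clinical,
      groups = intersect(config$patient_groups, unique(scores$group)),
      family = config$fdr_family), error = function(e) fail("correlate", e))
    note("correlate", nrow(scores), nrow(correlations))
    demographics <- tryCatch(
      demographics_table(meta, cohort$clinical,
                         patient_groups = config$patient_groups),
      error = function(e) fail("demographics", e))
  }

  result <- structure(list(scores = scores, comparison = comparison,
                           correlations = correlations,
                           demographics = demographics, cohort = cohort,
                           harmonization = harmonization, stages = stages,
                           config = config), class = "pbsi_run")
  if (!is.null(config$out_dir)) {
    cfg_record <- config
    cfg_record$out_dir <- NULL  # bundle content must not depend on its path
    cfg_record$input <- if (inherits(config$input, "cohort_spec"))
      unclass(config$input) else config$input
    write_results(list(scores = scores, comparison = comparison,
                       correlations = correlations,
                       demographics = demographics),
                  config$out_dir, config = cfg_record, seed = config$seed)
    note("write", nrow(scores), nrow(scores))
    result$stages <- stages
  }
  result
}

#' @export
print.pbsi_run <- function(x, ...) {
  cat(sprintf("<pbsi_run> %d subjects, %d stages\n",
              nrow(x$cohort$meta), length(x$stages)))
  print(x$comparison)
  invisible(x)
}
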