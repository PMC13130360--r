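#' Read a wide morphometry table from CSV/TSV
#'
#' Expects one header row with `subject_id` first and one column per atlas
#' region; the delimiter (comma or tab) is sniffed from the header line.
#' Columns are reordered to canonical atlas order; a missing region column is
#' an error naming it, unknown extra region columns are dropped with a
#' warning, and any non-numeric cell is an error with its row/column
#' coordinates. Metadata is joined from the subjects table.
#'
#' @param path file to read.
#' @param measure_class one of the four measure classes.
#' @param subjects subject metadata data.frame (from [read_subjects()]) with
#'   `subject_id`, `group`, `site`, `age`, `sex`.
#' @param atlas a [region_atlas()]; default [default_atlas()].
#' @return a validated [morphometry_table()].
#' @export
read_morphometry <- function(path, measure_class, subjects,
                             atlas = default_atlas()) {
  measure_class <- match.arg(measure_class, MEASURE_CLASSES)
  df <- read_delim_sniff(path)
  if (names(df)[1] != "subject_id")
    stop("first column must be 'subject_id' in ", path, call. = FALSE)
  regions <- atlas_regions(atlas, measure_class)
  missing_regions <- setdiff(regions, names(df))
  if (length(missing_regions))
    stop(sprintf("%s: missing region column(s): %s", path,
                 paste(missing_regions, collapse = ", ")), call. = FALSE)
  feat <- df[setdiff(names(df), "subject_id")]
  for (j in seq_along(feat)) {
    v <- feat[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("%s: non-numeric cell at row %d, column '%s'",
                     path, bad[1], names(feat)[j]), call. = FALSE)
      feat[[j]] <- num
    }
  }
  values <- as.matrix(feat)
  rownames(values) <- as.character(df$subject_id)
  meta <- subjects[match(df$subject_id, subjects$subject_id), , drop = FALSE]
  if (anyNA(meta$subject_id))
    stop(sprintf("%s: subject(s) absent from the subjects table: %s", path,
                 paste(utils::head(df$subject_id[is.na(meta$subject_id)], 5),
                       collapse = ", ")), call. = FALSE)
  rownames(meta) <- NULL
  morphometry_table(measure_class, values, meta, atlas)
}

read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"")
}

#' Read subject metadata (`subjects.csv`)
#'
#' @param path CSV/TSV with columns `subject_id`, `group`, `site`, `age`,
#'   `sex` (`"M"`/`"F"`).
#' @return validated data.frame.
#' @export
read_subjects <- function(path) {
  df <- read_delim_sniff(path)
  req <- c("subject_id", "group", "site", "age", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("subjects table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id in subjects table", call. = FALSE)
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be coded 'M'/'F'", call. = FALSE)
  df
}

#' Read the clinical table (`clinical.csv`)
#'
#' @param path CSV/TSV of clinical scores (see [validate_clinical()] for the
#'   expected columns).
#' @return validated data.frame (validation warns on PANSS additivity
#'   violations in real data, it does not fail).
#' @export
read_clinical <- function(path) {
  df <- read_delim_sniff(path)
  df$subject_id <- as.character(df$subject_id)
  validate_clinical(df, warn_only = TRUE)
  df
}

#' Write a simulated cohort in the dialect the readers consume
#'
#' One wide CSV per measure class plus `subjects.csv` and `clinical.csv`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (m in names(cohort$tables)) {
    p <- file.path(out_dir, paste0(m, ".csv"))
    df <- data.frame(subject_id = rownames(cohort$tables[[m]]$values),
                     cohort$tables[[m]]$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[m] <- p
  }
  p <- file.path(out_dir, "subjects.csv")
  utils::write.csv(cohort$meta, p, row.names = FALSE, quote = FALSE)
  paths["subjects"] <- p
  p <- file.path(out_dir, "clinical.csv")
  utils::write.csv(cohort$clinical, p, row.names = FALSE, quote = FALSE)
  paths["clinical"] <- p
  invisible(paths)
}

#' Read a full cohort directory
#'
#' @param dir directory holding `thickness.csv`, `area.csv`, `volume.csv`,
#'   `subcortical.csv`, `subjects.csv`, `clinical.csv`.
#' @param atlas a [region_atlas()].
#' @return list with `tables`, `meta`, `clinical`, `atlas`.
#' @export
read_cohort <- function(dir, atlas = default_atlas()) {
  meta <- read_subjects(file.path(dir, "subjects.csv"))
  tables <- lapply(stats::setNames(MEASURE_CLASSES, MEASURE_CLASSES),
                   function(m) read_morphometry(file.path(dir,
                                                          paste0(m, ".csv")),
                                                m, meta, atlas))
  clin_path <- file.path(dir, "clinical.csv")
  clinical <- if (file.exists(clin_path)) read_clinical(clin_path) else NULL
  list(tables = tables, meta = meta, clinical = clinical, atlas = atlas)
}

#' Write the analysis report bundle
#'
#' Writes `pbsi_scores.csv`, `group_differences.csv`,
#' `clinical_correlations.csv`, `demographics.csv` and `manifest.json` (the
#' run configuration hash, seed, software version and per-file checksums) so
#' a run can be audited and reproduced. Empty results yield header-only
#' files.
#'
#' @param results named list with any of `scores`, `comparison`
#'   (a `group_comparison`), `correlations`, `demographics`.
#' @param out_dir output directory.
#' @param config run configuration recorded (and hashed) in the manifest.
#' @param seed seed recorded in the manifest.
#' @return path of the manifest, invisibly.
#' @export
write_results <- function(results, out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    written[[name]] <<- p
  }
  if (!is.null(results$scores)) emit(results$scores, "pbsi_scores.csv")
  if (!is.null(results$comparison)) {
    cmp <- results$comparison
    tk <- cmp$tukey
    names(tk)[names(tk) == "p_adj"] <- "p_tukey"
    merged <- merge(cmp$anova, cmp$regression, by = "score",
                    suffixes = c("_anova", "_reg"))
    emit(merged, "group_differences.csv")
    emit(tk, "tukey_contrasts.csv")
  }
  if (!is.null(results$correlations))
    emit(results$correlations, "clinical_correlations.csv")
  if (!is.null(results$demographics))
    emit(results$demographics, "demographics.csv")

  manifest <- list(
    package = "pbsi",
    version = as.character(utils::packageVersion("pbsi")),
    seed = seed,
    config = config,
    config_hash = object_hash(config),
    files = lapply(written, file_hash))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(mp)
}

#' Best-effort converter for FreeSurfer-style stats tables
#'
#' Renames the first column of an `aparcstats2table`/`asegstats2table`-style
#' export to `subject_id` and strips common measure suffixes
#' (`_thickness`, `_area`, `_volume`) from region columns. Header renaming
#' only — no computation, no unit conversion.
#'
#' @param df data.frame as read from a FreeSurfer table export.
#' @return data.frame in the package's wide dialect.
#' @export
convert_freesurfer_stats <- function(df) {
  names(df)[1] <- "subject_id"
  names(df) <- sub("_(thickness|area|volume)$", "", names(df))
  df
}
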