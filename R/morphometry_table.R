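#' Morphometry table: subjects x regions for one measure class
#'
#' The package's central container. `values` is a numeric matrix with one row
#' per subject (rownames = subject ids) and one column per atlas region in
#' canonical order; `meta` carries group, site, age and sex per subject.
#'
#' Validation enforces the contracts all downstream stages rely on: columns
#' exactly match the atlas list for the measure class (canonical order),
#' subject ids unique, ages positive, group/site complete, all morphometric
#' values strictly positive and finite.
#'
#' @param measure_class one of `"thickness"`, `"area"`, `"volume"`,
#'   `"subcortical"`.
#' @param values numeric matrix, subjects x regions, rownames = subject ids.
#' @param meta data.frame with columns `subject_id`, `group`, `site`, `age`,
#'   `sex` (levels `"M"`/`"F"`), one row per subject, same order as `values`.
#' @param atlas a [region_atlas()]; defaults to [default_atlas()].
#' @return object of class `morph_table`.
#' @export
morphometry_table <- function(measure_class, values, meta,
                              atlas = default_atlas()) {
  measure_class <- match.arg(measure_class, MEASURE_CLASSES)
  regions <- atlas_regions(atlas, measure_class)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("values matrix must carry region column names", call. = FALSE)

  missing_regions <- setdiff(regions, colnames(values))
  if (length(missing_regions))
    stop(sprintf("missing region column(s) for measure class '%s': %s",
                 measure_class, paste(missing_regions, collapse = ", ")),
         call. = FALSE)
  extra <- setdiff(colnames(values), regions)
  if (length(extra)) {
    warning(sprintf("dropping %d unknown region column(s): %s",
                    length(extra), paste(utils::head(extra, 5), collapse = ", ")),
            call. = FALSE)
  }
  values <- values[, regions, drop = FALSE]  # canonical order

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "site", "age", "sex")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta$subject_id <- as.character(meta$subject_id)
  if (nrow(meta) != nrow(values))
    stop("metadata and values disagree on subject count", call. = FALSE)
  if (anyDuplicated(meta$subject_id))
    stop("duplicated subject_id in metadata", call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- meta$subject_id
  if (!identical(rownames(values), meta$subject_id))
    stop("values rownames do not match metadata subject_id order",
         call. = FALSE)
  if (anyNA(meta$group) || anyNA(meta$site))
    stop("missing group or site label", call. = FALSE)
  if (anyNA(meta$age) || any(meta$age <= 0))
    stop("ages must be present and > 0", call. = FALSE)
  if (!all(meta$sex %in% c("M", "F")))
    stop("sex must be coded 'M'/'F'", call. = FALSE)

  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("morphometric values must be numeric and finite", call. = FALSE)
  if (any(values <= 0))
    stop(sprintf("non-positive morphometric value(s) in measure class '%s'",
                 measure_class), call. = FALSE)

  structure(list(measure_class = measure_class, values = values, meta = meta),
            class = "morph_table")
}

#' @export
print.morph_table <- function(x, ...) {
  cat(sprintf("<morph_table> %s: %d subjects x %d regions; groups: %s\n",
              x$measure_class, nrow(x$values), ncol(x$values),
              paste(sort(unique(x$meta$group)), collapse = ", ")))
  invisible(x)
}

#' Subset a morphometry table by subject ids
#'
#' @param table a `morph_table`.
#' @param subject_ids ids to retain (order preserved as given).
#' @return a `morph_table` restricted to those subjects.
#' @export
subset_subjects <- function(table, subject_ids) {
  stopifnot(inherits(table, "morph_table"))
  subject_ids <- as.character(subject_ids)
  missing <- setdiff(subject_ids, table$meta$subject_id)
  if (length(missing))
    stop("unknown subject_id(s): ", paste(utils::head(missing, 5),
                                          collapse = ", "), call. = FALSE)
  idx <- match(subject_ids, table$meta$subject_id)
  out <- table
  out$values <- table$values[idx, , drop = FALSE]
  out$meta <- table$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

# Internal: F = 1 indicator used by every model that adjusts for sex.
sex_indicator <- function(sex) as.numeric(sex == "F")
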