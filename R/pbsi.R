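#' Spearman rank correlation between two regional profiles
#'
#' The similarity primitive of the whole package: values are converted to
#' average ("fractional") ranks and the Pearson correlation of the ranks is
#' returned, so heavily tied integer-valued inputs are handled exactly.
#' Symmetric in its arguments and always in `[-1, 1]`.
#'
#' @param a,b numeric vectors of equal length >= 3 (one subject's regional
#'   profile each, in canonical atlas order), no missing values, neither
#'   constant.
#' @return Spearman's rho.
#' @examples
#' spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b))
    stop("profiles differ in length", call. = FALSE)
  if (length(a) < 3L)
    stop("profiles must have length >= 3", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("profiles must not contain missing values", call. = FALSE)
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  rank_pearson(ra, rb)
}

# Pearson correlation of two rank vectors by explicit centring; errors on
# constant input (zero rank variance makes the correlation undefined).
rank_pearson <- function(ra, rb) {
  ca <- ra - mean(ra)
  cb <- rb - mean(rb)
  va <- sum(ca^2)
  vb <- sum(cb^2)
  if (va == 0 || vb == 0)
    stop("constant profile: rank correlation undefined", call. = FALSE)
  r <- sum(ca * cb) / sqrt(va * vb)
  min(1, max(-1, r))
}

#' Raw PBSI for one subject within a group
#'
#' The mean of the `n - 1` Spearman correlations between the indexed
#' subject's profile and every other member of the same diagnostic group.
#' Lower values mean the subject's regional profile is less like its peers' —
#' greater inter-individual heterogeneity.
#'
#' @param profiles numeric matrix (subjects x regions) or list of equal-length
#'   numeric vectors: the profiles of one group in one measure class.
#' @param index row position of the subject to score.
#' @return mean Spearman rho, in `[-1, 1]`.
#' @export
pbsi_raw <- function(profiles, index) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  n <- nrow(profiles)
  if (n < 3L)
    stop("group too small: PBSI needs >= 3 members (>= 2 correlations)",
         call. = FALSE)
  if (index < 1L || index > n) stop("index out of range", call. = FALSE)
  rhos <- vapply(setdiff(seq_len(n), index), function(j) {
    spearman_rho(profiles[index, ], profiles[j, ])
  }, numeric(1))
  mean(rhos)
}

# Full Spearman correlation matrix of subject profiles (rows) via ranks +
# centred crossproduct; identical tie handling to spearman_rho. The per-pair
# function and this matrix path are cross-checked in the test suite.
spearman_matrix <- function(profiles) {
  ranks <- t(apply(profiles, 1L, rank, ties.method = "average"))
  z <- ranks - rowMeans(ranks)
  v <- rowSums(z^2)
  if (any(v == 0))
    stop(sprintf("constant profile for subject(s): %s",
                 paste(rownames(profiles)[v == 0], collapse = ", ")),
         call. = FALSE)
  s <- tcrossprod(z)
  r <- s / sqrt(outer(v, v))
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Compute PBSI scores for a cohort
#'
#' For every measure class, every subject is correlated (Spearman) with all
#' other members of the *same diagnostic group* and the mean of the `n - 1`
#' coefficients is the subject's raw PBSI for that class. Raw scores are then
#' z-scored and aggregated into Cortical (thickness + area + volume) and
#' Total (all four classes) composites via [aggregate_pbsi()].
#'
#' Raw scores for a group depend only on that group's data (within-group
#' locality); z-scores depend on the chosen reference population.
#'
#' @param tables named list of [morphometry_table()] objects, one per measure
#'   class (`thickness`, `area`, `volume`, `subcortical`).
#' @param zscore_ref `"pooled"` (default: all analysed subjects form the
#'   z-scoring reference, keeping groups on a common scale) or
#'   `"within-group"`.
#' @param min_group_size smallest admissible group (default 3: at least two
#'   correlations per subject).
#' @return data.frame of class `pbsi_scores`: `subject_id`, `group`,
#'   `raw_<class>` for the four classes, `z_<class>`, `z_cortical`,
#'   `z_total`.
#' @export
compute_pbsi <- function(tables, zscore_ref = c("pooled", "within-group"),
                         min_group_size = 3L) {
  zscore_ref <- match.arg(zscore_ref)
  miss <- setdiff(MEASURE_CLASSES, names(tables))
  if (length(miss))
    stop("missing measure class table(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  raw <- raw_pbsi_table(tables, min_group_size = min_group_size)
  aggregate_pbsi(raw, reference = zscore_ref)
}

#' Raw (un-standardized) PBSI scores per measure class
#'
#' @inheritParams compute_pbsi
#' @return data.frame with `subject_id`, `group`, and `raw_<class>` columns
#'   (NA where the subject was excluded from a class).
#' @export
raw_pbsi_table <- function(tables, min_group_size = 3L) {
  base <- NULL
  for (m in intersect(MEASURE_CLASSES, names(tables))) {
    tab <- tables[[m]]
    stopifnot(inherits(tab, "morph_table"))
    vals <- tab$values
    keep <- !apply(vals, 1L, anyNA)
    if (any(!keep))
      warning(sprintf("%s: excluding %d subject(s) with missing regions",
                      m, sum(!keep)), call. = FALSE)
    vals <- vals[keep, , drop = FALSE]
    meta <- tab$meta[keep, , drop = FALSE]
    scores <- rep(NA_real_, nrow(vals))
    for (g in unique(meta$group)) {
      idx <- which(meta$group == g)
      if (length(idx) < min_group_size)
        stop(sprintf("group '%s' too small in measure class %s (n = %d < %d)",
                     g, m, length(idx), min_group_size), call. = FALSE)
      rho <- spearman_matrix(vals[idx, , drop = FALSE])
      scores[idx] <- (rowSums(rho) - diag(rho)) / (length(idx) - 1)
    }
    part <- data.frame(subject_id = meta$subject_id, group = meta$group,
                       stringsAsFactors = FALSE)
    part[[paste0("raw_", m)]] <- scores
    base <- if (is.null(base)) part else
      merge(base, part, by = c("subject_id", "group"), all = TRUE)
  }
  base[order(base$subject_id), , drop = FALSE]
}

#' z-score raw PBSI values and build the Cortical and Total composites
#'
#' Each raw measure-class score is standardized against the reference
#' population; the Cortical composite is the mean of the three cortical
#' z-scores and the Total composite the mean of all four, each re-standardized
#' against the same reference so every reported column has reference mean 0
#' and SD 1.
#'
#' @param raw data.frame with `subject_id`, `group` and `raw_<class>` columns
#'   (as from [raw_pbsi_table()]).
#' @param reference `"pooled"` or `"within-group"` z-scoring population.
#' @return `pbsi_scores` data.frame with raw, z, and composite columns.
#' @export
aggregate_pbsi <- function(raw, reference = c("pooled", "within-group")) {
  reference <- match.arg(reference)
  raw_cols <- paste0("raw_", MEASURE_CLASSES)
  miss <- setdiff(raw_cols, names(raw))
  if (length(miss))
    stop("raw scores missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- raw
  zs <- function(x, grp) {
    z <- rep(NA_real_, length(x))
    if (reference == "pooled") {
      ok <- !is.na(x)
      z[ok] <- zscore_against(x[ok], label = "PBSI z-scoring")
    } else {
      for (g in unique(grp)) {
        ok <- grp == g & !is.na(x)
        z[ok] <- zscore_against(x[ok], label = sprintf("group %s", g))
      }
    }
    z
  }
  for (m in MEASURE_CLASSES)
    out[[paste0("z_", m)]] <- zs(out[[paste0("raw_", m)]], out$group)
  cort <- rowMeans(as.matrix(out[paste0("z_", CORTICAL_CLASSES)]))
  tot <- rowMeans(as.matrix(out[paste0("z_", MEASURE_CLASSES)]))
  out$z_cortical <- zs(cort, out$group)
  out$z_total <- zs(tot, out$group)
  class(out) <- c("pbsi_scores", "data.frame")
  out
}

# Reported score columns, in the order group-comparison tables use.
PBSI_SCORE_COLUMNS <- c("z_thickness", "z_area", "z_volume", "z_subcortical",
                        "z_cortical", "z_total")
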