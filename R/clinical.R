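#' Pearson correlation with two-sided p from the t transform
#'
#' Pairwise-complete: rows where either vector is missing are dropped.
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return list: `r`, `p`, `n` (pairwise-complete sample size).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need >= 4 pairwise-complete observations", call. = FALSE)
  cx <- x - mean(x)
  cy <- y - mean(y)
  vx <- sum(cx^2); vy <- sum(cy^2)
  if (vx == 0 || vy == 0) stop("constant input", call. = FALSE)
  r <- sum(cx * cy) / sqrt(vx * vy)
  r <- min(1, max(-1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorted p-values are multiplied by `m / rank`, monotonicity is enforced by
#' a cumulative minimum from the largest rank down, values are capped at 1,
#' and the original order is restored. Invariant to the input order of the
#' family; adjusted values never fall below the raw ones.
#'
#' @param p numeric vector of p-values in `[0, 1]` (one test family).
#' @return adjusted p-values, same order as input.
#' @export
fdr_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  # guard the adjusted >= raw invariant against 1-ulp rounding in p*m/rank
  pmax(out, p)
}

# The paper-defined seven-variable clinical family.
CLINICAL_FAMILY <- c(panss_positive = "PANSS positive",
                     panss_negative = "PANSS negative",
                     panss_general = "PANSS general",
                     panss_total = "PANSS total",
                     fsiq = "IQ", mq = "MQ", gaf = "GAF")

#' Clinical correlations of PBSI scores with FDR control
#'
#' Within each patient group, each PBSI score column is Pearson-correlated
#' with the seven clinical variables (PANSS positive/negative/general/total,
#' IQ, MQ, GAF), pairwise-complete. The FDR family is the seven tests for
#' one PBSI measure within one group ("seven comparisons"), adjusted by
#' Benjamini-Hochberg; optionally the family can instead span the PBSI
#' score columns within one clinical variable.
#'
#' @param scores `pbsi_scores` data.frame.
#' @param clinical clinical table with the seven variables.
#' @param groups patient group labels to analyse (each separately).
#' @param score_cols PBSI columns to correlate (default the six reported
#'   ones).
#' @param family `"per-measure"` (default: 7 clinical variables per measure)
#'   or `"per-variable"` (the score columns per clinical variable).
#' @param min_n minimum pairwise-complete n for a correlation (pairs below
#'   it are reported with NA).
#' @return data.frame of class `clinical_correlations`: `group`,
#'   `pbsi_measure`, `clinical_variable`, `n`, `r`, `p_raw`, `p_fdr`.
#' @export
run_clinical_analysis <- function(scores, clinical,
                                  groups = c("recent", "chronic"),
                                  score_cols = intersect(PBSI_SCORE_COLUMNS,
                                                         names(scores)),
                                  family = c("per-measure", "per-variable"),
                                  min_n = 4L) {
  family <- match.arg(family)
  miss_g <- setdiff(groups, unique(scores$group))
  if (length(miss_g))
    stop("group(s) absent from scores: ", paste(miss_g, collapse = ", "),
         call. = FALSE)
  dat <- merge(scores, clinical, by = "subject_id")
  out <- NULL
  for (g in groups) {
    sub <- dat[dat$group == g, , drop = FALSE]
    for (col in score_cols) {
      for (v in names(CLINICAL_FAMILY)) {
        ok <- !is.na(sub[[col]]) & !is.na(sub[[v]])
        if (sum(ok) >= min_n && stats::sd(sub[[v]][ok]) > 0 &&
            stats::sd(sub[[col]][ok]) > 0) {
          pc <- pearson_corr(sub[[col]], sub[[v]])
          row <- data.frame(group = g, pbsi_measure = col,
                            clinical_variable = CLINICAL_FAMILY[[v]],
                            n = pc$n, r = pc$r, p_raw = pc$p,
                            stringsAsFactors = FALSE)
        } else {
          row <- data.frame(group = g, pbsi_measure = col,
                            clinical_variable = CLINICAL_FAMILY[[v]],
                            n = sum(ok), r = NA_real_, p_raw = NA_real_,
                            stringsAsFactors = FALSE)
        }
        out <- rbind(out, row)
      }
    }
  }
  out$p_fdr <- NA_real_
  key <- if (family == "per-measure")
    interaction(out$group, out$pbsi_measure, drop = TRUE)
  else
    interaction(out$group, out$clinical_variable, drop = TRUE)
  for (fam in levels(key)) {
    idx <- which(key == fam & !is.na(out$p_raw))
    if (length(idx)) out$p_fdr[idx] <- fdr_adjust(out$p_raw[idx])
  }
  class(out) <- c("clinical_correlations", "data.frame")
  out
}
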