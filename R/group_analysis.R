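#' Flag outliers by the 1.5 x IQR boxplot criterion
#'
#' Values outside `[Q1 - 1.5*IQR, Q3 + 1.5*IQR]` are flagged; quartiles use
#' linear interpolation between order statistics (type 7). The closed
#' interval means that with zero IQR (all values equal) nothing is flagged.
#' Fences are equivariant under affine transforms with positive scale, so
#' flagging does not depend on units.
#'
#' @param values numeric vector (one group, one score); length >= 4.
#' @param k fence multiplier (default 1.5).
#' @return logical mask, `TRUE` = retained.
#' @export
exclude_outliers <- function(values, k = 1.5) {
  ok <- !is.na(values)
  if (sum(ok) < 4L)
    stop("need >= 4 non-missing values to estimate quartiles", call. = FALSE)
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - k * iqr & values <= q[2] + k * iqr
  keep[!ok] <- NA
  keep
}

# Apply per-group, per-measure outlier exclusion to a pbsi_scores frame on
# the raw scores; flagged entries become NA in both raw and (later) z columns
# for that measure only (per-measure policy), or the whole row (listwise).
apply_outlier_policy <- function(raw, policy = c("per-measure", "listwise"),
                                 k = 1.5) {
  policy <- match.arg(policy)
  flagged <- matrix(FALSE, nrow(raw), length(MEASURE_CLASSES),
                    dimnames = list(NULL, MEASURE_CLASSES))
  for (m in MEASURE_CLASSES) {
    col <- paste0("raw_", m)
    for (g in unique(raw$group)) {
      idx <- which(raw$group == g)
      keep <- exclude_outliers(raw[[col]][idx], k = k)
      flagged[idx[!is.na(keep) & !keep], m] <- TRUE
    }
  }
  if (policy == "listwise") {
    drop_rows <- rowSums(flagged) > 0
    flagged[drop_rows, ] <- TRUE
  }
  for (m in MEASURE_CLASSES)
    raw[[paste0("raw_", m)]][flagged[, m]] <- NA
  attr(raw, "n_flagged") <- colSums(flagged)
  raw
}

#' Age/sex matching between patient and control pools
#'
#' Greedy nearest-neighbour matching on age, without replacement, within
#' exact sex strata: within each stratum the globally closest patient-control
#' pair is matched first, both members are removed, and the process repeats.
#' Distance ties are broken by a seed-determined random order, so the result
#' is deterministic given the seed. A sex stratum present in only one pool is
#' skipped with a warning.
#'
#' @param metadata data.frame with `subject_id`, `group`, `age`, `sex`.
#' @param treated_groups group labels forming the patient pool.
#' @param control_group label of the control pool.
#' @param ratio controls matched per patient (default 1).
#' @param caliper maximum admissible age distance in years (default `Inf`).
#' @param seed integer seed for tie-breaking.
#' @return character vector of retained subject ids (matched members of both
#'   pools).
#' @export
match_groups <- function(metadata, treated_groups, control_group = "HC",
                         ratio = 1L, caliper = Inf, seed = 1L) {
  stopifnot(all(c("subject_id", "group", "age", "sex") %in% names(metadata)))
  treated <- metadata[metadata$group %in% treated_groups, , drop = FALSE]
  control <- metadata[metadata$group == control_group, , drop = FALSE]
  if (!nrow(treated) || !nrow(control))
    stop("both pools must be non-empty", call. = FALSE)
  set.seed(as.integer(seed))
  keep <- character(0)
  for (s in union(unique(treated$sex), unique(control$sex))) {
    tr <- treated[treated$sex == s, , drop = FALSE]
    co <- control[control$sex == s, , drop = FALSE]
    if (!nrow(tr) || !nrow(co)) {
      warning(sprintf("sex stratum '%s' empty on one side: skipped", s),
              call. = FALSE)
      next
    }
    # random jitter of order for deterministic tie-breaking
    tr <- tr[sample.int(nrow(tr)), , drop = FALSE]
    co <- co[sample.int(nrow(co)), , drop = FALSE]
    d <- abs(outer(tr$age, co$age, `-`))
    quota <- rep(as.integer(ratio), nrow(tr))
    used_co <- rep(FALSE, nrow(co))
    matched_tr <- rep(FALSE, nrow(tr))
    repeat {
      d_open <- d
      d_open[quota == 0L, ] <- Inf
      d_open[, used_co] <- Inf
      if (!any(is.finite(d_open)) || min(d_open) > caliper) break
      pick <- which(d_open == min(d_open), arr.ind = TRUE)[1, ]
      quota[pick[1]] <- quota[pick[1]] - 1L
      used_co[pick[2]] <- TRUE
      matched_tr[pick[1]] <- TRUE
      keep <- c(keep, co$subject_id[pick[2]])
    }
    keep <- c(keep, tr$subject_id[matched_tr])
  }
  metadata$subject_id[metadata$subject_id %in% keep]
}

#' Tukey-Kramer honestly-significant-difference pairwise comparisons
#'
#' All-pairs comparisons after a one-way layout, using the studentized-range
#' distribution with the Kramer correction for unequal group sizes:
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, adjusted
#' `p = P(Q_{k, df} > q)`. At `k = 2` this reduces exactly to the two-sample
#' pooled t-test.
#'
#' @param values numeric response.
#' @param groups group factor/character of the same length.
#' @return data.frame: `group1`, `group2`, `diff` (mean of group2 minus mean
#'   of group1), `se`, `q`, `p_adj`, plus attributes `F`, `df`, `p_anova`.
#' @export
tukey_kramer <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(as.character(groups[ok]))
  k <- nlevels(groups)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  n <- tapply(values, groups, length)
  if (any(n < 2L)) stop("every group needs >= 2 observations", call. = FALSE)
  m <- tapply(values, groups, mean)
  df <- length(values) - k
  sse <- sum((values - m[groups])^2)
  mse <- sse / df
  ssb <- sum(n * (m - mean(values))^2)
  f <- (ssb / (k - 1)) / mse
  p_anova <- stats::pf(f, k - 1, df, lower.tail = FALSE)

  pairs <- utils::combn(levels(groups), 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    stringsAsFactors = FALSE)
  res$diff <- as.numeric(m[res$group2] - m[res$group1])
  res$se <- as.numeric(sqrt(mse / 2 * (1 / n[res$group1] + 1 / n[res$group2])))
  res$q <- abs(res$diff) / res$se
  res$p_adj <- stats::ptukey(res$q, nmeans = k, df = df, lower.tail = FALSE)
  rownames(res) <- NULL
  attr(res, "F") <- unname(f)
  attr(res, "df") <- c(k - 1, df)
  attr(res, "p_anova") <- unname(p_anova)
  res
}

#' Group comparison of PBSI scores
#'
#' For each PBSI score column: (i) ordinary least squares of the score on
#' group indicators (control group as reference, treatment coding) plus age
#' and sex; (ii) one-way ANOVA across the groups on the (outlier-filtered)
#' scores, without covariate adjustment, as a companion test; (iii)
#' Tukey-Kramer adjusted pairwise comparisons.
#'
#' @param scores a `pbsi_scores` data.frame (see [compute_pbsi()]).
#' @param metadata data.frame with `subject_id`, `age`, `sex`.
#' @param score_cols score columns to analyse (default the six reported PBSI
#'   columns).
#' @param reference_group reference level for the regression (default
#'   `"HC"` when present).
#' @return list of class `group_comparison`: `regression` (per score x group
#'   coefficient: estimate, se, t, p), `anova` (per score: F, df, p),
#'   `tukey` (per score x pair), `n_retained` (per score x group).
#' @export
compare_groups <- function(scores, metadata,
                           score_cols = intersect(PBSI_SCORE_COLUMNS,
                                                  names(scores)),
                           reference_group = NULL) {
  dat <- merge(scores, metadata[c("subject_id", "age", "sex")],
               by = "subject_id")
  groups <- unique(dat$group)
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  reference_group <- reference_group %||%
    (if ("HC" %in% groups) "HC" else sort(groups)[1])
  dat$group <- factor(dat$group,
                      levels = c(reference_group,
                                 sort(setdiff(groups, reference_group))))
  dat$sexF <- sex_indicator(dat$sex)

  reg <- anv <- tk <- nret <- NULL
  for (col in score_cols) {
    sub <- dat[!is.na(dat[[col]]), , drop = FALSE]
    if (any(table(sub$group) == 0L)) stop("empty group for ", col,
                                          call. = FALSE)
    fit <- stats::lm(stats::reformulate(c("group", "age", "sexF"),
                                        response = col), data = sub)
    cf <- summary(fit)$coefficients
    grp_rows <- grep("^group", rownames(cf))
    reg <- rbind(reg, data.frame(
      score = col,
      contrast = sub("^group", "", rownames(cf)[grp_rows]),
      estimate = cf[grp_rows, 1], se = cf[grp_rows, 2],
      t = cf[grp_rows, 3], p = cf[grp_rows, 4],
      row.names = NULL, stringsAsFactors = FALSE))

    th <- tukey_kramer(sub[[col]], sub$group)
    anv <- rbind(anv, data.frame(
      score = col, F = attr(th, "F"), df1 = attr(th, "df")[1],
      df2 = attr(th, "df")[2], p = attr(th, "p_anova"),
      stringsAsFactors = FALSE))
    th$score <- col
    tk <- rbind(tk, th)

    cnt <- table(sub$group)
    nret <- rbind(nret, data.frame(score = col, group = names(cnt),
                                   n = as.integer(cnt),
                                   stringsAsFactors = FALSE))
  }
  structure(list(regression = reg, anova = anv,
                 tukey = tk[c("score", setdiff(names(tk), "score"))],
                 n_retained = nret, reference_group = reference_group),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d scores, reference group '%s'\n",
              nrow(x$anova), x$reference_group))
  print(x$anova, ...)
  invisible(x)
}

#' Demographics and clinical summary with group tests
#'
#' Means +/- SD per group for continuous variables with one-way ANOVA when
#' all three groups carry the variable and a two-sample Welch t-test when
#' only the two patient groups do (illness duration, antipsychotic dose), and
#' a chi-square test for sex.
#'
#' @param metadata subject metadata (`group`, `age`, `sex`).
#' @param clinical clinical table joined on `subject_id`.
#' @param patient_groups the two patient labels for two-group tests.
#' @return data.frame: variable, per-group `mean (sd)` summaries, test name,
#'   statistic, p.
#' @export
demographics_table <- function(metadata, clinical,
                               patient_groups = c("recent", "chronic")) {
  dat <- merge(metadata, clinical, by = "subject_id")
  groups <- unique(dat$group)
  fmt <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  rows <- list()
  cont <- c(age = "age", gaf = "gaf", fsiq = "fsiq", mq = "mq",
            panss_total = "panss_total", illness_duration = "illness_duration",
            antipsychotic_dose = "antipsychotic_dose")
  for (v in cont) {
    per_group <- vapply(groups, function(g) {
      x <- dat[[v]][dat$group == g]
      if (all(is.na(x))) "-" else fmt(x)
    }, character(1))
    has <- vapply(groups, function(g) any(!is.na(dat[[v]][dat$group == g])),
                  logical(1))
    present <- groups[has]
    if (length(present) >= 3L) {
      sub <- dat[!is.na(dat[[v]]), ]
      th <- tukey_kramer(sub[[v]], sub$group)
      test <- "anova"; statistic <- attr(th, "F"); p <- attr(th, "p_anova")
    } else if (setequal(present, intersect(patient_groups, groups)) &&
               length(present) == 2L) {
      tt <- stats::t.test(dat[[v]][dat$group == present[1]],
                          dat[[v]][dat$group == present[2]])
      test <- "t-test"; statistic <- unname(tt$statistic); p <- tt$p.value
    } else {
      test <- NA_character_; statistic <- NA_real_; p <- NA_real_
    }
    rows[[v]] <- data.frame(variable = v,
                            t(per_group), test = test,
                            statistic = statistic, p = p,
                            stringsAsFactors = FALSE)
  }
  sex_tab <- table(dat$group, dat$sex)
  cs <- suppressWarnings(stats::chisq.test(sex_tab, correct = FALSE))
  sex_row <- data.frame(variable = "sex_female",
                        t(vapply(groups, function(g) {
                          sprintf("%d/%d F", sum(dat$sex[dat$group == g] == "F"),
                                  sum(dat$group == g))
                        }, character(1))),
                        test = "chi-square",
                        statistic = unname(cs$statistic), p = cs$p.value,
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(sex_row)))
  names(out)[2:(1 + length(groups))] <- groups
  rownames(out) <- NULL
  out
}

#' Chi-square test statistic from an observed contingency table
#'
#' Plain Pearson chi-square without continuity correction; exposed so the
#' demographics test can be audited against a hand-summed
#' `(O - E)^2 / E` computation.
#'
#' @param observed contingency table (matrix).
#' @return list: `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(observed) {
  observed <- as.matrix(observed)
  expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  stat <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Assign recent-onset vs chronic from illness duration
#'
#' The five-year operational split: duration <= 5 years is recent-onset,
#' > 5 years chronic.
#'
#' @param duration_years numeric vector of illness durations.
#' @param threshold split point in years (default 5).
#' @return character vector `"recent"` / `"chronic"` (NA preserved).
#' @export
classify_onset <- function(duration_years, threshold = 5) {
  ifelse(is.na(duration_years), NA_character_,
         ifelse(duration_years <= threshold, "recent", "chronic"))
}
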