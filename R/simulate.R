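#' Simulate a multi-site, multi-group morphometry cohort
#'
#' Generates one morphometry table per measure class plus subject metadata and
#' a clinical table, with the statistical structure the PBSI analysis assumes:
#'
#' * subject values: `(mu_r + sigma_g * tau_r * d_sr) * scale_br + shift_br +
#'   eps`, with `d_sr` standard-normal subject deviations (i.i.d. across
#'   regions, optionally mixed with a shared low-rank factor), `sigma_g` the
#'   group dispersion multiplier, site batch effects `scale`/`shift`, and
#'   measurement noise `eps ~ N(0, (noise_sd * mu_r)^2)`;
#' * values are clipped at 1% of the region mean (physically positive
#'   measures; the floor is far in the tail so rank statistics are intact);
#' * PANSS totals: group baseline `+ k * (RMS(d_s) - 1) +` noise, where
#'   `d_s` is the subject's deviation vector for the coupling measure class —
#'   subjects with more deviant structural profiles score higher when `k > 0`;
#' * subscales split the total with PANSS item-count weights (7/7/16 of 30)
#'   and always sum exactly to the stored total.
#'
#' Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `tables` (named list of [morphometry_table()]
#'   per measure class), `meta` (subject metadata data.frame), `clinical`
#'   (clinical scores data.frame), `rms_deviation` (subjects x measure-class
#'   matrix of RMS deviation magnitudes, the generator's ground truth),
#'   `atlas`, and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  spec <- fill_spec_defaults(validate_cohort_spec(spec))
  set.seed(as.integer(spec$seed))

  atlas <- simulation_atlas(spec$n_cortical, spec$n_subcortical)
  groups <- names(spec$group_sizes)
  n <- sum(spec$group_sizes)
  group <- rep(groups, times = as.integer(spec$group_sizes))
  site <- unlist(lapply(groups, function(g) {
    cnt <- spec$site_assignment[[g]]
    rep(names(cnt), times = as.integer(cnt))
  }), use.names = FALSE)
  subject_id <- sprintf("S%04d", seq_len(n))

  cv <- spec$covariate_ranges
  age <- rtnorm(n, cv$age_mean %||% mean(cv$age), cv$age_sd %||% 5,
                cv$age[1], cv$age[2])
  sex <- ifelse(stats::runif(n) < (cv$sex_prop_f %||% 0.5), "F", "M")
  meta <- data.frame(subject_id = subject_id, group = group, site = site,
                     age = round(age, 1), sex = sex,
                     stringsAsFactors = FALSE)

  sigma <- spec$heterogeneity[group]
  w <- spec$factor_weight
  rms <- matrix(NA_real_, n, length(MEASURE_CLASSES),
                dimnames = list(subject_id, MEASURE_CLASSES))
  tables <- stats::setNames(vector("list", length(MEASURE_CLASSES)),
                            MEASURE_CLASSES)
  for (m in MEASURE_CLASSES) {
    mu <- spec$region_means[[m]]
    tau <- spec$region_scales[[m]]
    p <- length(mu)
    d <- matrix(stats::rnorm(n * p), n, p)
    if (w > 0) {
      f <- stats::rnorm(n)
      d <- sqrt(1 - w^2) * d + w * f  # shared factor across regions
    }
    rms[, m] <- sqrt(rowMeans(d^2))
    vals <- sweep(d * sigma, 2L, tau, `*`)
    vals <- sweep(vals, 2L, mu, `+`)
    # per-site batch effects
    for (s in unique(site)) {
      eff <- spec$site_effects[[s]][[m]] %||% list(shift = 0, scale = 1)
      idx <- site == s
      vals[idx, ] <- sweep(vals[idx, , drop = FALSE], 2L,
                           rep_len(eff$scale %||% 1, p), `*`)
      vals[idx, ] <- sweep(vals[idx, , drop = FALSE], 2L,
                           rep_len(eff$shift %||% 0, p), `+`)
    }
    if (spec$noise_sd > 0) {
      eps <- matrix(stats::rnorm(n * p), n, p)
      vals <- vals + sweep(eps, 2L, spec$noise_sd * mu, `*`)
    }
    vals <- pmax(vals, matrix(0.01 * mu, n, p, byrow = TRUE))
    dimnames(vals) <- list(subject_id, atlas_regions(atlas, m))
    tables[[m]] <- morphometry_table(m, vals, meta, atlas)
  }

  clinical <- simulate_clinical(spec, meta, rms)
  list(tables = tables, meta = meta, clinical = clinical,
       rms_deviation = rms, atlas = atlas, spec = spec)
}

simulation_atlas <- function(n_cortical, n_subcortical) {
  if (n_cortical == 100L && n_subcortical == 14L) return(default_atlas())
  region_atlas(sprintf("CTX_%03d", seq_len(n_cortical)),
               sprintf("SUB_%02d", seq_len(n_subcortical)))
}

# PANSS subscale weights: item counts 7 (positive), 7 (negative), 16 (general).
PANSS_WEIGHTS <- c(positive = 7, negative = 7, general = 16) / 30
PANSS_FLOORS <- c(positive = 7, negative = 7, general = 16)

simulate_clinical <- function(spec, meta, rms) {
  n <- nrow(meta)
  cc <- spec$clinical_coupling
  dev <- rms[, cc$measure]
  out <- data.frame(subject_id = meta$subject_id, stringsAsFactors = FALSE)
  pp <- spec$clinical_params
  num <- function(field, default) {
    vapply(meta$group, function(g) (pp[[g]][[field]] %||% default)[1],
           numeric(1))
  }
  sdv <- function(field, default) {
    vapply(meta$group, function(g) (pp[[g]][[field]] %||% default)[2],
           numeric(1))
  }
  is_patient <- vapply(meta$group, function(g) isTRUE(pp[[g]]$patient),
                       logical(1))

  total_latent <- num("panss_total", c(62.6, 16.2)) +
    cc$k * (dev - 1) + stats::rnorm(n, 0, cc$noise_sd)
  total_latent <- pmax(total_latent, 30)
  sub <- sapply(names(PANSS_WEIGHTS), function(s) {
    pmax(round(PANSS_WEIGHTS[[s]] * total_latent + stats::rnorm(n, 0, 1.5)),
         PANSS_FLOORS[[s]])
  })
  out$panss_positive <- ifelse(is_patient, sub[, "positive"], NA_real_)
  out$panss_negative <- ifelse(is_patient, sub[, "negative"], NA_real_)
  out$panss_general <- ifelse(is_patient, sub[, "general"], NA_real_)
  out$panss_total <- out$panss_positive + out$panss_negative +
    out$panss_general

  out$gaf <- pmin(pmax(round(stats::rnorm(n, num("gaf", c(70, 10)),
                                          sdv("gaf", c(70, 10)))), 1), 100)
  out$fsiq <- round(stats::rnorm(n, num("fsiq", c(100, 15)),
                                 sdv("fsiq", c(100, 15))))
  out$mq <- round(stats::rnorm(n, num("mq", c(100, 15)),
                               sdv("mq", c(100, 15))))

  dur_lo <- vapply(meta$group, function(g)
    (pp[[g]]$duration_range %||% c(0.1, 30))[1], numeric(1))
  dur_hi <- vapply(meta$group, function(g)
    (pp[[g]]$duration_range %||% c(0.1, 30))[2], numeric(1))
  dur <- rtnorm(n, num("duration", c(5, 3)), sdv("duration", c(5, 3)),
                dur_lo, dur_hi)
  out$illness_duration <- ifelse(is_patient, round(dur, 1), NA_real_)
  dose <- pmax(stats::rnorm(n, num("dose", c(18, 12)),
                            sdv("dose", c(18, 12))), 0)
  out$antipsychotic_dose <- ifelse(is_patient, round(dose, 1), NA_real_)

  # cohort-specific instrument availability
  if (!is.null(spec$site_missing)) {
    for (s in names(spec$site_missing)) {
      vars <- intersect(spec$site_missing[[s]], names(out))
      out[meta$site == s, vars] <- NA
    }
  }
  # missing-at-random masks
  if (!is.null(spec$missing_rates)) {
    for (v in intersect(names(spec$missing_rates), names(out))) {
      r <- spec$missing_rates[[v]]
      if (r > 0) out[[v]][stats::runif(n) < r] <- NA
    }
  }
  validate_clinical(out, warn_only = TRUE)
  out
}

# Truncated-normal draws via the inverse-CDF (one uniform per value, so the
# RNG stream length does not depend on the bounds).
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Validate a clinical table
#'
#' Checks ranges (PANSS components non-negative, GAF in 1-100, duration and
#' dose non-negative) and the additivity of PANSS subscales. Generated data
#' must satisfy `panss_total = positive + negative + general` exactly; on
#' real data a deviation warns rather than fails.
#'
#' @param clinical data.frame with the clinical columns.
#' @param warn_only if TRUE, additivity violations warn instead of erroring.
#' @return the validated data.frame, invisibly.
#' @export
validate_clinical <- function(clinical, warn_only = TRUE) {
  req <- c("subject_id", "panss_positive", "panss_negative", "panss_general",
           "panss_total", "gaf", "fsiq", "mq", "illness_duration",
           "antipsychotic_dose")
  miss <- setdiff(req, names(clinical))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  chk <- function(v, ok, what) {
    bad <- !is.na(clinical[[v]]) & !ok(clinical[[v]])
    if (any(bad)) stop(sprintf("clinical column %s: %s", v, what),
                       call. = FALSE)
  }
  for (v in c("panss_positive", "panss_negative", "panss_general",
              "panss_total", "illness_duration", "antipsychotic_dose"))
    chk(v, function(x) x >= 0, "negative values")
  chk("gaf", function(x) x >= 1 & x <= 100, "outside 1-100")
  s <- clinical$panss_positive + clinical$panss_negative +
    clinical$panss_general
  bad <- !is.na(s) & !is.na(clinical$panss_total) &
    abs(s - clinical$panss_total) > 1e-8
  if (any(bad)) {
    msg <- sprintf("PANSS subscales do not sum to total for %d subject(s)",
                   sum(bad))
    if (warn_only) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  invisible(clinical)
}
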