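#' Fit a ComBat batch-harmonisation model
#'
#' Parametric empirical-Bayes location/scale adjustment for multi-site
#' feature tables. Per feature, values are standardized by the grand mean
#' plus protected covariate effects (here: diagnostic group, so true group
#' differences are not removed as batch noise) and the pooled SD; per-batch
#' location and scale are then estimated and shrunk toward batch-level priors
#' (normal prior for location, inverse-gamma for scale, hyperparameters by
#' moment matching) through iterative conditional updates.
#'
#' @param table a [morphometry_table()], or a numeric matrix
#'   (subjects x features).
#' @param batch batch (site) label per subject; defaults to the table's
#'   `site` column.
#' @param covariates protected biological covariates: a factor/character
#'   vector (e.g. diagnostic group; treatment-coded with its first level as
#'   reference), a numeric design matrix without intercept, or `NULL`.
#'   Defaults to the table's `group` column.
#' @param conv convergence tolerance for the EB conditional updates
#'   (default 1e-4).
#' @param max_iter maximum EB iterations (default 100).
#' @return object of class `combat_model` carrying the standardization
#'   snapshot (grand mean, covariate coefficients, pooled variance), the
#'   EB-shrunken per-batch location/scale, and the adjusted training values.
#' @references Johnson WE, Li C, Rahman A (2007) Adjusting batch effects in
#'   microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1):118-127.
#' @export
fit_combat <- function(table, batch = NULL, covariates = NULL,
                       conv = 1e-4, max_iter = 100L) {
  x <- combat_input(table, batch, covariates)
  dat <- t(x$values)                      # features x samples
  n_array <- ncol(dat)
  batch <- factor(x$batch)
  batches <- levels(batch)
  n_batches <- table(batch)

  if (length(batches) < 2L) {
    warning("single batch: harmonisation model is the identity adjustment",
            call. = FALSE)
    model <- structure(list(identity = TRUE, batches = batches,
                            features = colnames(x$values),
                            cov_info = x$cov_info),
                       class = "combat_model")
    model$adjusted <- x$values
    return(model)
  }
  if (any(n_batches < 2L))
    stop(sprintf("batch(es) with a single subject: %s",
                 paste(batches[n_batches < 2L], collapse = ", ")),
         call. = FALSE)

  batchmod <- stats::model.matrix(~ -1 + batch)
  design <- cbind(batchmod, x$cov_design)
  if (qr(design)$rank < ncol(design))
    stop("rank-deficient design: batch and covariates are confounded",
         call. = FALSE)

  b_hat <- solve(crossprod(design), t(design) %*% t(dat))
  n_b <- length(batches)
  grand_mean <- crossprod(as.numeric(n_batches) / n_array,
                          b_hat[seq_len(n_b), , drop = FALSE])[1, ]
  fitted_all <- t(design %*% b_hat)
  var_pooled <- rowMeans((dat - fitted_all)^2)
  if (any(var_pooled <= 0))
    stop("feature(s) with zero pooled variance cannot be harmonised",
         call. = FALSE)

  beta_cov <- if (ncol(x$cov_design))
    b_hat[(n_b + 1):nrow(b_hat), , drop = FALSE]
  else matrix(0, 0, nrow(dat))

  stand_mean <- stand_mean_for(grand_mean, beta_cov, x$cov_design)
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  gamma_hat <- delta_hat <- matrix(NA_real_, n_b, nrow(dat),
                                   dimnames = list(batches, rownames(dat)))
  for (i in seq_len(n_b)) {
    idx <- which(batch == batches[i])
    sd_i <- s_data[, idx, drop = FALSE]
    gamma_hat[i, ] <- rowMeans(sd_i)
    delta_hat[i, ] <- apply(sd_i, 1L, stats::var)
  }

  gamma_star <- delta_star <- gamma_hat
  for (i in seq_len(n_b)) {
    idx <- which(batch == batches[i])
    sol <- eb_fit(s_data[, idx, drop = FALSE], gamma_hat[i, ], delta_hat[i, ],
                  conv = conv, max_iter = max_iter)
    gamma_star[i, ] <- sol$gamma
    delta_star[i, ] <- sol$delta
  }
  if (any(delta_star <= 0))
    stop("non-positive EB scale estimate", call. = FALSE)

  model <- structure(list(
    identity = FALSE,
    features = colnames(x$values),
    batches = batches,
    n_batches = as.integer(n_batches),
    grand_mean = grand_mean,
    beta_cov = beta_cov,
    var_pooled = var_pooled,
    gamma_star = gamma_star,
    delta_star = delta_star,
    cov_info = x$cov_info,
    conv = conv), class = "combat_model")
  model$adjusted <- combat_adjust(model, x$values, x$batch, x$cov_design)
  model
}

# Moment-matched hyperpriors for the inverse-gamma scale prior.
aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

# Iterative conditional EB estimates of batch location/scale for one batch.
eb_fit <- function(s_data, g_hat, d_hat, conv, max_iter) {
  n <- ncol(s_data)
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  a <- aprior(d_hat)
  b <- bprior(d_hat)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (n * t2 * g_hat + d_old * g_bar) / (n * t2 + d_old)
    sum2 <- rowSums((s_data - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / abs(d_old + 1e-12))
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_new, delta = d_new, iterations = it)
}

stand_mean_for <- function(grand_mean, beta_cov, cov_design) {
  n <- if (!is.null(cov_design) && nrow(cov_design)) nrow(cov_design) else
    stop("empty design")
  sm <- matrix(grand_mean, length(grand_mean), n)
  if (ncol(cov_design))
    sm <- sm + t(cov_design %*% beta_cov)
  sm
}

# Core adjustment shared by fit (training data) and apply (new data):
# standardize, remove EB batch location/scale, back-transform.
combat_adjust <- function(model, values, batch, cov_design) {
  dat <- t(values)
  stand_mean <- stand_mean_for(model$grand_mean, model$beta_cov, cov_design)
  s_data <- (dat - stand_mean) / sqrt(model$var_pooled)
  for (bl in unique(batch)) {
    idx <- which(batch == bl)
    i <- match(bl, model$batches)
    s_data[, idx] <- (s_data[, idx, drop = FALSE] - model$gamma_star[i, ]) /
      sqrt(model$delta_star[i, ])
  }
  t(s_data * sqrt(model$var_pooled) + stand_mean)
}

#' Apply a fitted ComBat model to a morphometry table
#'
#' Returns the batch-adjusted values; metadata is untouched. Applying the
#' model to its own training data reproduces the fit-time adjusted output
#' exactly, and the result is invariant to subject row order.
#'
#' @param model a `combat_model` from [fit_combat()].
#' @param table a [morphometry_table()] (or matrix plus `batch`/`covariates`)
#'   whose features and batch labels are covered by the model.
#' @inheritParams fit_combat
#' @return same class as `table`, with adjusted values.
#' @export
apply_combat <- function(model, table, batch = NULL, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  x <- combat_input(table, batch, covariates, cov_info = model$cov_info)
  if (model$identity) return(table)
  if (!identical(colnames(x$values), model$features))
    stop("feature columns do not match the fitted model", call. = FALSE)
  unseen <- setdiff(unique(x$batch), model$batches)
  if (length(unseen))
    stop("unseen batch label(s): ", paste(unseen, collapse = ", "),
         call. = FALSE)
  adjusted <- combat_adjust(model, x$values, x$batch, x$cov_design)
  if (inherits(table, "morph_table")) {
    out <- table
    # harmonised values may graze zero; keep them positive at the same
    # floor the generator uses so downstream validation holds
    floor_vals <- matrix(pmax(0.01 * colMeans(table$values), 1e-8),
                         nrow(adjusted), ncol(adjusted), byrow = TRUE)
    out$values <- pmax(adjusted, floor_vals)
    out
  } else adjusted
}

# Normalise the three accepted input forms (morph_table / matrix) and build
# the protected-covariate design (treatment coding, first level = reference).
combat_input <- function(table, batch, covariates, cov_info = NULL) {
  if (inherits(table, "morph_table")) {
    values <- table$values
    batch <- batch %||% table$meta$site
    covariates <- covariates %||% table$meta$group
  } else {
    values <- as.matrix(table)
    if (is.null(batch)) stop("batch labels required for matrix input",
                             call. = FALSE)
  }
  if (length(batch) != nrow(values))
    stop("batch labels and subjects disagree in length", call. = FALSE)
  if (is.null(covariates)) {
    cov_design <- matrix(numeric(0), nrow(values), 0)
    info <- list(type = "none")
  } else if (is.matrix(covariates)) {
    cov_design <- covariates
    info <- list(type = "matrix", cols = colnames(covariates))
  } else {
    lev <- cov_info$levels %||% sort(unique(as.character(covariates)))
    f <- factor(as.character(covariates), levels = lev)
    if (anyNA(f)) stop("covariate level not seen at fit time", call. = FALSE)
    cov_design <- stats::model.matrix(~f)[, -1, drop = FALSE]
    info <- list(type = "factor", levels = lev)
  }
  list(values = values, batch = as.character(batch),
       cov_design = cov_design, cov_info = info)
}

#' Harmonise every measure class of a cohort
#'
#' Fits one ComBat model per measure class (classes have different units and
#' scales; pooling them would distort the EB priors) with site as batch and
#' diagnostic group as the protected covariate.
#'
#' @param tables named list of [morphometry_table()] per measure class.
#' @param batch_col metadata column holding the batch label (default
#'   `"site"`).
#' @return list with `tables` (adjusted) and `models` (per class).
#' @export
harmonize_tables <- function(tables, batch_col = "site") {
  models <- list()
  out <- tables
  for (m in names(tables)) {
    tab <- tables[[m]]
    batch <- tab$meta[[batch_col]]
    grp <- factor(tab$meta$group,
                  levels = unique(c(intersect(c("HC"), tab$meta$group),
                                    sort(unique(tab$meta$group)))))
    models[[m]] <- fit_combat(tab, batch = batch, covariates = grp)
    out[[m]] <- if (models[[m]]$identity) tab else
      apply_combat(models[[m]], tab, batch = batch, covariates = grp)
  }
  list(tables = out, models = models)
}

#' @export
print.combat_model <- function(x, ...) {
  if (x$identity) {
    cat("<combat_model> identity (single batch)\n")
  } else {
    cat(sprintf("<combat_model> %d features, batches: %s\n",
                length(x$features),
                paste(sprintf("%s(n=%d)", x$batches, x$n_batches),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Serialise a ComBat model to a JSON sidecar
#'
#' @param model a `combat_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_combat_model <- function(model, path) {
  keep <- model[setdiff(names(model), "adjusted")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, matrix = "rowmajor")
  invisible(path)
}
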