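# Oracle for the no-covariate case: exact (non-EB) location/scale adjustment.
# Per feature: grand mean = batch means weighted by batch size; pooled
# variance = mean squared residual around the batch means; each batch is
# recentred/rescaled onto that common scale. EB shrinkage converges to this
# in the large-n limit.
oracle_location_scale <- function(values, batch) {
  out <- values
  n <- nrow(values)
  for (j in seq_len(ncol(values))) {
    y <- values[, j]
    mb <- tapply(y, batch, mean)
    gm <- sum(mb * table(batch) / n)
    sp <- sqrt(mean((y - mb[batch])^2))
    sb <- tapply(y, batch, sd)
    out[, j] <- sp * (y - mb[batch]) / sb[batch] + gm
  }
  out
}

sim_batch_data <- function(n = 200, p = 30, shift = 0, scale = 1,
                           group_effect = 0, seed = 1) {
  set.seed(seed)
  batch <- rep(c("A", "B"), each = n / 2)
  group <- rep(rep(c("HC", "SCZ"), each = n / 4), 2)  # balanced in batch
  mu <- runif(p, 5, 10)
  vals <- matrix(rnorm(n * p), n, p) + matrix(mu, n, p, byrow = TRUE)
  vals[group == "SCZ", ] <- vals[group == "SCZ", ] + group_effect
  vals[batch == "B", ] <- vals[batch == "B", ] * scale + shift
  colnames(vals) <- paste0("f", seq_len(p))
  rownames(vals) <- paste0("s", seq_len(n))
  list(values = vals, batch = batch, group = group)
}

test_that("single batch yields the identity adjustment with a warning", {
  d <- sim_batch_data(n = 40)
  expect_warning(m <- fit_combat(d$values, batch = rep("A", 40),
                                 covariates = d$group), "single batch")
  expect_true(m$identity)
  expect_equal(m$adjusted, d$values, tolerance = 1e-10)
})

test_that("two-batch additive shift is removed (non-EB oracle limit)", {
  shift <- 4
  d <- sim_batch_data(n = 200, shift = shift, seed = 42)
  m <- fit_combat(d$values, batch = d$batch, covariates = NULL)
  adj <- m$adjusted
  gap <- colMeans(adj[d$batch == "B", ]) - colMeans(adj[d$batch == "A", ])
  expect_lt(mean(abs(gap)), 0.05 * shift)
  # and the EB answer tracks the exact non-EB oracle closely at this n
  orc <- oracle_location_scale(d$values, d$batch)
  expect_lt(mean(abs(adj - orc)), 0.05)
})

test_that("a protected, batch-balanced group effect survives harmonisation", {
  delta <- 1.5
  d <- sim_batch_data(n = 200, shift = 3, group_effect = delta, seed = 11)
  m <- fit_combat(d$values, batch = d$batch, covariates = factor(d$group))
  adj <- m$adjusted
  est <- mean(colMeans(adj[d$group == "SCZ", ]) -
                colMeans(adj[d$group == "HC", ]))
  expect_lt(abs(est - delta) / delta, 0.10)
})

test_that("harmonisation reduces the variance fraction explained by batch", {
  d <- sim_batch_data(n = 120, shift = 2, scale = 1.4, seed = 3)
  m <- fit_combat(d$values, batch = d$batch, covariates = factor(d$group))
  eta2 <- function(vals, batch) {
    mean(sapply(seq_len(ncol(vals)), function(j) {
      a <- anova(lm(vals[, j] ~ batch))
      a$`Sum Sq`[1] / sum(a$`Sum Sq`)
    }))
  }
  expect_lt(eta2(m$adjusted, d$batch), eta2(d$values, d$batch))
})

test_that("fit/apply consistency, permutation invariance, error contracts", {
  co <- make_tiny_cohort(seed = 19L, n_per_group = 10L,
                         heterogeneity = c(HC = 1, recent = 1.5,
                                           chronic = 2))
  # give the tiny cohort two sites
  for (m in names(co$tables)) {
    n <- nrow(co$tables[[m]]$meta)
    co$tables[[m]]$meta$site <- rep(c("X", "Y"), length.out = n)
    co$tables[[m]]$values[co$tables[[m]]$meta$site == "Y", ] <-
      co$tables[[m]]$values[co$tables[[m]]$meta$site == "Y", ] * 1.05
  }
  tab <- co$tables$subcortical
  model <- fit_combat(tab)
  reapplied <- apply_combat(model, tab)
  expect_equal(unname(reapplied$values),
               unname(pmax(model$adjusted,
                           matrix(pmax(0.01 * colMeans(tab$values), 1e-8),
                                  nrow(model$adjusted), ncol(model$adjusted),
                                  byrow = TRUE))), tolerance = 1e-12)

  # permuting rows before apply gives the same values per subject
  perm <- sample(nrow(tab$values))
  tab_perm <- tab
  tab_perm$values <- tab$values[perm, , drop = FALSE]
  tab_perm$meta <- tab$meta[perm, , drop = FALSE]
  out_perm <- apply_combat(model, tab_perm)
  expect_equal(out_perm$values[rownames(tab$values), ], reapplied$values,
               tolerance = 1e-12)

  # unseen batch label
  tab_bad <- tab
  tab_bad$meta$site[1] <- "Z"
  expect_error(apply_combat(model, tab_bad), "unseen batch")

  # batch with a single subject
  bad_batch <- tab$meta$site
  bad_batch[1] <- "solo"
  expect_error(fit_combat(tab, batch = bad_batch), "single subject")

  # rank-deficient: covariate identical to batch indicator
  expect_error(fit_combat(tab$values, batch = tab$meta$site,
                          covariates = factor(tab$meta$site)),
               "rank-deficient")
})

test_that("harmonize_tables adjusts every class and keeps metadata", {
  co <- simulate_cohort(spec_presets("paper-like", seed = 23L))
  h <- harmonize_tables(co$tables)
  expect_named(h$models, c("thickness", "area", "volume", "subcortical"))
  for (m in names(h$tables)) {
    expect_identical(h$tables[[m]]$meta, co$tables[[m]]$meta)
    expect_false(identical(h$tables[[m]]$values, co$tables[[m]]$values))
  }
})
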