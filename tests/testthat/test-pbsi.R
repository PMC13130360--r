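test_that("spearman_rho handles the canonical hand cases", {
  a <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rho(a, a), 1.0)
  expect_equal(spearman_rho(a, -a), -1.0)
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)),
               oracle_spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)))
  # symmetry
  b <- c(2, 7, 1, 8, 2.8)
  expect_equal(spearman_rho(a, b), spearman_rho(b, a))
  # errors
  expect_error(spearman_rho(1:4, 1:5), "length")
  expect_error(spearman_rho(c(1, 2), c(2, 1)), "length")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(c(1, NA, 3), c(1, 2, 3)), "missing")
})

test_that("spearman_rho agrees with stats::cor(method='spearman') with ties", {
  set.seed(101)
  for (i in 1:300) {
    len <- sample(c(14L, 100L), 1)
    pr <- random_profile_pair(len)
    expect_equal(spearman_rho(pr$a, pr$b),
                 cor(pr$a, pr$b, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("pbsi_raw equals the full-matrix off-diagonal-average oracle", {
  set.seed(7)
  for (n in c(3, 5, 8)) {
    mat <- matrix(rnorm(n * 14), n, 14)
    for (i in seq_len(n))
      expect_equal(pbsi_raw(mat, i), oracle_pbsi(mat, i), tolerance = 1e-13)
  }
  # identical (non-constant) profiles in a group => PBSI 1 for everyone
  mat <- matrix(rep(c(1, 3, 2, 5, 4), each = 4), 4, 5)
  for (i in 1:4) expect_equal(pbsi_raw(mat, i), 1.0)
  # duplicating a subject's profile strictly raises that subject's PBSI
  set.seed(8)
  mat <- matrix(rnorm(5 * 10), 5, 10)
  before <- pbsi_raw(mat, 1)
  after <- pbsi_raw(rbind(mat, mat[1, ]), 1)
  expect_gt(after, before)
  expect_error(pbsi_raw(mat[1:2, ], 1), "too small")
})

test_that("matrix path and per-pair path agree exactly", {
  set.seed(12)
  mat <- matrix(round(rnorm(9 * 20, 10, 3)), 9, 20)  # heavy ties
  rownames(mat) <- paste0("s", 1:9)
  rho <- pbsi:::spearman_matrix(mat)
  for (i in c(1, 4, 9)) {
    expect_equal((sum(rho[i, ]) - 1) / 8, pbsi_raw(mat, i),
                 tolerance = 1e-13)
    for (j in c(2, 5)) expect_equal(rho[i, j], spearman_rho(mat[i, ],
                                                            mat[j, ]))
  }
  expect_error(pbsi:::spearman_matrix(rbind(mat, s10 = rep(1, 20))),
               "constant")
})

test_that("raw PBSI is local to its group and order-invariant", {
  co <- make_tiny_cohort(seed = 31L)
  raw1 <- raw_pbsi_table(co$tables)
  # modifying chronic data leaves HC raw scores untouched
  co2 <- co
  chronic <- co$meta$subject_id[co$meta$group == "chronic"]
  idx <- which(rownames(co2$tables$thickness$values) == chronic[1])
  p <- ncol(co2$tables$thickness$values)
  co2$tables$thickness$values[idx, ] <-
    co2$tables$thickness$values[idx, p:1]  # rank-breaking scramble
  raw2 <- raw_pbsi_table(co2$tables)
  hc <- raw1$group == "HC"
  expect_identical(raw1$raw_thickness[hc], raw2$raw_thickness[hc])
  expect_false(identical(raw1$raw_thickness[raw1$group == "chronic"],
                         raw2$raw_thickness[raw2$group == "chronic"]))

  # permuting subject rows yields the same score per subject_id
  perm <- sample(nrow(co$meta))
  co3 <- co
  for (m in names(co3$tables)) {
    co3$tables[[m]]$values <- co3$tables[[m]]$values[perm, , drop = FALSE]
    co3$tables[[m]]$meta <- co3$tables[[m]]$meta[perm, , drop = FALSE]
  }
  raw3 <- raw_pbsi_table(co3$tables)
  m1 <- raw1[order(raw1$subject_id), ]
  m3 <- raw3[order(raw3$subject_id), ]
  expect_equal(m1$raw_volume, m3$raw_volume, tolerance = 1e-14)
})

test_that("aggregate_pbsi standardizes and composes as documented", {
  set.seed(5)
  n <- 5
  raw <- data.frame(subject_id = paste0("s", 1:n), group = "G",
                    raw_thickness = runif(n, 0.3, 0.9),
                    raw_area = runif(n, 0.3, 0.9),
                    raw_volume = runif(n, 0.3, 0.9),
                    raw_subcortical = runif(n, 0.3, 0.9))
  sc <- aggregate_pbsi(raw, reference = "pooled")
  # explicit-summation oracle for the composites
  zcol <- function(x) (x - mean(x)) / sd(x)
  zt <- zcol(raw$raw_thickness); za <- zcol(raw$raw_area)
  zv <- zcol(raw$raw_volume); zs <- zcol(raw$raw_subcortical)
  expect_equal(sc$z_thickness, zt, tolerance = 1e-12)
  expect_equal(sc$z_cortical, zcol((zt + za + zv) / 3), tolerance = 1e-12)
  expect_equal(sc$z_total, zcol((zt + za + zv + zs) / 4), tolerance = 1e-12)
  # reference population has mean 0, sd 1 on every reported column
  for (col in c("z_thickness", "z_area", "z_volume", "z_subcortical",
                "z_cortical", "z_total")) {
    expect_lt(abs(mean(sc[[col]])), 1e-10)
    expect_lt(abs(sd(sc[[col]]) - 1), 1e-10)
  }
  # two subjects symmetric about the mean get opposite totals
  raw2 <- raw[1:2, ]
  raw2[2, 3:6] <- 2 * colMeans(raw[3:6])[1:4] - unlist(raw2[1, 3:6])
  raw2 <- rbind(raw2, raw[3, ])
  raw2[3, 3:6] <- colMeans(raw[3:6])  # a subject exactly at the mean
  sc2 <- aggregate_pbsi(raw2)
  expect_equal(sc2$z_total[1], -sc2$z_total[2], tolerance = 1e-10)
  # zero-SD reference errors
  const <- raw; const[3:6] <- 0.5
  expect_error(aggregate_pbsi(const), "zero standard deviation")
})

test_that("within-group z-scoring standardizes inside each group", {
  co <- make_tiny_cohort(seed = 77L)
  sc <- compute_pbsi(co$tables, zscore_ref = "within-group")
  for (g in unique(sc$group)) {
    z <- sc$z_total[sc$group == g]
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
  }
  # pooled reference instead leaves group means free
  scp <- compute_pbsi(co$tables, zscore_ref = "pooled")
  expect_gt(abs(mean(scp$z_total[scp$group == "chronic"])), 0.1)
})

test_that("compute_pbsi enforces the minimum group size", {
  co <- make_tiny_cohort(seed = 1L, n_per_group = 3L)
  expect_s3_class(compute_pbsi(co$tables), "pbsi_scores")
  co_small <- make_tiny_cohort(seed = 1L, n_per_group = 3L)
  keep <- co_small$meta$subject_id[-1]
  co_small$tables <- lapply(co_small$tables, subset_subjects, keep)
  expect_error(compute_pbsi(co_small$tables), "too small")
})
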