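test_that("IQR flagging matches the sorted-quartile oracle", {
  x <- c(1:10, 100)
  keep <- exclude_outliers(x)
  q1 <- oracle_quartile(x, 0.25); q3 <- oracle_quartile(x, 0.75)
  expect_identical(which(!keep), 11L)
  expect_identical(keep, x >= q1 - 1.5 * (q3 - q1) &
                     x <= q3 + 1.5 * (q3 - q1))
  # symmetric sample with no extremes: nothing flagged
  set.seed(2); y <- pmin(pmax(rnorm(50), -2), 2)
  expect_true(all(exclude_outliers(y)))
  # degenerate IQR: all equal, fences collapse onto the value, all kept
  expect_true(all(exclude_outliers(rep(3.3, 6))))
  # affine equivariance with positive scale
  set.seed(3); z <- rt(40, df = 3)
  expect_identical(exclude_outliers(z), exclude_outliers(2.7 * z - 11))
  expect_error(exclude_outliers(c(1, 2, 3)), ">= 4")
})

test_that("per-measure vs listwise outlier policies", {
  raw <- data.frame(subject_id = sprintf("s%02d", 1:12), group = "G",
                    raw_thickness = c(rnorm(11, 0.8, 0.01), 0.2),
                    raw_area = rnorm(12, 0.8, 0.01),
                    raw_volume = rnorm(12, 0.8, 0.01),
                    raw_subcortical = rnorm(12, 0.8, 0.01))
  per <- apply_outlier_policy(raw, "per-measure")
  expect_true(is.na(per$raw_thickness[12]))
  expect_false(is.na(per$raw_area[12]))  # still contributes elsewhere
  lst <- apply_outlier_policy(raw, "listwise")
  expect_true(all(is.na(lst[12, paste0("raw_", c("thickness", "area",
                                                 "volume", "subcortical"))])))
})

test_that("matching retains everyone when the pools coincide", {
  meta <- data.frame(subject_id = sprintf("s%02d", 1:40),
                     group = rep(c("HC", "SCZ"), each = 20),
                     age = rep(seq(20, 39), 2),
                     sex = rep(rep(c("M", "F"), 10), 2))
  keep <- match_groups(meta, treated_groups = "SCZ", seed = 1L)
  expect_setequal(keep, meta$subject_id)
  kept <- meta[meta$subject_id %in% keep, ]
  expect_equal(mean(kept$age[kept$group == "SCZ"]) -
                 mean(kept$age[kept$group == "HC"]), 0)
})

test_that("matching shrinks the age gap when pools are offset", {
  set.seed(10)
  gaps <- replicate(20, {
    meta <- data.frame(
      subject_id = sprintf("s%03d", 1:80),
      group = rep(c("HC", "SCZ"), each = 40),
      age = c(rnorm(40, 30, 5), rnorm(40, 40, 5)),
      sex = sample(c("M", "F"), 80, replace = TRUE))
    pre <- abs(diff(tapply(meta$age, meta$group, mean)))
    keep <- match_groups(meta, treated_groups = "SCZ", seed = 99L)
    kept <- meta[meta$subject_id %in% keep, ]
    post <- abs(diff(tapply(kept$age, kept$group, mean)))
    c(pre, post)
  })
  expect_true(all(gaps[2, ] < gaps[1, ]))
})

test_that("matching skips a one-sided sex stratum with a warning", {
  meta <- data.frame(subject_id = sprintf("s%02d", 1:12),
                     group = rep(c("HC", "SCZ"), each = 6),
                     age = rep(25:30, 2),
                     sex = c(rep("M", 6), rep("F", 3), rep("M", 3)))
  expect_warning(keep <- match_groups(meta, treated_groups = "SCZ",
                                      seed = 2L), "stratum")
  expect_false(any(meta$sex[meta$subject_id %in% keep] == "F"))
})

test_that("Tukey-Kramer reduces to the pooled t-test at k = 2", {
  set.seed(4)
  x <- rnorm(14); y <- rnorm(10, 0.8)
  tk <- tukey_kramer(c(x, y), rep(c("a", "b"), c(14, 10)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(attr(tk, "p_anova"), tt$p.value, tolerance = 1e-10)
})

test_that("Tukey agrees with stats::TukeyHSD and dominates the raw t-test", {
  set.seed(5)
  vals <- c(rnorm(12), rnorm(15, 0.5), rnorm(9, 1))
  grp <- rep(c("a", "b", "c"), c(12, 15, 9))
  tk <- tukey_kramer(vals, grp)
  ref <- TukeyHSD(aov(vals ~ grp))$grp
  # rows: b-a, c-a, c-b vs ours a/b, a/c, b/c
  expect_equal(unname(tk$diff), unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(unname(tk$p_adj), unname(ref[, "p adj"]), tolerance = 1e-8)
  for (i in seq_len(nrow(tk))) {
    a <- vals[grp == tk$group1[i]]; b <- vals[grp == tk$group2[i]]
    expect_gte(tk$p_adj[i], t.test(a, b, var.equal = TRUE)$p.value - 1e-12)
  }
  # antisymmetry under group swap
  tk_rev <- tukey_kramer(vals, factor(grp, levels = c("c", "b", "a")))
  expect_equal(sort(abs(tk_rev$diff)), sort(abs(tk$diff)), tolerance = 1e-12)
  expect_equal(sort(tk_rev$p_adj), sort(tk$p_adj), tolerance = 1e-12)
})

test_that("compare_groups: zero noise and equal means give zero contrasts", {
  scores <- data.frame(subject_id = sprintf("s%02d", 1:30),
                       group = rep(c("HC", "recent", "chronic"), each = 10),
                       z_total = rep(c(0.5, 0.5, 0.5), each = 10) +
                         rep(seq(-0.45, 0.45, length.out = 10), 3))
  meta <- data.frame(subject_id = scores$subject_id,
                     age = rep(30, 30), sex = rep(c("M", "F"), 15))
  cmp <- compare_groups(scores, meta, score_cols = "z_total")
  expect_true(all(abs(cmp$tukey$diff) < 1e-12))
  expect_identical(cmp$reference_group, "HC")
  expect_equal(cmp$n_retained$n, rep(10L, 3))
})

test_that("compare_groups is invariant to subject row order", {
  co <- make_tiny_cohort(seed = 55L, n_per_group = 12L)
  sc <- compute_pbsi(co$tables)
  cmp1 <- compare_groups(sc, co$meta)
  perm <- sample(nrow(sc))
  cmp2 <- compare_groups(sc[perm, ], co$meta[sample(nrow(co$meta)), ])
  expect_equal(cmp1$anova$F, cmp2$anova$F, tolerance = 1e-12)
  expect_equal(cmp1$regression$estimate, cmp2$regression$estimate,
               tolerance = 1e-12)
})

test_that("chi-square matches the (O-E)^2/E hand sum; onset rule splits at 5y", {
  obs <- matrix(c(12, 8, 15, 9, 7, 11), nrow = 2)
  cs <- chi_square_test(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(cs$statistic, sum((obs - expected)^2 / expected),
               tolerance = 1e-14)
  expect_equal(cs$p, chisq.test(obs, correct = FALSE)$p.value,
               tolerance = 1e-12)
  expect_identical(classify_onset(c(0.5, 5, 5.01, 12, NA)),
                   c("recent", "recent", "chronic", "chronic", NA))
})

test_that("demographics table mirrors the study layout", {
  co <- simulate_cohort(spec_presets("paper-like", seed = 31L))
  dem <- demographics_table(co$meta, co$clinical)
  expect_true(all(c("age", "gaf", "illness_duration", "sex_female") %in%
                    dem$variable))
  # duration/dose exist only for patients -> two-group t-test
  expect_identical(dem$test[dem$variable == "illness_duration"], "t-test")
  expect_identical(dem$test[dem$variable == "age"], "anova")
  expect_identical(dem$test[dem$variable == "sex_female"], "chi-square")
  expect_true(all(dem$p >= 0 & dem$p <= 1, na.rm = TRUE))
  # generated durations respect the recent/chronic assignment rule
  cl <- merge(co$meta, co$clinical)
  pat <- cl[!is.na(cl$illness_duration), ]
  expect_identical(unname(classify_onset(pat$illness_duration)), pat$group)
})
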