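# Independent oracles, deliberately written with different machinery than the
# implementation: sorting-based ranks, explicit summation, direct definitions.

# Fractional ranks by sorting (no rank()): average the positions of tied
# values in the sorted order.
oracle_ranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Brute-force Spearman rho: Pearson of oracle ranks by explicit summation.
oracle_spearman <- function(a, b) {
  ra <- oracle_ranks(a); rb <- oracle_ranks(b)
  n <- length(ra)
  num <- sum(ra * rb) - n * mean(ra) * mean(rb)
  den <- sqrt((sum(ra^2) - n * mean(ra)^2) * (sum(rb^2) - n * mean(rb)^2))
  num / den
}

# Full-matrix PBSI oracle: every pairwise rho, then the off-diagonal row mean.
oracle_pbsi <- function(mat, index) {
  n <- nrow(mat)
  rhos <- sapply(setdiff(seq_len(n), index), function(j)
    oracle_spearman(mat[index, ], mat[j, ]))
  mean(rhos)
}

# Benjamini-Hochberg by direct enumeration of the step-up definition:
# adj_i = min over j with p_(j) >= p_(i) of min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- sapply(seq_len(m), function(i) {
    min(pmin(1, m * sorted[i:m] / (i:m)))
  })
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Type-7 quartile by explicit sorted-order interpolation.
oracle_quartile <- function(x, prob) {
  s <- sort(x)
  h <- (length(s) - 1) * prob + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Pearson r and two-sided p by explicit sums and the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * (1 - pt(abs(tstat), n - 2)))
}

# Small hand-made cohort: deterministic three-group tables for unit tests.
make_tiny_cohort <- function(seed = 42L, n_per_group = 8L,
                             heterogeneity = c(HC = 1, recent = 2,
                                               chronic = 3)) {
  spec <- cohort_spec(
    group_sizes = stats::setNames(rep(n_per_group, length(heterogeneity)),
                                  names(heterogeneity)),
    n_cortical = 20L, n_subcortical = 14L,
    heterogeneity = heterogeneity,
    clinical_coupling = list(k = 0, measure = "area", noise_sd = 10),
    seed = seed)
  simulate_cohort(spec)
}

# Random profile pair generator incl. ties (integer-rounded values).
random_profile_pair <- function(len, tie_prob = 0.5) {
  a <- rnorm(len, 10, 3)
  b <- rnorm(len, 10, 3)
  if (runif(1) < tie_prob) {
    a <- round(a)
    b <- round(b)
    if (length(unique(a)) < 2) a[1] <- a[1] + 1
    if (length(unique(b)) < 2) b[1] <- b[1] + 1
  }
  list(a = a, b = b)
}
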