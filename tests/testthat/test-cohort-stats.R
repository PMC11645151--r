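test_that("group comparisons dispatch to the right two-sided tests", {
  # identical continuous samples: Welch t = 0, p = 1
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("T1D", "HC"), each = 3)
  wt <- group_compare(v, g, "t")
  expect_equal(wt$statistic, 0)
  expect_equal(wt$p, 1)
  expect_equal(wt$effect, 0)
  # Mann-Whitney on fully separated triples: U = 0, exact p = 0.1
  mw <- group_compare(c(4, 5, 6, 1, 2, 3), g, "mannwhitney")
  expect_equal(mw$p, 0.1)
  expect_equal(mw$p, mw_exact_p_enum(c(1, 2, 3), c(4, 5, 6)))
  # Fisher on a 2x2 with zero association: p = 1
  cat2 <- rep(c("yes", "no"), 4)
  gg <- rep(c("T1D", "HC"), each = 4)
  expect_equal(group_compare(cat2, gg, "fisher")$p, 1)
  expect_error(group_compare(1:5, rep("A", 5), "t"), "two groups")
})

test_that("Mann-Whitney switches to the tie-corrected approximation", {
  set.seed(8)
  x <- round(rnorm(20), 1); y <- round(rnorm(20, 0.8), 1)
  got <- group_compare(c(x, y), rep(c("a", "b"), each = 20), "mannwhitney")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  expect_equal(got$p, ref$p.value)
})

test_that("adjusted means reduce to raw means and are centering-invariant", {
  set.seed(5)
  g <- rep(c("HC", "T1D"), each = 15)
  y <- rnorm(30) + 2 * (g == "T1D")
  am0 <- adjusted_means(y, g)
  expect_equal(am0$means$estimate,
               c(mean(y[g == "HC"]), mean(y[g == "T1D"])))
  z <- rnorm(30)
  am1 <- adjusted_means(y, g, data.frame(z = z))
  am2 <- adjusted_means(y, g, data.frame(z = z - mean(z)))
  expect_equal(am1$means$estimate, am2$means$estimate)
  expect_equal(am1$difference, am2$difference)
  # rank deficiency is reported with the offending column
  expect_error(adjusted_means(y, g, data.frame(z = z, z2 = 2 * z)),
               "collinear")
})

test_that("adjusted means recover a known group effect", {
  # CI coverage over replicates (the nominal-coverage check at 500 reps
  # lives in the acceptance suite; this is a coarse sanity band)
  g <- rep(c("HC", "T1D"), each = 25)
  covered <- vapply(1:100, function(s) {
    set.seed(s)
    z <- rnorm(50)
    y <- 2 * (g == "T1D") + 1 * z + rnorm(50, sd = 0.8)
    am <- adjusted_means(y, g, data.frame(z = z))
    am$difference["lower"] <= 2 && 2 <= am$difference["upper"]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("Spearman rho: monotone extremes and exhaustive n = 5 oracle", {
  expect_equal(spearman_cor(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_cor(1:6, -(1:6))$rho, -1)
  x <- c(2, 4, 6, 8, 10)
  perms <- rbind(c(1, 2, 3, 4, 5), c(2, 1, 3, 5, 4), c(5, 4, 3, 2, 1),
                 c(3, 1, 4, 5, 2), c(1, 3, 2, 4, 5))
  for (i in seq_len(nrow(perms))) {
    y <- perms[i, ]
    d <- rank(x) - rank(y)
    rho_oracle <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
    expect_equal(spearman_cor(x, y)$rho, rho_oracle)
  }
  # invariance under strictly monotone transforms
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman_cor(exp(a), b)$rho, spearman_cor(a, b)$rho)
  expect_equal(spearman_cor(a, b^3 + b)$rho, spearman_cor(a, b)$rho)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("Spearman p and adjusted companion regression", {
  set.seed(12)
  x <- rnorm(25); y <- 0.6 * x + rnorm(25)
  got <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate))
  adj <- spearman_cor(x, y, covariates = data.frame(age = rnorm(25)),
                      adjust_scale = "raw")
  expect_true(is.finite(adj$adjusted$slope))
  expect_true(adj$adjusted$lower < adj$adjusted$slope &&
                adj$adjusted$slope < adj$adjusted$upper)
})

test_that("KS two-sample: D against brute-force ECDF scan, p asymptotics", {
  a <- c(1, 2, 3); b <- c(1.5, 2.5)
  got <- ks_2sample(a, b)
  expect_equal(got$D, ks_D_brute(a, b))
  expect_equal(ks_2sample(a, a)$D, 0)
  expect_equal(ks_2sample(c(1, 2), c(10, 11))$D, 1)
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(40, mean = runif(1, -1, 1))
    got <- ks_2sample(x, y)
    expect_equal(got$D, ks_D_brute(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(got$D, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-6)
    # D in [0,1], symmetric
    expect_true(got$D >= 0 && got$D <= 1)
    expect_equal(ks_2sample(y, x)$D, got$D)
  }
  expect_error(ks_2sample(numeric(0), 1:3), "non-empty")
})

test_that("single-cell QC filter applies the exact thresholds", {
  genes <- c(499, 500, 5000, 5001, 600, 600)
  mito <- c(0.1, 0.1, 0.1, 0.1, 0.49, 0.50)
  out <- scrna_qc_filter(genes, mito)
  expect_equal(out$kept, c(2L, 3L, 5L))
  expect_equal(unname(out$summary["low_genes"]), 1)
  expect_equal(unname(out$summary["high_genes"]), 1)
  expect_equal(unname(out$summary["high_mito"]), 1)
  expect_equal(unname(out$summary["kept"]) +
                 sum(out$summary[c("low_genes", "high_genes", "high_mito")]),
               unname(out$summary["input"]))
  # idempotence
  again <- scrna_qc_filter(genes[out$kept], mito[out$kept])
  expect_equal(again$kept, seq_along(out$kept))
})

test_that("sqrt regression equals adjusted means on the transformed scale", {
  set.seed(7)
  g <- rep(c("HC", "T1D"), each = 12)
  y <- rgamma(24, shape = 2 + 2 * (g == "T1D"), rate = 0.5)
  sr <- sqrt_regression(y, g)
  am <- adjusted_means(sqrt(y), g)
  expect_equal(sr$effect, am$difference)
  # identical groups: zero effect
  y2 <- rep(c(1, 4, 9), 4)
  expect_equal(unname(sqrt_regression(y2, rep(c("a", "b"), 6))$effect["estimate"]),
               0)
  expect_error(sqrt_regression(c(-1, 2, 3, 4), rep(c("a", "b"), 2)),
               "nonnegative")
})

test_that("t-test power: null case, monotonicity, and validity", {
  expect_equal(ttest_power(28, 12, 0, 78), 0.05, tolerance = 1e-12)
  expect_gte(ttest_power(28, 12, 88, 78), 0.80)
  # strictly increasing in |delta| and in min(n1, n2)
  pw <- vapply(seq(0, 150, by = 25), ttest_power, numeric(1),
               n1 = 28, n2 = 12, sd = 78)
  expect_true(all(diff(pw) > 0))
  pn <- vapply(c(6, 12, 24, 48), function(n) ttest_power(28, n, 88, 78),
               numeric(1))
  expect_true(all(diff(pn) > 0))
  expect_equal(ttest_power(20, 20, 50, 78),
               stats::power.t.test(n = 20, delta = 50, sd = 78,
                                   strict = TRUE)$power,
               tolerance = 1e-6)
  expect_error(ttest_power(1, 12, 88, 78), ">= 2")
})
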