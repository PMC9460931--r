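test_that("pooled-SD Cohen's d reproduces hand-derived values", {
  # A-RMS tibia groups: pooled sd = sqrt((15*0.009^2 + 15*0.005^2)/30)
  expect_equal(cohen_d_pooled(0.032, 0.009, 16, 0.023, 0.005, 16),
               0.009 / sqrt((0.009^2 + 0.005^2) / 2), tolerance = 1e-12)
  expect_equal(cohen_d_pooled(0.032, 0.009, 16, 0.023, 0.005, 16), 1.236,
               tolerance = 1e-3)
  expect_equal(cohen_d_pooled(1.71, 0.45, 16, 2.00, 0.46, 16), 0.637,
               tolerance = 1e-3)
  # symmetric in group order; zero for identical groups
  expect_equal(cohen_d_pooled(1.71, 0.45, 16, 2.00, 0.46, 16),
               cohen_d_pooled(2.00, 0.46, 16, 1.71, 0.45, 16))
  expect_equal(cohen_d_pooled(5, 1, 10, 5, 1, 10), 0)
  expect_error(cohen_d_pooled(1, 0, 10, 2, 0, 10), "pooled SD is zero")
})

test_that("unpaired t agrees with stats::t.test and its summary form", {
  set.seed(31L)
  for (i in 1:5) {
    x <- rnorm(12, 1, 2)
    y <- rnorm(17, 0.2, 1.5)
    mine <- unpaired_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    # raw-sample call equals the summary form at the sample's own m/s/n
    froms <- unpaired_t_from_summary(mean(x), sd(x), length(x),
                                     mean(y), sd(y), length(y))
    expect_equal(mine$t_stat, froms$t_stat, tolerance = 1e-12)
  }
  # summary form on the published A-RMS tibia row
  cmp <- unpaired_t_from_summary(0.032, 0.009, 16, 0.023, 0.005, 16)
  expect_equal(cmp$t_stat, 3.50, tolerance = 0.01)
  expect_equal(cmp$p_value, 0.0015, tolerance = 0.05)
  expect_equal(cmp$df, 30)
  # identical samples: t = 0, p = 1; antisymmetry in group order
  z <- c(1, 2, 3, 4)
  same <- unpaired_t(z, z)
  expect_identical(same$t_stat, 0)
  expect_identical(same$p_value, 1)
  expect_equal(unpaired_t(z, z + 1)$t_stat, -unpaired_t(z + 1, z)$t_stat)
})

test_that("ICC(1,1) equals its one-way ANOVA definition and recovers truth", {
  # exact repetition
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  expect_equal(icc_1_1(x, x)$icc, 1)
  # oracle: mean squares from stats::aov on the long-format table
  set.seed(32L)
  d1 <- rnorm(20); d2 <- d1 + rnorm(20, 0, 0.5)
  res <- icc_1_1(d1, d2)
  long <- data.frame(y = c(d1, d2), subj = factor(rep(1:20, 2)))
  tab <- anova(lm(y ~ subj, data = long))
  bms <- tab[["Mean Sq"]][1L]
  wms <- tab[["Mean Sq"]][2L]
  expect_equal(res$bms, bms, tolerance = 1e-10)
  expect_equal(res$wms, wms, tolerance = 1e-10)
  expect_equal(res$icc, (bms - wms) / (bms + wms), tolerance = 1e-10)
  # variance-components recovery: sigma_b^2 = 3 sigma_w^2 -> ICC = 0.75
  set.seed(33L)
  n <- 500
  truth <- rnorm(n, 0, sqrt(3))
  icc <- icc_1_1(truth + rnorm(n), truth + rnorm(n))$icc
  expect_gte(icc, 0.70)
  expect_lte(icc, 0.80)
  # null recovery
  set.seed(34L)
  icc0 <- icc_1_1(rnorm(n), rnorm(n))$icc
  expect_gte(icc0, -0.1)
  expect_lte(icc0, 0.1)
  # invariance under shift and positive scaling
  expect_equal(icc_1_1(d1, d2)$icc, icc_1_1(10 + d1, 10 + d2)$icc)
  expect_equal(icc_1_1(d1, d2)$icc, icc_1_1(3.2 * d1, 3.2 * d2)$icc)
  expect_error(icc_1_1(c(1, 2, NA), c(1, 2, 3)), "non-finite")
  expect_error(icc_1_1(1:2, 1:2), "at least 3")
})

test_that("pearson_r matches the product-moment formula", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(2.1, 0.4, 3.3, 2.8, 5.0)
  # hand oracle: explicit sums
  rxy <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$r, rxy, tolerance = 1e-12)
  tt <- rxy * sqrt(3 / (1 - rxy^2))
  expect_equal(res$p_value, 2 * pt(-abs(tt), 3), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), y), "zero variance")
})

test_that("the empirical ROC matches Mann-Whitney pair counting", {
  # perfect separation
  r <- roc_with_youden(c(5, 6, 7), c(1, 2, 3))
  expect_equal(r$auc, 1)
  expect_equal(r$sens_at_cutoff, 1)
  expect_equal(r$spec_at_cutoff, 1)
  # identical multisets
  r0 <- roc_with_youden(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$auc, 0.5)
  # hand-listed 6 vs 6 with ties
  pos <- c(0.040, 0.031, 0.027, 0.027, 0.022, 0.051)
  neg <- c(0.025, 0.027, 0.020, 0.018, 0.030, 0.022)
  r6 <- roc_with_youden(pos, neg)
  expect_equal(r6$auc, brute_auc(pos, neg), tolerance = 1e-12)
  expect_equal(r6$youden_j,
               max(r6$sensitivity + r6$specificity - 1))
  # agreement with pROC as an independent implementation
  pr <- pROC::roc(response = rep(c(1, 0), each = 6), predictor = c(pos, neg),
                  direction = "<", quiet = TRUE)
  expect_equal(r6$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  # invariance under a strictly increasing transform
  r6t <- roc_with_youden(exp(3 * pos), exp(3 * neg))
  expect_equal(r6t$auc, r6$auc, tolerance = 1e-12)
  # all-identical values: flagged degenerate, not an error
  rd <- roc_with_youden(rep(2, 4), rep(2, 5))
  expect_equal(rd$auc, 0.5)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$youden_cutoff))
})

test_that("Youden ties break toward specificity, then the smaller threshold", {
  # J is maximal (=1) on a whole gap of thresholds when groups separate;
  # the rule picks the candidate with max specificity, then smallest value
  r <- roc_with_youden(c(10, 11), c(1, 2))
  expect_equal(r$youden_j, 1)
  expect_equal(r$spec_at_cutoff, 1)
  expect_equal(r$youden_cutoff, 6)  # midpoint 2|10, smallest among ties
})

test_that("binormal AUC matches its closed form on the published summaries", {
  expect_equal(binormal_auc(0, 1, 0, 2), 0.5)
  expect_equal(binormal_auc(0.032, 0.009, 0.023, 0.005),
               pnorm(0.009 / sqrt(0.009^2 + 0.005^2)), tolerance = 1e-12)
  expect_equal(round(binormal_auc(0.032, 0.009, 0.023, 0.005), 3), 0.809)
  expect_equal(round(binormal_auc(0.044, 0.013, 0.034, 0.007), 3), 0.751)
  expect_error(binormal_auc(1, 0, 2, 0), "s1\\^2 \\+ s2\\^2 > 0")
})

test_that("standardized-beta OLS reduces to r and recovers planted effects", {
  set.seed(35L)
  x <- rnorm(40)
  y <- 0.6 * x + rnorm(40, 0, 0.5)
  fit <- ols_standardized_beta(y, data.frame(x = x))
  expect_equal(fit$coefficients$beta, pearson_r(x, y)$r, tolerance = 1e-12)
  # exact linear combination: R^2 = 1, p ~ 0
  z <- rnorm(40)
  fit2 <- suppressWarnings(   # summary.lm flags the noiseless fit
    ols_standardized_beta(2 * x - 3 * z, data.frame(x = x, z = z)))
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)
  expect_true(all(fit2$coefficients$p_value < 1e-12))
  expect_error(ols_standardized_beta(y, data.frame(x = x, x2 = 2 * x)),
               "rank-deficient")
  # recovery simulation: planted standardized betas at n = 32
  set.seed(36L)
  betas <- replicate(200, {
    g <- rep(0:1, each = 16)
    age <- rnorm(32)
    out <- 0.5 * g + 0.3 * age + rnorm(32, 0, 0.6)
    ols_standardized_beta(out, data.frame(group = g, age = age))$coefficients$beta[1L]
  })
  planted <- 0.5 * sd(rep(0:1, each = 16)) /
    sqrt(0.5^2 * var(rep(0:1, each = 16)) + 0.3^2 + 0.6^2)
  expect_lt(abs(mean(betas) - planted), 0.05)
})
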