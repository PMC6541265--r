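test_that("Egger test is null on a funnel symmetric by construction", {
  s <- mirrored_studies()
  e <- egger_test(s)
  expect_lt(abs(e$t_stat), 1)
  expect_gt(e$p, .3)
  expect_equal(e$df, nrow(s) - 2)
  expect_error(egger_test(toy_studies(c(.1, .2), c(30, 30))), "at least 3")
})

test_that("Egger coefficients match the closed-form normal-equations oracle", {
  s <- toy_studies(c(.45, .3, .18, .1), c(15, 40, 90, 250))
  e <- egger_test(s)
  # oracle: OLS of y* = z/se on x* = 1/se via explicit normal equations
  ys <- s$z / sqrt(s$var_z); xs <- 1 / sqrt(s$var_z)
  X <- cbind(1, xs)
  beta <- solve(t(X) %*% X, t(X) %*% ys)
  resid <- ys - X %*% beta
  s2 <- sum(resid^2) / (length(ys) - 2)
  se_int <- sqrt(s2 * solve(t(X) %*% X)[1, 1])
  expect_equal(e$intercept, beta[1], tolerance = 1e-12)
  expect_equal(e$slope, beta[2], tolerance = 1e-12)
  expect_equal(e$t_stat, beta[1] / se_int, tolerance = 1e-12)
  # and the asymmetry direction is positive for this small-studies-big set
  expect_gt(e$intercept, 0)
  # the classical variant agrees with metafor's lm regtest
  m <- metafor::rma(yi = s$z, vi = s$var_z, method = "DL")
  rt <- metafor::regtest(m, model = "lm")
  expect_equal(e$t_stat, as.numeric(rt$zval), tolerance = 1e-10)
})

test_that("the weighted Egger variant reproduces the meta-regression form", {
  s <- toy_studies(c(.5, .28, .2, .12, .05), c(12, 30, 60, 120, 300))
  e <- egger_test(s, weighted = TRUE)
  fit <- lm(z ~ I(sqrt(var_z)), data = s, weights = 1 / s$var_z)
  expect_equal(e$intercept, unname(coef(fit)[2]), tolerance = 1e-12)
})

test_that("trim-and-fill imputes nothing on symmetric data and is
          idempotent on a mirrored-complete set", {
  s <- mirrored_studies()
  tf <- trim_and_fill(s)
  expect_equal(tf$k0, 0)
  expect_equal(tf$r_adjusted, pool_random_effects(s)$r_pooled)
  expect_false(any(tf$filled$filled))
})

test_that("trim-and-fill recovers one-sided extremes and matches oracles", {
  # 7 symmetric studies plus 3 one-sided extremes at the imprecise end
  s <- toy_studies(c(.2, .25, .15, .22, .18, .21, .19, .8, .7, .6),
                   c(150, 120, 100, 90, 80, 200, 60, 12, 14, 16))
  tf <- trim_and_fill(s, side = "left", estimator = "L0")
  # rank-based L0 oracle, evaluated directly at the converged center
  mu_final <- {
    yy <- s$z; v <- s$var_z
    keep <- order(yy)[seq_len(nrow(s) - tf$k0)]
    sum(yy[keep] / v[keep]) / sum(1 / v[keep])
  }
  dev <- s$z - mu_final
  tn <- sum(rank(abs(dev), ties.method = "first")[dev > 0])
  k0_oracle <- max(0, round((4 * tn - 10 * 11) / (2 * 10 - 1)))
  expect_equal(tf$k0, k0_oracle)
  # cross-check against the independent reference implementation
  m <- metafor::rma(yi = s$z, vi = s$var_z, method = "FE")
  mtf <- metafor::trimfill(m, side = "left", estimator = "L0")
  expect_equal(tf$k0, mtf$k0)
  # observed studies all survive in the final pooled set
  expect_true(all(s$study_id %in% tf$filled$study_id))
  expect_equal(sum(tf$filled$filled), tf$k0)
  # filling pulls the estimate down, toward the symmetric core
  expect_lt(tf$r_adjusted, pool_random_effects(s)$r_pooled)
})

test_that("cumulative meta-analysis runs most-precise-first and ends at the
          full pool", {
  s <- toy_studies(c(.4, .1, .3, .2, .5), c(20, 200, 60, 100, 15))
  cm <- cumulative_meta(s)
  expect_equal(nrow(cm), 5)
  # first row is the single most precise study
  expect_equal(cm$study_id[1], s$study_id[which.min(s$var_z)])
  expect_equal(cm$r_pooled[1], tanh(s$z[which.min(s$var_z)]))
  # final row equals the full random-effects pool
  expect_equal(cm$r_pooled[5], pool_random_effects(s)$r_pooled)
  # on this small-studies-big set the estimate drifts upward
  expect_gt(cm$r_pooled[5], cm$r_pooled[1])
})

test_that("TOP10 pools the most precise tenth, deterministically under ties", {
  s <- toy_studies(c(.4, .1, .3, .2, .5, .25, .33, .15, .28, .45),
                   c(20, 200, 60, 100, 15, 30, 40, 80, 50, 25))
  t10 <- suppressWarnings(top10(s))
  expect_equal(t10$k, 1)
  expect_equal(t10$r_pooled, tanh(.1))   # the n = 200 study
  # ties in precision break by study_id order
  s2 <- toy_studies(rep(.2, 12), rep(50, 12),
                    ids = sprintf("S.%02d", 12:1))
  s2$z <- atanh(seq(.1, .32, length.out = 12))
  t2 <- top10(s2)
  expect_equal(sort(t2$studies$study_id), c("S.01", "S.02"))
  t2b <- top10(s2[sample(12), ])
  expect_equal(t2b$r_pooled, t2$r_pooled)
})

test_that("limit meta-analysis: no adjustment needed when there is no
          small-study association", {
  # heterogeneous but exchangeable effects at varied precision
  set.seed(3)
  k <- 30
  n <- sample(c(20, 50, 100, 200), k, replace = TRUE)
  z <- .25 + rnorm(k, 0, .15)
  s <- toy_studies(z, n)
  lm0 <- limit_meta(s)
  p0 <- pool_random_effects(s)
  expect_lt(abs(lm0$r_limit - p0$r_pooled), .08)
  expect_true(all(lm0$shrinkage >= 0 & lm0$shrinkage <= 1))
})

test_that("limit meta-analysis matches an independent weighted-regression
          oracle on a toy set", {
  s <- toy_studies(c(.9, .5, .38, .05, .12), c(12, 25, 50, 110, 260))
  lmx <- limit_meta(s)
  expect_gt(lmx$tau2, 0)
  # oracle: same extended model fitted through lm() instead of the
  # package's closed-form normal equations
  tau2 <- pool_random_effects(s)$tau2
  x <- sqrt(s$var_z + tau2)
  fit <- lm(s$z ~ x, weights = 1 / (s$var_z + tau2))
  expect_equal(lmx$beta0, unname(coef(fit)[1]), tolerance = 1e-12)
  expect_equal(lmx$beta1, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(lmx$z_limit,
               unname(coef(fit)[1] + coef(fit)[2] * sqrt(tau2)),
               tolerance = 1e-12)
  vc <- vcov(summary(fit)) / summary(fit)$sigma^2
  se_or <- sqrt(vc[1, 1] + tau2 * vc[2, 2] + 2 * sqrt(tau2) * vc[1, 2])
  expect_equal(lmx$se_limit, se_or, tolerance = 1e-12)
  # Q decomposition: Q_small + Q_resid <= Q (equality up to truncation)
  expect_lte(lmx$Q_small + lmx$Q_resid, lmx$Q + 1e-8)
  expect_gte(lmx$Q_small, 0)
  expect_gte(lmx$Q_resid, 0)
  # alternative adjustments stay on the shrunken side of the naive pool
  expect_lt(limit_meta(s, adjust = "intercept")$r_limit, lmx$r_limit)
})

test_that("limit meta-analysis falls back to the fixed-effect estimate when
          tau2 is zero", {
  s <- toy_studies(c(.199, .2, .201, .2), c(50, 60, 70, 80))
  lmx <- limit_meta(s)
  expect_equal(lmx$tau2, 0)
  expect_match(lmx$note, "fixed-effect")
  expect_equal(lmx$r_limit, pool_fixed_effects(s)$r_pooled)
  expect_equal(lmx$shrinkage, rep(0, 4))
})

test_that("funnel data covers observed, shrunken and filled studies", {
  s <- toy_studies(c(.2, .25, .15, .22, .8, .7), c(150, 120, 100, 90, 12, 14))
  tf <- trim_and_fill(s, side = "left")
  lmx <- limit_meta(s)
  fd <- funnel_data(s, trimfill = tf, limit = lmx)
  expect_equal(nrow(fd), nrow(s) + tf$k0)
  expect_equal(sum(fd$filled), tf$k0)
  expect_false(anyNA(fd$r_shrunken[!fd$filled]))
  expect_equal(fd$precision, 1 / fd$se_z)
})
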