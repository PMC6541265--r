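test_that("pooling identical studies returns them unchanged, no heterogeneity", {
  s <- toy_studies(rep(atanh(.2), 5), rep(50, 5))
  p <- pool_random_effects(s)
  expect_equal(p$r_pooled, .2)
  expect_equal(p$Q, 0)
  expect_equal(p$I2, 0)
  expect_equal(p$tau2, 0)
  f <- pool_fixed_effects(s)
  expect_equal(f$r_pooled, .2)
  expect_equal(f$tau2, 0)
})

test_that("DerSimonian-Laird pooling matches metafor on toy sets", {
  sets <- list(toy_studies(c(.2, .3, .4), c(53, 103, 153)),
               toy_studies(c(-.1, .05, .22, .4, .18), c(20, 35, 60, 90, 200)))
  set.seed(7)
  for (i in 1:5) {
    k <- sample(3:12, 1)
    sets[[length(sets) + 1]] <-
      toy_studies(rnorm(k, .2, .3), sample(15:300, k))
  }
  for (s in sets) {
    p <- pool_random_effects(s)
    m <- metafor::rma(yi = s$z, vi = s$var_z, method = "DL")
    expect_equal(p$z_pooled, as.numeric(m$beta), tolerance = 1e-10)
    expect_equal(p$se_z, m$se, tolerance = 1e-10)
    expect_equal(p$tau2, m$tau2, tolerance = 1e-10)
    expect_equal(p$Q, m$QE, tolerance = 1e-10)
    f <- pool_fixed_effects(s)
    mf <- metafor::rma(yi = s$z, vi = s$var_z, method = "FE")
    expect_equal(f$z_pooled, as.numeric(mf$beta), tolerance = 1e-10)
    # Wald CI on z, back-transformed
    expect_equal(p$ci_low, tanh(as.numeric(m$beta) - qnorm(.975) * m$se),
                 tolerance = 1e-10)
  }
})

test_that("PM and REML tau2 estimators match metafor", {
  s <- toy_studies(c(-.1, .05, .22, .4, .18, .6), c(20, 35, 60, 90, 200, 25))
  # the two implementations use different root-finding stops, so agreement
  # is to convergence precision, not machine precision
  expect_equal(pool_random_effects(s, "PM")$tau2,
               metafor::rma(yi = s$z, vi = s$var_z, method = "PM")$tau2,
               tolerance = 1e-3)
  expect_equal(pool_random_effects(s, "REML")$tau2,
               metafor::rma(yi = s$z, vi = s$var_z, method = "REML")$tau2,
               tolerance = 1e-3)
})

test_that("pooled estimate is invariant under study reordering", {
  s <- toy_studies(c(.5, -.2, .1, .3, .25), c(12, 40, 90, 33, 61))
  p1 <- pool_random_effects(s)
  p2 <- pool_random_effects(s[c(4, 1, 5, 3, 2), ])
  expect_equal(p1$r_pooled, p2$r_pooled)
  expect_equal(p1$tau2, p2$tau2)
})

test_that("random-effects intervals are at least as wide as fixed-effect", {
  set.seed(11)
  for (i in 1:10) {
    k <- sample(3:15, 1)
    s <- toy_studies(rnorm(k, .2, .25), sample(15:200, k))
    re <- pool_random_effects(s)
    fe <- pool_fixed_effects(s)
    expect_gte(re$ci_high - re$ci_low, fe$ci_high - fe$ci_low - 1e-12)
    expect_equal(re$I2, fe$I2)   # Q-based, model-free
  }
})

test_that("adding a study at the pooled value does not move the estimate", {
  s <- toy_studies(c(.1, .3, .45), c(40, 80, 25))
  p <- pool_random_effects(s)
  s2 <- rbind(s, data.frame(study_id = "Toy.99.1", r = p$r_pooled,
                            z = p$z_pooled, var_z = .02))
  p2 <- pool_random_effects(s2)
  # tau2 shrinks slightly, which can only pull the estimate toward itself
  expect_equal(p2$z_pooled, p$z_pooled, tolerance = 1e-3)
})

test_that("degenerate inputs are rejected", {
  expect_error(pool_random_effects(toy_studies(.2, 50)), "at least 2")
  bad <- toy_studies(c(.1, .2), c(50, 50)); bad$var_z[1] <- 0
  expect_error(pool_random_effects(bad), "non-positive")
})

test_that("parameter recovery on synthetic data without selection", {
  # moderate replication count here; the full-scale check lives in the
  # acceptance suite
  nrep <- 60
  rhat <- tau2hat <- numeric(nrep)
  for (i in seq_len(nrep)) {
    rows <- generate_meta_dataset(
      synthetic_config(k = 200, mu_z = .15, tau = .10, selection = 0,
                       seed = 5000 + i))
    st <- aggregate_studies(rows, var_method = "fisher",
                            split_shared_control = FALSE)
    p <- pool_random_effects(st)
    rhat[i] <- p$r_pooled; tau2hat[i] <- p$tau2
  }
  expect_lt(abs(mean(rhat) - tanh(.15)), .02)
  expect_lt(abs(mean(tau2hat) - .01), .25 * .01)
})
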