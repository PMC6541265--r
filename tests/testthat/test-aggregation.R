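test_that("a single outcome passes through the composite unchanged", {
  cc <- composite_effect(0.3, 0.02)
  expect_equal(cc$es, 0.3)
  expect_equal(cc$var, 0.02)
  ao <- aggregate_outcomes(.25, 20, 20)
  expect_equal(ao$r, .25)
  expect_error(composite_effect(numeric(0), numeric(0)), "empty")
})

test_that("two correlated outcomes: mean point estimate, variance between
          the single-outcome variance and half of it", {
  v <- 1 / 47   # n = 50 per outcome
  cc <- composite_effect(c(.2, .4), c(v, v), within_r = .5)
  expect_equal(cc$es, .3)
  expect_lt(cc$var, v)
  expect_gt(cc$var, v / 2)
  # direct evaluation of the composite-variance formula
  expect_equal(cc$var, (2 * v + 2 * .5 * v) / 4)
})

test_that("perfectly redundant outcomes add no information", {
  v <- 1 / 27
  cc <- composite_effect(rep(.3, 4), rep(v, 4), within_r = 1)
  expect_equal(cc$var, v)
  expect_equal(cc$es, .3)
})

test_that("composite estimate stays within the input range; variance is
          non-increasing in m and non-decreasing in within_r", {
  set.seed(42)
  for (i in 1:25) {
    m <- sample(2:8, 1)
    es <- runif(m, -.5, .6)
    v <- runif(m, .005, .05)
    rho <- runif(1)
    cc <- composite_effect(es, v, rho)
    expect_gte(cc$es, min(es)); expect_lte(cc$es, max(es))
    # raising the imputed correlation never reduces the variance
    cc3 <- composite_effect(es, v, min(1, rho + .2))
    expect_gte(cc3$var, cc$var - 1e-12)
  }
  # with equal component variances, the composite variance
  # v (1 + (m-1) rho) / m is non-increasing in m
  for (rho in c(0, .3, .5, .9)) {
    vs <- vapply(1:8, function(m)
      composite_effect(rep(.2, m), rep(.04, m), rho)$var, numeric(1))
    expect_true(all(diff(vs) < 1e-12))
    expect_equal(vs, .04 * (1 + (1:8 - 1) * rho) / (1:8))
  }
})

test_that("aggregating arms sharing one control: mean effect, control once", {
  # one arm is the identity
  a1 <- aggregate_interventions(.2, .01, 50, 50)
  expect_equal(a1$z, .2)
  expect_equal(a1$n_total, 100)
  # arms r = .08 (n 208) and .03 (n 212) sharing a 101-person control
  v1 <- var_z_conversion(.08, 107, 101 / 2)
  v2 <- var_z_conversion(.03, 111, 101 / 2)
  ai <- aggregate_interventions(atanh(c(.08, .03)), c(v1, v2),
                                c(107, 111), 101)
  expect_equal(ai$r, .055, tolerance = .001)
  expect_equal(ai$n_total, 107 + 111 + 101)
  # identical arms return the common value
  ak <- aggregate_interventions(rep(.15, 4), rep(.02, 4), rep(30, 4), 30)
  expect_equal(ak$r, tanh(.15))
})

test_that("aggregation order is explicit: outcomes within arm, then arms", {
  rows <- data.frame(
    study_id = "A.2000.1", available_data = "post-msds",
    measure = rep(c("m1", "m2"), 2),
    intervention = rep(c("arm1", "arm2"), each = 2),
    n_t = rep(c(20, 30), each = 2), n_c = 25,
    n_total = rep(c(45, 55), each = 2),
    r = c(.1, .3, .2, .4), stringsAsFactors = FALSE)
  st <- aggregate_studies(rows)
  expect_equal(nrow(st), 1)
  # balanced design: grand mean on the z scale
  expect_equal(st$z, mean(atanh(c(.1, .3, .2, .4))))
  expect_equal(st$n_arms, 2)
  expect_equal(st$n_rows, 4)
  # participants: both treatment groups, control once
  expect_equal(st$n_total, 20 + 30 + 25)
  # reordering rows changes nothing
  st2 <- aggregate_studies(rows[c(3, 1, 4, 2), ])
  expect_equal(st2$z, st$z)
  expect_equal(st2$var_z, st$var_z)
})

test_that("StudyEffect invariants hold on every aggregated fixture", {
  for (id in ppi_datasets()$dataset_id) {
    st <- aggregate_fixture(id)
    expect_equal(st$z, atanh(st$r), info = id)
    expect_true(all(st$var_z > 0), info = id)
    expect_true(all(st$n_eff >= 4), info = id)
    expect_equal(st$n_eff, 3 + 1 / st$var_z, info = id)
    expect_false(any(duplicated(st$study_id)), info = id)
  }
})

test_that("the five fixtures aggregate to the published study counts", {
  reg <- ppi_datasets()
  for (i in seq_len(nrow(reg))) {
    st <- aggregate_fixture(reg$dataset_id[i])
    expect_equal(nrow(st), reg$k_expected[i], info = reg$dataset_id[i])
  }
})
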