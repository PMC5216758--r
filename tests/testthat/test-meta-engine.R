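worked <- eff_df(c(0.2, 0, 0.4), rep(0.2, 3))

test_that("fixed-effect pooling is the inverse-variance average", {
  two <- eff_df(c(0.2, 0.2), c(0.2, 0.2))
  f <- pool_fixed(two)
  expect_equal(f$log_or, 0.2)
  expect_equal(f$se, 0.2 / sqrt(2))
  expect_equal(pool_fixed(worked)$log_or, 0.2)
  # a dominant high-precision study pulls the pool to itself
  dom <- pool_fixed(eff_df(c(0, 1), c(1, 1e-4)))
  expect_equal(dom$log_or, 1, tolerance = 1e-6)
  expect_error(pool_fixed(worked[1, ]), class = "insufficient_data")
})

test_that("Cochran's Q, I2 and DL tau2 reproduce the worked chain", {
  q <- cochran_q(worked)
  expect_equal(q$q, 2)
  expect_equal(q$df, 2)
  expect_equal(q$p_het, exp(-1), tolerance = 1e-6)  # chi2(2) survival at 2
  expect_equal(cochran_q(eff_df(c(0.3, 0.3), c(0.1, 0.4)))$q, 0)
  expect_equal(i_squared(10, 5), 50)
  expect_equal(i_squared(2, 2), 0)
  expect_equal(i_squared(2.5, 5), 0)     # truncation at zero
  expect_equal(dl_tau2(worked), 0)       # Q <= df
  # (0, 1) each var 0.01: Q = 50, denominator 100
  expect_equal(dl_tau2(eff_df(c(0, 1), c(0.1, 0.1))), 0.49)
})

test_that("random-effects pooling continues the worked chain and reduces to fixed at tau2 = 0", {
  r <- pool_random(worked)
  expect_equal(r$tau2, 0)
  expect_equal(r$or, exp(0.2))
  expect_equal(r$se, sqrt(0.04 / 3))
  expect_equal(r$ci_low, exp(0.2 - 1.96 * sqrt(0.04 / 3)))
  expect_equal(r$ci_high, exp(0.2 + 1.96 * sqrt(0.04 / 3)))
  f <- pool_fixed(worked)
  expect_equal(r$log_or, f$log_or)
  expect_equal(r$se, f$se)
  null <- pool_random(eff_df(c(0, 0, 0), c(0.1, 0.2, 0.3)))
  expect_equal(null$or, 1)
  expect_equal(null$p, 1)
})

test_that("engine agrees with metafor's DL implementation on random instances", {
  skip_if_not_installed("metafor")
  set.seed(101)
  for (i in 1:10) {
    k <- sample(3:15, 1)
    eff <- eff_df(rnorm(k, 0.2, 0.4), runif(k, 0.05, 0.5))
    ref <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "DL")
    expect_equal(pool_random(eff)$log_or, unname(coef(ref)), tolerance = 1e-8)
    expect_equal(dl_tau2(eff), ref$tau2, tolerance = 1e-8)
    expect_equal(cochran_q(eff)$q, ref$QE, tolerance = 1e-8)
    expect_equal(i_squared(cochran_q(eff)$q, k - 1),
                 max(0, (ref$QE - (k - 1)) / ref$QE) * 100, tolerance = 1e-8)
  }
})

test_that("Q is invariant under shifting all effects by a constant", {
  set.seed(5)
  eff <- eff_df(rnorm(6), runif(6, 0.1, 0.5))
  shifted <- eff; shifted$log_or <- shifted$log_or + 1.7
  expect_equal(cochran_q(shifted)$q, cochran_q(eff)$q)
})

test_that("pooled CI contains the estimate and narrows as k grows", {
  set.seed(8)
  widths <- sapply(c(4, 16, 64), function(k) {
    eff <- eff_df(rnorm(k, 0.3, 0.05), rep(0.3, k))
    r <- pool_random(eff)
    expect_true(r$ci_low <= r$or && r$or <= r$ci_high)
    log(r$ci_high) - log(r$ci_low)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("heterogeneity classes follow the 25/50 cut points", {
  expect_equal(classify_heterogeneity(0), "mild")
  expect_equal(classify_heterogeneity(24.9), "mild")
  expect_equal(classify_heterogeneity(25), "moderate")
  expect_equal(classify_heterogeneity(50), "moderate")
  expect_equal(classify_heterogeneity(50.1), "large")
})

test_that("meta_analyze enforces the three-independent-source rule", {
  expect_error(meta_analyze(replicated_table(k = 2), "rs0000001"),
               class = "eligibility_error")
  # duplicate pubmed_id counts once: three cohorts, two publications
  tab <- make_table(
    make_record("s1", pubmed_id = "PM1"),
    make_record("s2", pubmed_id = "PM1", case = c(12, 22, 28)),
    make_record("s3", pubmed_id = "PM2", case = c(9, 21, 31)))
  err <- tryCatch(meta_analyze(tab, "rs0000001"), error = identity)
  expect_s3_class(err, "eligibility_error")
  expect_equal(err$n_sources, 2L)
  # but all three cohorts contribute effects once a third source exists
  tab4 <- make_table(
    make_record("s1", pubmed_id = "PM1"),
    make_record("s2", pubmed_id = "PM1", case = c(12, 22, 28)),
    make_record("s3", pubmed_id = "PM2", case = c(9, 21, 31)),
    make_record("s4", pubmed_id = "PM3", case = c(11, 19, 30)))
  m <- meta_analyze(tab4, "rs0000001")
  expect_equal(m$k, 4L)
  expect_equal(m$n_sources, 3L)
})

test_that("meta_analyze recovers a planted effect and refuses mixed schemes", {
  cfg <- sim_config(k = 3, n_cases = 5000, n_controls = 5000,
                    theta = 0.3, tau2 = 0, seed = 21)
  m <- meta_analyze(simulate_dataset(cfg), "rs0000001")
  expect_lt(abs(m$log_or - 0.3), 3 * m$se)
  mixed <- make_table(
    make_record("g1"), make_record("g2"), make_record("g3"),
    make_record("c1", scheme = "carrier", case = c(10, 20),
                control = c(15, 15)))
  expect_error(meta_analyze(mixed, "rs0000001"),
               class = "applicability_error")
})

test_that("Wald p back-calculated from OR and CI matches the forward computation", {
  eff <- eff_df(c(0.25, 0.4, 0.1, 0.3), c(0.1, 0.2, 0.15, 0.12))
  r <- pool_random(eff)
  expect_equal(wald_p_from_ci(r$or, r$ci_low, r$ci_high), r$p,
               tolerance = 1e-10)
})
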