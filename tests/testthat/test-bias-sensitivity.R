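test_that("Egger regression matches closed-form OLS on a 3-point instance", {
  eff <- eff_df(c(0.5, 0.2, 0.1), c(0.5, 0.25, 0.125))
  x <- 1 / eff$se            # 2, 4, 8
  y <- eff$log_or / eff$se   # 1, 0.8, 0.8
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (3 - 2)
  se_int <- sqrt(s2 * (1 / 3 + mean(x)^2 / sum((x - mean(x))^2)))
  e <- egger_test(eff)
  expect_equal(e$intercept, intercept, tolerance = 1e-10)
  expect_equal(e$se, se_int, tolerance = 1e-10)
  expect_equal(e$p, 2 * pt(-abs(intercept / se_int), df = 1),
               tolerance = 1e-10)
})

test_that("Egger test agrees with metafor's classic regression form", {
  skip_if_not_installed("metafor")
  set.seed(33)
  for (i in 1:5) {
    k <- sample(5:15, 1)
    se <- runif(k, 0.1, 0.6)
    eff <- eff_df(rnorm(k, 0.2, se), se)
    ref <- metafor::regtest(x = eff$log_or, sei = eff$se,
                            model = "lm", predictor = "sei")
    mine <- egger_test(eff)
    expect_equal(mine$p, ref$pval, tolerance = 1e-8)
  }
})

test_that("a funnel symmetric in the standardized deviates has near-zero intercept", {
  # mirror pairs around theta = 0: snd values +/-c at each precision
  se <- rep(c(0.1, 0.2, 0.4), each = 2)
  eff <- eff_df(rep(c(1, -1), 3) * 0.3 * se, se)
  expect_lt(abs(egger_test(eff)$intercept), 1e-10)
})

test_that("Egger intercept is invariant under joint scaling of effects and errors", {
  set.seed(12)
  eff <- eff_df(rnorm(8, 0.2, 0.3), runif(8, 0.1, 0.5))
  scaled <- eff_df(eff$log_or * 3, eff$se * 3)
  expect_equal(egger_test(scaled)$intercept, egger_test(eff)$intercept,
               tolerance = 1e-10)
  expect_error(egger_test(eff_df(c(0.1, 0.2, 0.3), rep(0.2, 3))),
               class = "degenerate_regression")
  expect_error(egger_test(eff[1:2, ]), class = "insufficient_data")
})

test_that("Begg tau matches brute-force pair counting and cor.test", {
  brute_tau <- function(x, y) {
    s <- 0; nx <- 0; ny <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) {
      if (j <= i) next
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      s <- s + sx * sy; nx <- nx + (sx != 0); ny <- ny + (sy != 0)
    }
    s / sqrt(nx * ny)
  }
  set.seed(44)
  for (i in 1:10) {
    k <- sample(4:8, 1)
    eff <- eff_df(rnorm(k), runif(k, 0.1, 0.8))
    fixed <- pool_fixed(eff)
    dev <- (eff$log_or - fixed$log_or) /
      sqrt(pmax(eff$se^2 - fixed$se^2, 1e-12))
    b <- begg_test(eff)
    expect_equal(b$tau, brute_tau(dev, eff$se^2), tolerance = 1e-10)
    expect_equal(b$tau,
                 unname(cor.test(dev, eff$se^2,
                                 method = "kendall")$estimate),
                 tolerance = 1e-10)
  }
})

test_that("Begg tau hits +/-1 for perfectly (dis)cordant deviates", {
  # construct deviates monotone in the variance, then reverse
  eff <- eff_df(c(0.05, 0.3, 0.9, 2.0), c(0.1, 0.2, 0.3, 0.4))
  fixed <- pool_fixed(eff)
  dev <- (eff$log_or - fixed$log_or) /
    sqrt(pmax(eff$se^2 - fixed$se^2, 1e-12))
  expect_true(all(diff(dev) > 0))  # construction check
  expect_equal(begg_test(eff)$tau, 1)
  rev_eff <- eff_df(-eff$log_or, eff$se)  # mirrors every deviate
  fixed_r <- pool_fixed(rev_eff)
  dev_r <- (rev_eff$log_or - fixed_r$log_or) /
    sqrt(pmax(rev_eff$se^2 - fixed_r$se^2, 1e-12))
  expect_true(all(diff(dev_r) < 0))
  expect_equal(begg_test(rev_eff)$tau, -1)
  expect_error(begg_test(eff[1:2, ]), class = "insufficient_data")
})

test_that("funnel data passes points through and references the pooled estimate", {
  eff <- eff_df(c(0.1, 0.2, 0.3, 0.15), c(0.1, 0.2, 0.3, 0.25))
  fd <- funnel_data(eff)
  expect_equal(nrow(fd$points), 4L)
  expect_equal(fd$points$log_or, eff$log_or)
  expect_equal(fd$reference, pool_random(eff)$log_or)
})

test_that("leave-one-out produces k re-pooled results and flags fragile pools", {
  tab <- replicated_table(k = 5)
  s <- leave_one_out(tab, "rs0000001")
  expect_equal(nrow(s$leave_one_out), 5L)
  expect_true(all(s$leave_one_out$k == 4L))
  # identical studies: every omission gives the same pooled OR
  expect_equal(length(unique(round(s$leave_one_out$or, 12))), 1L)
  expect_true(s$robust)
  # re-pooling all k studies recovers the baseline
  expect_equal(pool_random(s$baseline$effects)$or, s$baseline$or_pooled)

  # planted outlier: its omission moves the pooled OR the most
  out_tab <- make_table(
    make_record("s1", pubmed_id = "PM1", case = c(260, 500, 240)),
    make_record("s2", pubmed_id = "PM2", case = c(255, 505, 240),
                control = c(245, 505, 250)),
    make_record("s3", pubmed_id = "PM3", case = c(262, 498, 240)),
    make_record("s4", pubmed_id = "PM4", case = c(520, 400, 80)))
  s2 <- leave_one_out(out_tab, "rs0000001")
  shift <- abs(log(s2$leave_one_out$or) - s2$baseline$log_or)
  expect_equal(s2$leave_one_out$omitted[which.max(shift)], "s4")
})

test_that("HWE sensitivity excludes exactly the planted violating study", {
  ok1 <- make_record("h1", pubmed_id = "P1", control = c(250, 500, 250),
                     case = c(300, 480, 220))
  ok2 <- make_record("h2", pubmed_id = "P2", control = c(248, 504, 248),
                     case = c(305, 470, 225))
  ok3 <- make_record("h3", pubmed_id = "P3", control = c(252, 496, 252),
                     case = c(298, 482, 220))
  viol <- make_record("h4", pubmed_id = "P4", control = c(400, 200, 400),
                      case = c(300, 480, 220))
  expect_true(hwe_test(c(400, 200, 400))$violated)  # construction check
  tab <- make_table(ok1, ok2, ok3, viol)
  s <- hwe_sensitivity(tab, "rs0000001")
  expect_equal(s$excluded_ids, "h4")
  expect_equal(s$hwe_excluded$k, 3L)
  # all passing: nothing excluded, no re-pooled subset
  s0 <- hwe_sensitivity(make_table(ok1, ok2, ok3), "rs0000001")
  expect_equal(length(s0$excluded_ids), 0L)
  expect_null(s0$hwe_excluded)
})
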