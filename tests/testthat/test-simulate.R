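test_that("simulated counts conserve arm sizes and the seed fixes the dataset", {
  cfg <- sim_config(k = 12, n_cases = 400, n_controls = 300,
                    theta = 0.2, tau2 = 0.01, seed = 5)
  tab <- simulate_dataset(cfg)
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$case_n_AA + tab$case_n_Aa + tab$case_n_aa == 400))
  expect_true(all(tab$control_n_AA + tab$control_n_Aa +
                    tab$control_n_aa == 300))
  # byte-identical CSV across runs with the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_study_table(simulate_dataset(cfg), p1)
  write_study_table(simulate_dataset(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  # per-study substreams: growing k leaves earlier studies unchanged
  bigger <- simulate_dataset(sim_config(k = 15, n_cases = 400,
                                        n_controls = 300, theta = 0.2,
                                        tau2 = 0.01, seed = 5))
  expect_equal(plain(bigger)[1:12, ], plain(tab)[1:12, ])
})

test_that("the case genotype law implies an allelic odds ratio of exactly exp(theta)", {
  for (p0 in c(0.1, 0.3, 0.5, 0.8)) {
    for (theta in c(-0.5, 0, 0.3, 1)) {
      pr <- genesynopsis:::.case_genotype_probs(p0, theta)
      p_case <- pr[1] + pr[2] / 2          # case effect-allele frequency
      or <- (p_case / (1 - p_case)) / (p0 / (1 - p0))
      expect_equal(or, exp(theta), tolerance = 1e-12)
    }
  }
})

test_that("a null study draws cases and controls from the same law", {
  pr <- genesynopsis:::.case_genotype_probs(0.3, 0)
  expect_equal(pr, c(0.09, 0.42, 0.49), tolerance = 1e-12)
  set.seed(2)
  rec <- simulate_study(sim_config(n_cases = 200000, n_controls = 200000,
                                   p0 = 0.3), study_theta = 0)
  case_freq <- (2 * rec$case_n_AA + rec$case_n_Aa) / 400000
  ctrl_freq <- (2 * rec$control_n_AA + rec$control_n_Aa) / 400000
  expect_equal(case_freq, ctrl_freq, tolerance = 0.01)
  expect_equal(case_freq, 0.3, tolerance = 0.01)
})

test_that("under tau2 = 0 the between-study Q has mean near its df", {
  qs <- sapply(1:200, function(r) {
    tab <- simulate_dataset(sim_config(k = 5, n_cases = 2000,
                                       n_controls = 2000, theta = 0.2,
                                       tau2 = 0, seed = 1000 + r))
    eff <- lapply(seq_len(nrow(tab)), function(i)
      study_odds_ratio(build_contrast(tab[i, ], "additive"),
                       study_id = tab$study_id[i]))
    cochran_q(eff)$q
  })
  # chi2(4): mean 4, sd sqrt(8); SE of the mean ~ 0.2
  expect_lt(abs(mean(qs) - 4), 0.6)
})

test_that("mean I2 rises with the between-study variance", {
  mean_i2 <- function(tau2, seeds) {
    mean(sapply(seeds, function(s) {
      tab <- simulate_dataset(sim_config(k = 10, n_cases = 1000,
                                         n_controls = 1000, theta = 0.2,
                                         tau2 = tau2, seed = s))
      meta_analyze(tab, "rs0000001")$i2
    }))
  }
  seeds <- 1:60
  i2s <- c(mean_i2(0, seeds), mean_i2(0.05, seeds), mean_i2(0.2, seeds))
  expect_true(all(diff(i2s) > 0))
})

test_that("significance censoring suppresses null studies and biases the funnel", {
  cfg <- sim_config(k = 40, n_cases = 300, n_controls = 300, theta = 0,
                    tau2 = 0, censor_prob = 1, censor_alpha = 0.05,
                    seed = 77)
  tab <- simulate_dataset(cfg)
  expect_lt(nrow(tab), 10)           # most null studies are non-significant
  expect_gt(attr(tab, "n_censored"), 30)
  # every survivor is nominally significant on the additive contrast
  ps <- sapply(seq_len(nrow(tab)), function(i) {
    e <- study_odds_ratio(build_contrast(tab[i, ], "additive"))
    2 * pnorm(-abs(e$log_or / e$se))
  })
  expect_true(all(ps < 0.05))
})
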