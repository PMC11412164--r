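test_that("quantile-probability summaries match brute-force order statistics", {
  tr <- data.frame(duration_ms = 2000, choice = "long",
                   rt_ms = c(300, 400, 500, 600, 700))
  qp <- suppressWarnings(qp_stats(tr))
  expect_equal(qp$q50[qp$choice == "long"], 500)
  expect_equal(qp$prop[qp$choice == "long"], 1)
  expect_true(all(is.na(qp[qp$choice == "short",
                           c("q10", "q30", "q50", "q70", "q90")])))

  set.seed(30)
  sim <- simulate_ddm_condition(ddm_params(v = 1, a = 1.8, t0 = 0.3),
                                n = 500)
  tr2 <- data.frame(duration_ms = 1000,
                    choice = ifelse(sim$choice == "upper", "long", "short"),
                    rt_ms = sim$rt * 1000, censored = sim$censored)
  qp2 <- qp_stats(tr2)
  for (ch in c("short", "long")) {
    rts <- tr2$rt_ms[!tr2$censored & tr2$choice == ch]
    got <- as.numeric(qp2[qp2$choice == ch,
                          c("q10", "q30", "q50", "q70", "q90")])
    expect_equal(got, oracle_quantile7(rts, c(.1, .3, .5, .7, .9)),
                 tolerance = 1e-10)
  }
  # quantiles non-decreasing; proportions sum to 1 within duration
  expect_true(all(diff(as.numeric(qp2[1, 5:9])) >= 0))
  expect_equal(sum(qp2$prop), 1)
})

test_that("QP fitting is deterministic and near-unbiased on Wiener data", {
  set.seed(31)
  sim <- simulate_ddm_condition(ddm_params(v = 1.5, a = 1.6, t0 = 0.3),
                                n = 4000)
  tr <- data.frame(duration_ms = 2000,
                   choice = ifelse(sim$choice == "upper", "long", "short"),
                   rt_ms = sim$rt * 1000, censored = sim$censored)
  f1 <- fit_ddm_condition(tr, fix_alpha = 2, n_starts = 2, seed = 4)
  f2 <- fit_ddm_condition(tr, fix_alpha = 2, n_starts = 2, seed = 4)
  expect_identical(f1[c("v", "a", "z", "t0", "objective")],
                   f2[c("v", "a", "z", "t0", "objective")])
  expect_lt(abs(f1$v - 1.5) / 1.5, 0.15)
  expect_lt(abs(f1$a - 1.6) / 1.6, 0.15)
  expect_lt(abs(f1$t0 - 0.3), 0.05)
})

test_that("null-drift data yield a near-zero drift estimate", {
  set.seed(32)
  sim <- simulate_ddm_condition(ddm_params(v = 0, a = 1.6, t0 = 0.3),
                                n = 3000)
  tr <- data.frame(duration_ms = 2000,
                   choice = ifelse(sim$choice == "upper", "long", "short"),
                   rt_ms = sim$rt * 1000, censored = sim$censored)
  f <- fit_ddm_condition(tr, fix_alpha = 2, n_starts = 2, seed = 5)
  expect_lt(abs(f$v), 0.15 * 1.5)   # below 15% of a typical drift
})

test_that("recovery is close to unbiased over a grid of Wiener conditions", {
  set.seed(33)
  rel_v <- c(); rel_a <- c()
  for (i in 1:12) {
    v <- runif(1, 0.8, 2.5); a <- runif(1, 1.2, 2.0); t0 <- runif(1, .25, .4)
    sim <- simulate_ddm_condition(ddm_params(v = v, a = a, t0 = t0),
                                  n = 5000)
    tr <- data.frame(duration_ms = 2000,
                     choice = ifelse(sim$choice == "upper", "long", "short"),
                     rt_ms = sim$rt * 1000, censored = sim$censored)
    f <- fit_ddm_condition(tr, fix_alpha = 2, n_starts = 3, seed = i)
    rel_v <- c(rel_v, (f$v - v) / v)
    rel_a <- c(rel_a, (f$a - a) / a)
  }
  expect_lt(abs(median(rel_v)), 0.05)
  expect_lt(abs(median(rel_a)), 0.05)
})

test_that("freeing alpha on Wiener data does not absorb spurious structure", {
  set.seed(34)
  sim <- simulate_ddm_condition(ddm_params(v = 1.5, a = 1.6, t0 = 0.3),
                                n = 4000)
  tr <- data.frame(duration_ms = 2000,
                   choice = ifelse(sim$choice == "upper", "long", "short"),
                   rt_ms = sim$rt * 1000, censored = sim$censored)
  f_free <- fit_ddm_condition(tr, fix_alpha = NULL, n_starts = 2, seed = 6)
  expect_gte(f_free$alpha, 1.7)   # estimate stays near the Gaussian end
  expect_lt(abs(f_free$v - 1.5) / 1.5, 0.25)
})

test_that("parameter slopes and their correlations behave as planted", {
  d <- data.frame(subject = rep("s1", 3), frequency_Hz = c(4, 8, 12),
                  v = c(2, 1.5, 1), a = c(1.4, 1.4, 1.4))
  sl <- parameter_slopes(d)
  expect_equal(sl$slope_v, -0.5)
  expect_equal(sl$slope_a, 0)

  # negatively coupled slope pairs recover negative correlations
  set.seed(35)
  hits <- replicate(200, {
    x <- rnorm(24)
    y <- -0.5 * x + rnorm(24, sd = sqrt(1 - 0.25))
    sc <- slope_correlations(x, y)
    all(sc$estimate < 0)
  })
  expect_gte(mean(hits), 0.90)
})

test_that("recovery reports align parameters by name", {
  rep <- recovery_report(ddm_params(v = 1.5, a = 1.6, t0 = 0.3),
                         list(v = 1.4, a = 1.7, z = 0.5, t0 = 0.32,
                              alpha = 2))
  expect_equal(rep$rel_error[rep$param == "v"], abs(1.4 - 1.5) / 1.5)
  expect_error(recovery_report(list(q = 1), list(r = 2)), "shared")
})
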