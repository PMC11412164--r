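test_that("one-factor rm-ANOVA reproduces the hand-computed worked example", {
  d <- data.frame(s = rep(1:2, each = 3), a = rep(1:3, 2),
                  y = c(1, 2, 3, 2, 3, 5))
  res <- rm_anova(d, "y", "s", "a")
  expect_equal(res$F, 19, tolerance = 1e-10)
  expect_equal(c(res$df1, res$df2), c(2, 2))
  ora <- oracle_rm_anova_1way(d)
  expect_equal(res$F, ora$F, tolerance = 1e-8)
  expect_equal(res$p, ora$p, tolerance = 1e-8)
})

test_that("rm-ANOVA handles constant data and shift invariance", {
  d <- expand.grid(s = 1:3, a = 1:2, b = 1:3)
  d$y <- 5
  res <- rm_anova(d, "y", "s", c("a", "b"))
  expect_true(all(res$F == 0))

  set.seed(14)
  d$y <- rnorm(nrow(d))
  r1 <- rm_anova(d, "y", "s", c("a", "b"))
  d2 <- d; d2$y <- d2$y + 100
  r2 <- rm_anova(d2, "y", "s", c("a", "b"))
  expect_equal(r1$F, r2$F, tolerance = 1e-8)

  # unbalanced designs are refused, not imputed
  expect_error(rm_anova(d[-1, ], "y", "s", c("a", "b")), "balanced")
})

test_that("two-way rm-ANOVA matches the aov projection oracle on random tables", {
  set.seed(15)
  for (i in 1:6) {
    ns <- sample(2:5, 1); na <- sample(2:3, 1); nb <- sample(2:3, 1)
    d <- expand.grid(s = seq_len(ns), a = seq_len(na), b = seq_len(nb))
    d$y <- rnorm(nrow(d))
    mine <- rm_anova(d, "y", "s", c("a", "b"))
    ora <- oracle_rm_anova_2way(d)
    expect_equal(mine$F[mine$effect == "a"], ora$A, tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "b"], ora$B, tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "a:b"], ora$AB, tolerance = 1e-8)
  }
})

test_that("two-way rm-ANOVA holds its nominal type-I rate under the null", {
  set.seed(16)
  rej <- replicate(1000, {
    d <- expand.grid(s = 1:24, a = 1:3, b = 1:3)
    d$y <- rnorm(nrow(d))
    res <- rm_anova(d, "y", "s", c("a", "b"))
    res$p[1] < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Greenhouse-Geisser epsilon stays in range and shrinks p", {
  set.seed(17)
  d <- expand.grid(s = 1:10, a = 1:3)
  d$y <- rnorm(nrow(d)) + 0.5 * d$a
  res <- rm_anova(d, "y", "s", "a", gg_correction = TRUE)
  expect_true(res$gg_epsilon >= 0.5 && res$gg_epsilon <= 1)
  expect_gte(res$p_gg, res$p)
})

test_that("linear contrasts reproduce hand-computed t and Cohen's d", {
  # per-subject contrast scores (y3 - y1) of 0.5, 1.0, 1.5
  d <- expand.grid(subject = 1:3, level = 1:3)
  d$y <- c(0, 0, 0,  0, 0, 0,  0.5, 1.0, 1.5)
  lc <- linear_contrast(d, "y", "subject", "level")
  expect_equal(lc$t, 1 / (0.5 / sqrt(3)), tolerance = 1e-10)  # 3.4641
  expect_equal(lc$cohen_d, 2, tolerance = 1e-12)

  # scores symmetric about zero: t = 0
  d$y <- c(0, 0, 0,  0, 0, 0,  -1, 0, 1)
  expect_equal(linear_contrast(d, "y", "subject", "level")$t, 0)

  # reversing the level order flips the sign, preserves magnitude
  d$y <- c(0, 0, 0, 0.2, 0.1, 0.4, 0.9, 1.2, 1.4)
  fwd <- linear_contrast(d, "y", "subject", "level")
  d2 <- d; d2$level <- 4 - d2$level
  rev <- linear_contrast(d2, "y", "subject", "level")
  expect_equal(rev$t, -fwd$t, tolerance = 1e-10)

  dz <- expand.grid(subject = 1:3, level = 1:3); dz$y <- dz$level
  expect_error(linear_contrast(dz, "y", "subject", "level"),
               "zero variance")
})

test_that("simple main effects localise a planted interaction", {
  # frequency effect planted only at the highest amplitude
  set.seed(18)
  hit <- replicate(200, {
    d <- expand.grid(s = 1:24, freq = 1:3, amp = 1:3)
    d$y <- rnorm(nrow(d), sd = 0.5) + ifelse(d$amp == 3, 0.3 * d$freq, 0)
    sme <- simple_main_effects(d, "y", "s", "freq", "amp")
    which.min(sme$p) == 3
  })
  expect_gte(mean(hit), 0.90)
  d <- expand.grid(s = 1:4, freq = 1:3, amp = 1:3); d$y <- rnorm(nrow(d))
  expect_equal(nrow(simple_main_effects(d, "y", "s", "freq", "amp")), 3)
})

test_that("simple-main-effect probes are calibrated under the null", {
  set.seed(19)
  rej <- replicate(1000, {
    d <- expand.grid(s = 1:24, freq = 1:3)
    d$y <- rnorm(nrow(d))
    rm_anova(d, "y", "s", "freq")$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("direction bins follow the documented boundary convention", {
  expect_equal(direction_bins(c(0, 60, 61, 90, 120, 120.5, 179.9)),
               c(1L, 1L, 2L, 2L, 2L, 3L, 3L))
  expect_error(direction_bins(180), "\\[0, 180\\)")
  expect_error(direction_bins(-1), "\\[0, 180\\)")
  set.seed(20)
  b <- direction_bins(runif(9000, 0, 180))
  expect_true(all(abs(table(b) / 9000 - 1 / 3) < 0.03))
})

test_that("Mann-Whitney slope comparison: U, rank-biserial, exactness", {
  sep <- slope_comparison(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$rank_biserial, 1)

  il <- slope_comparison(c(1, 3), c(2, 4))
  expect_equal(il$U, 1)
  expect_equal(il$rank_biserial, 0.5)
  expect_equal(il$p, oracle_mw_exact_p(c(1, 3), c(2, 4)), tolerance = 1e-12)

  # swapping the groups flips the rank-biserial sign
  ab <- slope_comparison(c(0.1, 0.5, 0.9), c(0.3, 0.4, 1.2))
  ba <- slope_comparison(c(0.3, 0.4, 1.2), c(0.1, 0.5, 0.9))
  expect_equal(ab$rank_biserial, -ba$rank_biserial)

  expect_error(slope_comparison(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals full permutation enumeration", {
  set.seed(21)
  for (i in 1:10) {
    x <- round(rnorm(sample(3:5, 1)), 3)
    y <- round(rnorm(sample(3:5, 1)) + 0.5, 3)
    res <- slope_comparison(x, y)
    expect_true(res$exact)
    expect_equal(res$p, oracle_mw_exact_p(x, y), tolerance = 1e-10)
  }
})

test_that("per-subject slopes are OLS on rank-coded levels", {
  d <- data.frame(subject = rep(c("p1", "p2"), each = 3),
                  level = rep(1:3, 2),
                  y = c(2, 1.5, 1, 4, 4, 4))
  sl <- per_subject_slopes(d, "y", "subject", "level")
  expect_equal(sl$slope, c(-0.5, 0))
})
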