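test_that("RT filtering applies the window first, then the per-subject 3-SD log rule", {
  tr <- data.frame(subject = "s1", rt_ms = c(150, 250, 400, 2500, 600))
  kept <- filter_rts(tr)
  expect_equal(nrow(kept), 3)
  excl <- attr(kept, "exclusions")
  expect_equal(excl$n_window, 2)
  expect_equal(excl$n_sd, 0)

  # identical RTs: zero SD, the 3-SD rule removes nothing
  eq <- data.frame(subject = "s2", rt_ms = rep(500, 20))
  expect_equal(nrow(filter_rts(eq)), 20)

  # a 1900 ms trial inside the window but > 3 SD out on the log scale
  set.seed(5)
  base <- exp(rnorm(19, log(500), 0.1))
  tr3 <- data.frame(subject = "s3", rt_ms = c(base, 1900))
  lr <- log(tr3$rt_ms)
  stopifnot(abs(lr[20] - mean(lr)) > 3 * sd(lr))  # oracle: manual z-score
  kept3 <- filter_rts(tr3)
  expect_equal(nrow(kept3), 19)
  expect_false(1900 %in% kept3$rt_ms)
  expect_equal(attr(kept3, "exclusions")$n_sd, 1)
})

test_that("filtering is idempotent and flags near-empty subjects", {
  set.seed(6)
  tr <- data.frame(subject = rep(c("a", "b"), c(50, 2)),
                   rt_ms = c(exp(rnorm(50, log(600), 0.2)), 500, 700))
  k1 <- suppressWarnings(filter_rts(tr))
  k2 <- suppressWarnings(filter_rts(k1))
  expect_equal(nrow(k1), nrow(k2))
  expect_equal(attr(k2, "exclusions")$n_window, c(0, 0))
  expect_warning(filter_rts(tr), "< 3 surviving")
  expect_error(filter_rts(data.frame(subject = 1, rt_ms = -5)), "positive")
})

test_that("the Gumbel curve and its quantile inverse are mutually consistent", {
  m <- log10(2000); s <- 0.1
  expect_equal(pgumbel_dur(10^m, m, s), 1 - exp(-1), tolerance = 1e-12)
  # closed-form median: 10^(m + s log(log 2)) -- hand-evaluated
  expect_equal(qgumbel_dur(0.5, m, s), 1838.15, tolerance = 1e-4)
  expect_equal(qgumbel_dur(0.5, m, s), oracle_gumbel_q(0.5, m, s))
  for (p in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    expect_equal(pgumbel_dur(qgumbel_dur(p, m, s), m, s), p,
                 tolerance = 1e-10)
  }
  # s -> 0 approaches a step at 10^m
  expect_lt(pgumbel_dur(10^m * 0.99, m, 1e-4), 1e-10)
  expect_gt(pgumbel_dur(10^m * 1.01, m, 1e-4), 1 - 1e-10)
  expect_error(qgumbel_dur(1.2, m, s), "p")
})

test_that("MLE recovers a known Gumbel observer at large n", {
  set.seed(7)
  tr <- make_gumbel_trials(log10(2000), 0.1, n_per_dur = 2000)
  fit <- fit_psychometric(tr)
  # generating quartiles: F^-1(.75) = 10^(m + 0.3266 s), F^-1(.25) = 10^(m - 1.2459 s)
  bp_true <- oracle_gumbel_q(0.5, log10(2000), 0.1)
  cv_true <- (oracle_gumbel_q(0.75, log10(2000), 0.1) -
                oracle_gumbel_q(0.25, log10(2000), 0.1)) / (2 * bp_true)
  expect_equal(fit$bp_ms, bp_true, tolerance = 0.02)
  expect_equal(fit$cv, cv_true, tolerance = 0.02)
  expect_equal(cv_true, 0.17817, tolerance = 1e-4)
})

test_that("separated data bracket the BP and flag the floored scale", {
  durs <- c(1000, 1260, 1580, 2520, 3170, 4000)  # none at 2,000 ms
  tr <- data.frame(duration_ms = rep(durs, each = 10),
                   choice = rep(ifelse(durs > 2000, "long", "short"),
                                each = 10))
  fit <- fit_psychometric(tr)
  expect_true(fit$bp_ms > 1580 && fit$bp_ms < 2520)
  expect_true("s_floor" %in% fit$flags)
})

test_that("reversed response labels are caught by the orientation guard", {
  set.seed(8)
  tr <- make_gumbel_trials(log10(2000), 0.1, n_per_dur = 100)
  tr$choice <- ifelse(tr$choice == "long", "short", "long")
  fit <- fit_psychometric(tr)
  expect_true("non_monotonic" %in% fit$flags)
})

test_that("CV is invariant to uniform rescaling of all durations", {
  set.seed(9)
  tr <- make_gumbel_trials(log10(2000), 0.12, n_per_dur = 300)
  f1 <- fit_psychometric(tr)
  tr2 <- tr; tr2$duration_ms <- tr2$duration_ms * 3
  f2 <- fit_psychometric(tr2)
  expect_equal(f1$cv, f2$cv, tolerance = 1e-4)
  expect_equal(f2$bp_ms / f1$bp_ms, 3, tolerance = 1e-4)
})

test_that("condition-wise fitting yields the design's cell counts", {
  tt <- generate_experiment("auditory", n_subjects = 1, seed = 13)
  fits <- curves_by_condition(tt)          # unfiltered: exactly 42 per cell
  expect_equal(nrow(fits), 9)
  expect_true(all(fits$n == 42))
  coll <- curves_by_condition(tt, group_vars = c("subject", "frequency_Hz"))
  expect_equal(nrow(coll), 3)
  expect_true(all(coll$n == 126))
  # a sparse grouping is flagged low_n rather than silently trusted
  sparse <- curves_by_condition(tt[tt$duration_ms %in% c(1000, 4000), ])
  expect_true(all(grepl("low_n", sparse$flags)))
})

test_that("the fitter is as efficient as an independent GLM route at session size", {
  # the cumulative Gumbel on log10 duration is exactly a binomial GLM with
  # cloglog link, so glm() is an independent maximum-likelihood oracle;
  # at 42 trials/curve both routes should sit on the same error floor
  set.seed(10)
  m <- log10(2000); s <- 0.1
  bp_true <- oracle_gumbel_q(0.5, m, s)
  cv_true <- (oracle_gumbel_q(0.75, m, s) - oracle_gumbel_q(0.25, m, s)) /
    (2 * bp_true)
  errs <- t(replicate(200, {
    tr <- make_gumbel_trials(m, s, n_per_dur = 6)   # 42-trial curve
    fit <- fit_psychometric(tr)
    g <- suppressWarnings(
      glm((choice == "long") ~ log10(duration_ms),
          family = binomial("cloglog"), data = tr))
    cg <- unname(coef(g))
    s_g <- 1 / cg[2]; m_g <- -cg[1] * s_g
    bp_g <- oracle_gumbel_q(0.5, m_g, s_g)
    cv_g <- (oracle_gumbel_q(0.75, m_g, s_g) -
               oracle_gumbel_q(0.25, m_g, s_g)) / (2 * bp_g)
    c(bp = abs(fit$bp_ms - bp_true) / bp_true,
      cv = abs(fit$cv - cv_true) / cv_true,
      bp_glm = abs(bp_g - bp_true) / bp_true,
      cv_glm = abs(cv_g - cv_true) / cv_true)
  }))
  med <- apply(errs, 2, median, na.rm = TRUE)
  expect_lt(abs(med["bp"] - med["bp_glm"]), 0.01)
  expect_lt(abs(med["cv"] - med["cv_glm"]), 0.04)
})

test_that("BP and CV errors shrink to tolerance as trials per curve grow", {
  set.seed(12)
  m <- log10(2000); s <- 0.1
  bp_true <- oracle_gumbel_q(0.5, m, s)
  cv_true <- (oracle_gumbel_q(0.75, m, s) - oracle_gumbel_q(0.25, m, s)) /
    (2 * bp_true)
  err_at <- function(n_per_dur, n_rep) {
    e <- t(replicate(n_rep, {
      fit <- fit_psychometric(make_gumbel_trials(m, s, n_per_dur))
      c(bp = abs(fit$bp_ms - bp_true) / bp_true,
        cv = abs(fit$cv - cv_true) / cv_true)
    }))
    apply(e, 2, median)
  }
  e42 <- err_at(6, 150)     # one condition cell
  e420 <- err_at(60, 150)   # ten sessions' worth
  expect_lt(e420["bp"], e42["bp"])   # consistency
  expect_lt(e420["cv"], e42["cv"])
  expect_lt(e420["bp"], 0.03)        # tolerances reached at 420 trials
  expect_lt(e420["cv"], 0.10)
})
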