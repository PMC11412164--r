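# Independent oracles used across the suite.  Each is deliberately written
# from first principles (closed forms, numerical integration, brute-force
# enumeration) rather than through the package's own code paths.

# Wiener absorption probability at the upper boundary, unit diffusion.
oracle_p_upper <- function(v, a, z) {
  if (abs(v) < 1e-12) return(z)
  (1 - exp(-2 * v * z * a)) / (1 - exp(-2 * v * a))
}

# CDF of the package's symmetric alpha-stable variates (stable scale
# 1/sqrt(2)) by numerical inversion of the characteristic function
# phi(t) = exp(-|c t|^alpha).
oracle_stable_cdf <- function(x, alpha, scale = 1 / sqrt(2)) {
  vapply(x, function(xx) {
    integrand <- function(t) sin(t * xx) / t * exp(-(scale * t)^alpha)
    0.5 + (1 / pi) * stats::integrate(integrand, 0, Inf,
                                      rel.tol = 1e-9,
                                      subdivisions = 2000L)$value
  }, numeric(1))
}

# Brute-force type-7 quantile (sort + linear interpolation on (n-1)p + 1).
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }, numeric(1))
}

# Repeated-measures ANOVA through stats::aov Error() strata — an
# independent route to the same classical decomposition.
oracle_rm_anova_1way <- function(df) {
  df$s <- factor(df$s); df$a <- factor(df$a)
  sm <- summary(stats::aov(y ~ a + Error(s / a), data = df))
  tab <- sm[["Error: s:a"]][[1]]
  list(F = tab["a", "F value"], p = tab["a", "Pr(>F)"])
}

oracle_rm_anova_2way <- function(df) {
  df$s <- factor(df$s); df$a <- factor(df$a); df$b <- factor(df$b)
  sm <- summary(stats::aov(y ~ a * b + Error(s / (a * b)), data = df))
  list(
    A = sm[["Error: s:a"]][[1]]["a", "F value"],
    B = sm[["Error: s:b"]][[1]]["b", "F value"],
    AB = sm[["Error: s:a:b"]][[1]]["a:b", "F value"])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_stat(x, y)
  n2 <- length(y)
  u_all <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(u_all - n1 * n2 / 2) >= abs(u_obs - n1 * n2 / 2) - 1e-12)
}

# Cumulative Gumbel quantile, written out independently of the package.
oracle_gumbel_q <- function(p, m, s) 10^(m + s * log(-log(1 - p)))

# Generate one temporal-bisection curve's worth of binomial responses from
# a known Gumbel observer.
make_gumbel_trials <- function(m, s, n_per_dur,
                               durations = c(1000, 1260, 1580, 2000,
                                             2520, 3170, 4000)) {
  d <- rep(durations, each = n_per_dur)
  p <- 1 - exp(-exp((log10(d) - m) / s))
  data.frame(duration_ms = d,
             choice = ifelse(stats::runif(length(d)) < p, "long", "short"),
             stringsAsFactors = FALSE)
}
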