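#' Levy-flight drift-diffusion parameters
#'
#' The five-parameter configuration of the accumulation-to-bound model:
#' drift rate `v` (signed; negative drives toward the lower/"short"
#' boundary), boundary separation `a`, relative starting point `z`
#' (fraction of `a`), nondecision time `t0` (seconds), and the stable-noise
#' exponent `alpha`.  `alpha = 2` gives the classic Wiener diffusion with
#' Gaussian momentary noise; lower values interpolate toward Cauchy noise
#' with heavy-tailed "jumps" in the accumulated evidence.
#'
#' @param v Drift rate (evidence/s); may be a named vector with one drift
#'   per stimulus duration.
#' @param a Boundary separation (> 0).
#' @param z Relative starting point, in (0, 1); 0.5 is unbiased.
#' @param t0 Nondecision time in seconds (>= 0).
#' @param alpha Stable exponent, in (1, 2].
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(v = 1, a = 2, z = 0.5, t0 = 0.3)
#' @export
ddm_params <- function(v, a, z = 0.5, t0 = 0.3, alpha = 2) {
  stopifnot(is.numeric(v), length(v) >= 1L)
  if (!is.finite(a) || a <= 0) stop("'a' must be > 0", call. = FALSE)
  if (!is.finite(z) || z <= 0 || z >= 1) {
    stop("'z' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(t0) || t0 < 0) stop("'t0' must be >= 0", call. = FALSE)
  .check_alpha(alpha)
  structure(list(v = v, a = a, z = z, t0 = t0, alpha = alpha),
            class = "ddm_params")
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 1 || alpha > 2) {
    stop("'alpha' must lie in (1, 2]", call. = FALSE)
  }
  invisible(alpha)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "<ddm_params> a = %g, z = %g, t0 = %g s, alpha = %g\n  v: %s\n",
    x$a, x$z, x$t0, x$alpha,
    paste(signif(x$v, 4), collapse = ", ")))
  invisible(x)
}

#' Symmetric alpha-stable random variates
#'
#' Draws i.i.d. symmetric (beta = 0) alpha-stable samples by the
#' Chambers-Mallows-Stuck construction, rescaled by \eqn{1/\sqrt{2}} so
#' that `alpha = 2` returns exactly standard normal (unit-variance)
#' variates.  Uses R's global RNG stream, so `set.seed()` makes draws
#' reproducible.
#'
#' @param n Number of variates (>= 1).
#' @param alpha Stable exponent, in (1, 2].
#' @return Numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' x <- rstable_sym(1000, alpha = 2)  # standard normal sample
#' @export
rstable_sym <- function(n, alpha) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  .check_alpha(alpha)
  cpp_rstable(as.integer(n), alpha)
}

#' Simulate one Levy-flight diffusion trial
#'
#' Euler first-passage integration: evidence starts at `z*a` and evolves by
#' `x <- x + v*dt + dt^(1/alpha) * xi` with `xi` from [rstable_sym], until
#' it crosses the upper boundary `a` ("long") or the lower boundary 0
#' ("short").  Trials whose decision time exceeds `max_t` are flagged
#' censored, never dropped.
#'
#' @param params A [ddm_params] object (scalar `v`).
#' @param dt Integration step in seconds (default 0.001).
#' @param max_t Decision-time cap in seconds (default 10).
#' @return A one-row data.frame with `choice` ("upper"/"lower" or NA),
#'   `rt` (seconds, `> t0`), and `censored`.
#' @export
simulate_ddm_trial <- function(params, dt = 0.001, max_t = 10) {
  stopifnot(inherits(params, "ddm_params"), dt > 0)
  sim <- cpp_simulate_levy(params$v[1L], params$a, params$z, params$t0,
                           params$alpha, dt, max_t)
  data.frame(choice = c("lower", "upper")[sim$choice + 1L],
             rt = sim$rt, censored = sim$censored,
             stringsAsFactors = FALSE)
}

#' Simulate a block of Levy-flight diffusion trials
#'
#' Runs `n` independent trials at fixed parameters and attaches a summary
#' (upper-choice proportion, RT quantiles of the uncensored trials, and the
#' censoring count).
#'
#' @param params A [ddm_params] object; if `v` has length > 1 the first
#'   element is used (see [simulate_scaling_study] for per-duration drifts).
#' @param n Number of trials (>= 1).
#' @param dt,max_t As in [simulate_ddm_trial].
#' @return A data.frame of `n` rows (`choice`, `rt`, `censored`) with a
#'   `"summary"` attribute (list: `p_upper`, `rt_quantiles`, `n_censored`).
#' @examples
#' set.seed(7)
#' sim <- simulate_ddm_condition(ddm_params(v = 1, a = 2), n = 500)
#' attr(sim, "summary")$p_upper
#' @export
simulate_ddm_condition <- function(params, n, dt = 0.001, max_t = 10) {
  stopifnot(inherits(params, "ddm_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  sim <- cpp_simulate_levy(rep(params$v[1L], n), params$a, params$z,
                           params$t0, params$alpha, dt, max_t)
  out <- data.frame(choice = c("lower", "upper")[sim$choice + 1L],
                    rt = sim$rt, censored = sim$censored,
                    stringsAsFactors = FALSE)
  ok <- !out$censored
  attr(out, "summary") <- list(
    p_upper = mean(sim$choice[ok] == 1L),
    rt_quantiles = stats::quantile(out$rt[ok],
                                   probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                   names = TRUE),
    n_censored = sum(!ok))
  out
}

#' Closed-form Wiener absorption probability
#'
#' For `alpha = 2` (unit-diffusion Wiener process) the probability of
#' absorbing at the upper boundary from absolute start `z_abs = z*a` is
#' \deqn{P(upper) = (1 - e^{-2 v z a}) / (1 - e^{-2 v a}),}
#' with the limit `z` as `v -> 0`.  Used as the analytic oracle for the
#' simulator.
#'
#' @param v Drift rate.
#' @param a Boundary separation (> 0).
#' @param z Relative starting point in (0, 1).
#' @return Absorption probability at the upper boundary.
#' @examples
#' wiener_p_upper(v = 1, a = 2, z = 0.5)  # 0.8808
#' @export
wiener_p_upper <- function(v, a, z = 0.5) {
  stopifnot(a > 0, z > 0, z < 1)
  if (abs(v) < 1e-12) return(z)
  expm1(-2 * v * z * a) / expm1(-2 * v * a)
}

#' Closed-form Wiener mean decision time
#'
#' Mean first-passage time to either boundary of the unit-diffusion Wiener
#' process started at `z*a`, excluding nondecision time: the solution of
#' the exit-time ODE \eqn{\tfrac12 m'' + v m' = -1} with absorbing ends,
#' \deqn{E[T] = \frac{a}{v}\,\frac{1 - e^{-2vza}}{1 - e^{-2va}} -
#'   \frac{za}{v}} for `v != 0`, and `za (a - za)` at `v = 0`.
#'
#' @inheritParams wiener_p_upper
#' @return Mean decision time in seconds.
#' @export
wiener_mean_dt <- function(v, a, z = 0.5) {
  stopifnot(a > 0, z > 0, z < 1)
  za <- z * a
  if (abs(v) < 1e-9) return(za * (a - za))
  (a / v) * (expm1(-2 * v * za) / expm1(-2 * v * a)) - za / v
}

#' Three-level parameter-scaling simulation study
#'
#' Simulates the bisection task at three levels of one diffusion parameter:
#' level 1 uses the base parameters, levels 2 and 3 multiply the target
#' parameter by 0.75 and 0.75^2 while holding everything else fixed (e.g. a
#' base drift of 2 becomes 1.5 then 1.125).  Each level is simulated for
#' every stimulus duration, then summarised by a pooled psychometric fit
#' (bisection point and coefficient of variation) and mean RT per duration.
#' When the target is `alpha`, scaled values that would leave (1, 2] are
#' clipped to 1.01 with a warning.
#'
#' @param base A [ddm_params] with one drift per stimulus duration (named
#'   or in the order of `durations_ms`).
#' @param target One of `"v"`, `"a"`, `"alpha"`.
#' @param durations_ms Stimulus durations (ms) matching `base$v`.
#' @param n_per_level Total trials per level, split evenly over durations.
#' @param dt,max_t Integration settings.
#' @param scale Per-level multiplier (default 0.75).
#' @return List of class `scaling_study` with elements `target`, `levels`
#'   (parameter value per level), `trials` (per-level trial tables),
#'   `summary` (data.frame: level, cv, bp_ms, mean RT per duration).
#' @examples
#' \donttest{
#' base <- ddm_params(v = bisection_drifts(2), a = 1.5)
#' set.seed(11)
#' st <- simulate_scaling_study(base, "v", n_per_level = 7000)
#' st$summary
#' }
#' @export
simulate_scaling_study <- function(base, target = c("v", "a", "alpha"),
                                   durations_ms = bisection_durations(),
                                   n_per_level = 50000, dt = 0.001,
                                   max_t = 10, scale = 0.75) {
  target <- match.arg(target)
  stopifnot(inherits(base, "ddm_params"))
  n_dur <- length(durations_ms)
  if (length(base$v) != n_dur) {
    stop("'base$v' must supply one drift per duration", call. = FALSE)
  }
  n_per_dur <- max(1L, floor(n_per_level / n_dur))
  factors <- scale^(0:2)

  levels <- lapply(factors, function(f) {
    p <- base
    if (target == "v") p$v <- base$v * f
    if (target == "a") p$a <- base$a * f
    if (target == "alpha") {
      al <- base$alpha * f
      if (al <= 1) {
        warning("scaled alpha left (1, 2]; clipped to 1.01", call. = FALSE)
        al <- 1.01
      }
      p$alpha <- al
    }
    p
  })

  trials <- vector("list", 3L)
  summ <- vector("list", 3L)
  for (lev in 1:3) {
    p <- levels[[lev]]
    v_per_trial <- rep(p$v, each = n_per_dur)
    sim <- cpp_simulate_levy(v_per_trial, p$a, p$z, p$t0, p$alpha, dt, max_t)
    tab <- data.frame(
      level = lev,
      duration_ms = rep(durations_ms, each = n_per_dur),
      choice = ifelse(is.na(sim$choice), NA_character_,
                      c("short", "long")[sim$choice + 1L]),
      rt_ms = sim$rt * 1000,
      censored = sim$censored,
      stringsAsFactors = FALSE)
    ok <- !tab$censored
    fit <- fit_psychometric(tab[ok, ])
    rt_by_dur <- tapply(tab$rt_ms[ok], tab$duration_ms[ok], mean)
    trials[[lev]] <- tab
    rt_cols <- as.data.frame(t(as.numeric(rt_by_dur)))
    names(rt_cols) <- paste0("rt_", durations_ms)
    summ[[lev]] <- cbind(data.frame(
      level = lev,
      param_value = switch(target, v = max(abs(p$v)), a = p$a,
                           alpha = p$alpha),
      bp_ms = fit$bp_ms, cv = fit$cv,
      mean_rt_ms = mean(tab$rt_ms[ok])), rt_cols)
  }
  structure(list(target = target, levels = levels, trials = trials,
                 summary = do.call(rbind, summ)),
            class = "scaling_study")
}

#' @export
print.scaling_study <- function(x, ...) {
  cat(sprintf("<scaling_study> target = %s (x0.75 cascade)\n", x$target))
  print(x$summary[, c("level", "param_value", "bp_ms", "cv", "mean_rt_ms")])
  invisible(x)
}

#' The seven log-spaced bisection durations (ms)
#'
#' @return `c(1000, 1260, 1580, 2000, 2520, 3170, 4000)`.
#' @export
bisection_durations <- function() {
  c(1000, 1260, 1580, 2000, 2520, 3170, 4000)
}

#' Default per-duration drift rates for the bisection task
#'
#' Signed drifts antisymmetric in log duration about the geometric mean of
#' the stimulus set (2,000 ms): negative for short stimuli, positive for
#' long ones, scaled so the extreme durations get `+/- v_max`.
#'
#' @param v_max Absolute drift at the extreme durations.
#' @param durations_ms Stimulus durations.
#' @return Named numeric vector of drifts, one per duration.
#' @examples
#' bisection_drifts(2)
#' @export
bisection_drifts <- function(v_max = 2, durations_ms = bisection_durations()) {
  ld <- log(durations_ms)
  mid <- (min(ld) + max(ld)) / 2
  v <- v_max * (ld - mid) / (max(ld) - mid)
  names(v) <- durations_ms
  v
}
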