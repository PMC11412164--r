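#' Quantile-probability summary of choice/RT data
#'
#' Deterministic sufficient statistics for quantile-probability fitting:
#' for every stimulus duration and each choice, the response proportion,
#' the RT quantiles at probabilities {0.1, 0.3, 0.5, 0.7, 0.9} (type-7
#' linear interpolation), and the trial count.  A duration with no trials
#' of one choice gets `NA` quantiles for that choice.
#'
#' @param trials Trial table with `duration_ms`, `choice`
#'   (`"short"`/`"long"`), `rt_ms`; censored rows (if a `censored` column
#'   is present) are excluded.
#' @param probs Quantile probabilities.
#' @param min_n Warn when a duration has fewer total trials than this.
#' @return Data.frame of class `qp_stats`: `duration_ms`, `choice`, `n`,
#'   `prop` (of that duration's trials), and one column per quantile.
#' @examples
#' tr <- data.frame(duration_ms = 2000, choice = "long",
#'                  rt_ms = c(300, 400, 500, 600, 700))
#' qp_stats(tr)
#' @export
qp_stats <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                     min_n = 10) {
  stopifnot(is.data.frame(trials),
            all(c("duration_ms", "choice", "rt_ms") %in% names(trials)))
  if ("censored" %in% names(trials)) {
    trials <- trials[!trials$censored, , drop = FALSE]
  }
  trials <- trials[!is.na(trials$choice), , drop = FALSE]
  durs <- sort(unique(trials$duration_ms))
  rows <- list()
  for (d in durs) {
    sub <- trials[trials$duration_ms == d, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning(sprintf("duration %g has only %d trials", d, nrow(sub)),
              call. = FALSE)
    }
    for (ch in c("short", "long")) {
      rts <- sub$rt_ms[sub$choice == ch]
      q <- if (length(rts) > 0L) {
        stats::quantile(rts, probs = probs, type = 7, names = FALSE)
      } else rep(NA_real_, length(probs))
      row <- data.frame(duration_ms = d, choice = ch, n = length(rts),
                        prop = length(rts) / nrow(sub),
                        stringsAsFactors = FALSE)
      row[paste0("q", probs * 100)] <- as.list(q)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qp_stats", "data.frame")
  out
}

# Observed QP bins for the chi-square objective: per duration x choice, the
# outer-bin masses are 0.1 of that choice's proportion, inner bins 0.2.
.qp_bins <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                     min_choice_n = 5L) {
  qp <- qp_stats(trials, probs = probs, min_n = 0)
  durs <- unique(qp$duration_ms)
  bin_w <- diff(c(0, probs, 1))
  lapply(durs, function(d) {
    per_choice <- lapply(c("short", "long"), function(ch) {
      r <- qp[qp$duration_ms == d & qp$choice == ch, , drop = FALSE]
      if (r$n >= min_choice_n) {
        list(choice = ch, edges = as.numeric(r[1, paste0("q", probs * 100)]),
             p_obs = r$prop * bin_w)
      } else {
        list(choice = ch, edges = numeric(0), p_obs = r$prop)
      }
    })
    n_d <- sum(qp$n[qp$duration_ms == d])
    list(duration_ms = d, n = n_d, bins = per_choice)
  })
}

# Model bin probabilities from a simulated trial set, against observed edges.
.qp_model_probs <- function(sim_choice, sim_rt_ms, bins_one) {
  n <- length(sim_choice)
  unlist(lapply(bins_one$bins, function(b) {
    is_ch <- !is.na(sim_choice) & sim_choice == b$choice
    if (length(b$edges) == 0L) return(sum(is_ch) / n)
    rts <- sim_rt_ms[is_ch]
    cnt <- tabulate(findInterval(rts, vec = b$edges) + 1L,
                    nbins = length(b$edges) + 1L)
    cnt / n
  }), use.names = FALSE)
}

#' Fit Levy-flight diffusion parameters to one condition
#'
#' Desk-scale quantile-probability estimation: a chi-square discrepancy
#' between observed and model response-proportion/RT-quantile bins is
#' minimised by multi-start Nelder-Mead, with the model bins computed by
#' simulating the diffusion afresh at each proposal under common random
#' numbers (the same RNG substream every evaluation, so the objective is
#' deterministic in the parameters).  Drift is fitted per stimulus
#' duration; boundary separation `a`, relative start `z`, nondecision time
#' `t0` (and `alpha`) are shared across durations.  When `fix_alpha` is
#' `NULL`, `alpha` is profiled on the grid {1.2, 1.4, 1.6, 1.8, 2.0} and
#' then refined continuously around the best grid point.
#'
#' @param trials Trial table (`duration_ms`, `choice`, `rt_ms`; censored
#'   rows excluded).
#' @param fix_alpha Fix the stable exponent (e.g. 2 for the Wiener model);
#'   `NULL` frees it.
#' @param n_sim Simulated trials per duration per objective evaluation.
#' @param n_starts Number of Nelder-Mead starts (jittered around a
#'   data-driven start).
#' @param seed Integer seed controlling the common random numbers and the
#'   start jitter; identical seeds give identical fits.
#' @param dt,max_t Simulation settings; the effective horizon is capped at
#'   1.5x the slowest observed RT, since proposals slower than the data
#'   cannot fit them anyway.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param bounds Box constraints on the shared parameters (list with `v`,
#'   `a`, `z`, `t0` ranges); proposals outside are rejected.  Defaults span
#'   the plausible range for seconds-scale bisection data.
#' @return List of class `ddm_fit`: `v` (named per duration), `a`, `z`,
#'   `t0`, `alpha`, `objective`, `converged`, `n_starts`.
#' @examples
#' \donttest{
#' set.seed(5)
#' sim <- simulate_ddm_condition(ddm_params(v = 1.5, a = 1.6, t0 = 0.3),
#'                               n = 2000)
#' tr <- data.frame(duration_ms = 2000,
#'                  choice = ifelse(sim$choice == "upper", "long", "short"),
#'                  rt_ms = sim$rt * 1000, censored = sim$censored)
#' fit_ddm_condition(tr, fix_alpha = 2, n_starts = 2, seed = 1)
#' }
#' @export
fit_ddm_condition <- function(trials, fix_alpha = NULL, n_sim = 2000,
                              n_starts = 4, seed = 1, dt = 0.004,
                              max_t = 10, maxit = 250,
                              bounds = list(v = c(-8, 8), a = c(0.3, 4),
                                            z = c(0.05, 0.95),
                                            t0 = c(0.01, 2))) {
  stopifnot(is.data.frame(trials))
  if ("censored" %in% names(trials)) {
    trials <- trials[!trials$censored, , drop = FALSE]
  }
  trials <- trials[!is.na(trials$choice), , drop = FALSE]
  bins <- .qp_bins(trials)
  durs <- vapply(bins, `[[`, numeric(1), "duration_ms")
  n_dur <- length(durs)
  seed <- as.integer(seed)
  crn_seed <- seed + 104729L  # CRN substream, fixed across proposals
  # proposals slower than the data cannot fit them; cap the horizon
  max_t <- min(max_t, 1.5 * max(trials$rt_ms) / 1000)

  objective <- function(v, a, z, t0, alpha) {
    if (a < bounds$a[1] || a > bounds$a[2] ||
        z < bounds$z[1] || z > bounds$z[2] ||
        t0 < bounds$t0[1] || t0 > bounds$t0[2] ||
        any(abs(v) > bounds$v[2]) ||
        alpha <= 1 || alpha > 2) {
      return(1e10)
    }
    chi2 <- 0
    old <- get0(".Random.seed", envir = globalenv())
    if (!is.null(old)) {
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(crn_seed)
    for (i in seq_len(n_dur)) {
      sim <- cpp_simulate_levy(rep(v[i], n_sim), a, z, t0, alpha, dt, max_t)
      ch <- ifelse(is.na(sim$choice), NA_character_,
                   c("short", "long")[sim$choice + 1L])
      p_mod <- .qp_model_probs(ch, sim$rt * 1000, bins[[i]])
      p_obs <- unlist(lapply(bins[[i]]$bins, `[[`, "p_obs"))
      chi2 <- chi2 + bins[[i]]$n *
        sum((p_obs - p_mod)^2 / pmax(p_mod, 2 / n_sim))
    }
    chi2
  }

  # data-driven start: t0 near the fastest responses, drift from the
  # choice proportions through the Wiener absorption formula at a ~ 1.5
  min_rt_s <- min(trials$rt_ms) / 1000
  t0_start <- max(0.05, 0.85 * min_rt_s)
  a_start <- 1.5
  p_long <- vapply(seq_len(n_dur), function(i) {
    pb <- bins[[i]]$bins[[2]]$p_obs
    sum(pb)
  }, numeric(1))
  v_start <- stats::qlogis(pmin(pmax(p_long, 0.02), 0.98)) / a_start

  fit_inner <- function(alpha_val, free_alpha, starts_seed, n_st) {
    par0 <- c(v_start, log(a_start), stats::qlogis(0.5), log(t0_start))
    if (free_alpha) par0 <- c(par0, stats::qlogis(alpha_val - 1))
    obj_tr <- function(par) {
      v <- par[seq_len(n_dur)]
      a <- exp(par[n_dur + 1])
      z <- stats::plogis(par[n_dur + 2])
      t0 <- exp(par[n_dur + 3])
      al <- if (free_alpha) 1 + stats::plogis(par[n_dur + 4]) else alpha_val
      objective(v, a, z, t0, al)
    }
    best <- NULL
    set.seed(starts_seed)
    for (st in seq_len(n_st)) {
      p0 <- if (st == 1L) par0 else
        par0 + stats::rnorm(length(par0), 0, 0.3)
      ans <- stats::optim(p0, obj_tr, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-7))
      if (is.null(best) || ans$value < best$value) best <- ans
    }
    best
  }

  if (!is.null(fix_alpha)) {
    .check_alpha(fix_alpha)
    best <- fit_inner(fix_alpha, FALSE, seed, n_starts)
    alpha_hat <- fix_alpha
    free_alpha <- FALSE
  } else {
    grid <- c(1.2, 1.4, 1.6, 1.8, 2.0)
    grid_fits <- lapply(grid, function(al) {
      fit_inner(al, FALSE, seed, max(2L, n_starts %/% 2L))
    })
    vals <- vapply(grid_fits, `[[`, numeric(1), "value")
    al_best <- grid[which.min(vals)]
    # continuous refinement around the best grid point (alpha free)
    best <- fit_inner(min(al_best, 1.99), TRUE, seed + 1L, n_starts)
    if (best$value > min(vals)) {  # keep the grid optimum if better
      best <- grid_fits[[which.min(vals)]]
      alpha_hat <- al_best
      free_alpha <- FALSE
    } else {
      alpha_hat <- 1 + stats::plogis(best$par[n_dur + 4])
      free_alpha <- TRUE
    }
  }

  v_hat <- best$par[seq_len(n_dur)]
  names(v_hat) <- durs
  structure(list(
    v = v_hat,
    a = exp(best$par[n_dur + 1]),
    z = stats::plogis(best$par[n_dur + 2]),
    t0 = exp(best$par[n_dur + 3]),
    alpha = alpha_hat,
    objective = best$value,
    converged = best$convergence == 0L,
    n_starts = n_starts,
    seed = seed
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "<ddm_fit> a = %.3f, z = %.3f, t0 = %.3f s, alpha = %.2f (chi2 = %.1f%s)\n",
    x$a, x$z, x$t0, x$alpha, x$objective,
    if (x$converged) "" else ", NOT converged"))
  cat("  v:", paste(sprintf("%s=%.3f", names(x$v), x$v), collapse = ", "),
      "\n")
  invisible(x)
}

#' True-versus-estimated parameter recovery report
#'
#' @param true,estimated Named numeric vectors (or `ddm_params`/`ddm_fit`
#'   objects); errors are computed on the shared parameter names.
#' @param n_trials,seed Bookkeeping fields.
#' @return Data.frame of class `recovery_report` with `param`, `true`,
#'   `estimated`, `abs_error`, `rel_error`.
#' @export
recovery_report <- function(true, estimated, n_trials = NA_integer_,
                            seed = NA_integer_) {
  flat <- function(x) {
    if (inherits(x, c("ddm_params", "ddm_fit"))) {
      v <- x$v
      names(v) <- if (length(v) > 1L) paste0("v_", names(v)) else "v"
      c(v, a = x$a, z = x$z, t0 = x$t0, alpha = x$alpha)
    } else unlist(x)
  }
  tv <- flat(true); ev <- flat(estimated)
  shared <- intersect(names(tv), names(ev))
  if (length(shared) == 0L) stop("no shared parameter names", call. = FALSE)
  out <- data.frame(param = shared, true = unname(tv[shared]),
                    estimated = unname(ev[shared]),
                    stringsAsFactors = FALSE)
  out$abs_error <- abs(out$estimated - out$true)
  out$rel_error <- out$abs_error / pmax(abs(out$true), 1e-12)
  attr(out, "n_trials") <- n_trials
  attr(out, "seed") <- seed
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' Per-subject slopes of fitted parameters across frequency levels
#'
#' OLS slope of each requested parameter against the rank-coded level
#' (1, 2, 3) per subject; the companion [slope_correlations] relates these
#' to behavioural CV/RT slopes between subjects.
#'
#' @param fits Long data.frame with one row per subject x level and one
#'   column per parameter.
#' @param subject,level Column names.
#' @param params Parameter column names to take slopes of.
#' @return Data.frame: `subject` plus one `slope_<param>` column each;
#'   subjects missing a level are dropped (with a message).
#' @export
parameter_slopes <- function(fits, subject = "subject",
                             level = "frequency_Hz",
                             params = c("v", "a")) {
  stopifnot(is.data.frame(fits), all(params %in% names(fits)))
  out <- NULL
  for (p in params) {
    sl <- per_subject_slopes(fits, p, subject, level)
    names(sl)[2] <- paste0("slope_", p)
    out <- if (is.null(out)) sl else merge(out, sl, by = "subject")
  }
  out
}

#' Between-subject correlation of two slope sets
#'
#' Pearson and Spearman correlations (both reported) between matched
#' per-subject slopes, e.g. drift-rate slope versus CV slope across
#' frequency.
#'
#' @param slopes_x,slopes_y Numeric vectors of equal length (matched by
#'   subject).
#' @return Data.frame with rows `pearson` and `spearman`: `estimate`, `p`.
#' @export
slope_correlations <- function(slopes_x, slopes_y) {
  stopifnot(length(slopes_x) == length(slopes_y), length(slopes_x) >= 3L)
  pe <- stats::cor.test(slopes_x, slopes_y, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(slopes_x, slopes_y, method = "spearman"))
  data.frame(method = c("pearson", "spearman"),
             estimate = c(unname(pe$estimate), unname(sp$estimate)),
             p = c(pe$p.value, sp$p.value),
             stringsAsFactors = FALSE)
}
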