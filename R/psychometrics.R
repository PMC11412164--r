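#' Response-time outlier filtering
#'
#' Two-stage exclusion applied before psychometric fitting: first an
#' absolute window (trials with RT below 200 ms or above 2,000 ms are
#' removed), then, on the windowed data, removal of trials farther than
#' `sd_limit` standard deviations from the mean of each participant's
#' log-transformed RT distribution.  The window runs first so that gross
#' outliers cannot inflate the log-RT standard deviation.
#'
#' @param trials Trial table with at least `rt_ms` (and `subject` when
#'   `per_subject = TRUE`); all `rt_ms` must be positive.
#' @param rt_window_ms Absolute window, default `c(200, 2000)` ms.
#' @param sd_limit SD cutoff on log RT, default 3.
#' @param per_subject Compute the log-RT mean/SD per subject (default) or
#'   pooled.
#' @return The kept trials, with an `"exclusions"` attribute: a data.frame
#'   per subject counting removals by each rule (`n_window`, `n_sd`) and a
#'   `flagged` column marking subjects left with fewer than 3 trials
#'   (also raised as a warning).
#' @examples
#' tr <- data.frame(subject = "s1", rt_ms = c(150, 250, 400, 2500, 600))
#' filter_rts(tr)   # window removes 150 and 2500
#' @export
filter_rts <- function(trials, rt_window_ms = c(200, 2000), sd_limit = 3,
                       per_subject = TRUE) {
  stopifnot(is.data.frame(trials), "rt_ms" %in% names(trials))
  if (any(!is.finite(trials$rt_ms)) || any(trials$rt_ms <= 0)) {
    stop("all 'rt_ms' must be positive and finite", call. = FALSE)
  }
  if (per_subject && !"subject" %in% names(trials)) {
    stop("'subject' column required for per-subject filtering",
         call. = FALSE)
  }
  subj <- if (per_subject) as.character(trials$subject) else
    rep("all", nrow(trials))

  in_window <- trials$rt_ms >= rt_window_ms[1] & trials$rt_ms <= rt_window_ms[2]
  keep <- in_window
  # 3-SD rule on log RT, computed from the windowed data only
  for (s in unique(subj)) {
    idx <- which(subj == s & in_window)
    lr <- log(trials$rt_ms[idx])
    s_sd <- stats::sd(lr)
    if (length(idx) >= 2L && is.finite(s_sd) && s_sd > 0) {
      out <- abs(lr - mean(lr)) > sd_limit * s_sd
      keep[idx[out]] <- FALSE
    }
  }

  log <- do.call(rbind, lapply(unique(subj), function(s) {
    i <- subj == s
    data.frame(subject = s,
               n_total = sum(i),
               n_window = sum(i & !in_window),
               n_sd = sum(i & in_window & !keep),
               n_kept = sum(i & keep),
               stringsAsFactors = FALSE)
  }))
  log$flagged <- log$n_kept < 3L
  if (any(log$flagged)) {
    warning(sprintf("subject(s) with < 3 surviving trials: %s",
                    paste(log$subject[log$flagged], collapse = ", ")),
            call. = FALSE)
  }
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- log
  out
}

#' Cumulative Gumbel psychometric function on log10 duration
#'
#' The probability of a "long" categorisation as a function of stimulus
#' duration, parameterised on log10 duration to respect the log spacing of
#' the stimulus set:
#' \deqn{F(x) = 1 - \exp\{-\exp[(\log_{10} x - m)/s]\}.}
#' This orientation (one of the two mirrored "cumulative Gumbel" variants)
#' is fixed package-wide; its quantile function is
#' \eqn{F^{-1}(p) = 10^{m + s \ln(-\ln(1-p))}}.
#'
#' @param duration_ms Positive stimulus duration(s), ms.
#' @param m Location on log10-ms.
#' @param s Scale on log10-ms (> 0).
#' @return Probability of "long" in (0, 1), strictly increasing in
#'   `duration_ms`.
#' @examples
#' pgumbel_dur(10^3.3, m = 3.3, s = 0.1)  # 1 - exp(-1) at x = 10^m
#' @export
pgumbel_dur <- function(duration_ms, m, s) {
  stopifnot(all(duration_ms > 0), s > 0)
  1 - exp(-exp((log10(duration_ms) - m) / s))
}

#' @rdname pgumbel_dur
#' @param p Probability in (0, 1).
#' @return `qgumbel_dur`: the duration (ms) at which `F` crosses `p`.
#' @export
qgumbel_dur <- function(p, m, s) {
  if (any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  }
  stopifnot(s > 0)
  10^(m + s * log(-log1p(-p)))
}

#' Fit a psychometric curve and extract BP and CV
#'
#' Binomial maximum-likelihood fit of the cumulative Gumbel
#' ([pgumbel_dur]) to the proportion of "long" responses per duration,
#' with guess/lapse rates fixed (defaults 0).  From the fitted curve the
#' bisection point (BP) is the duration at 0.5 probability of "long"
#' (accuracy/bias), and the coefficient of variation (CV) is half the
#' 0.25-0.75 quantile spread divided by the BP (precision; higher = less
#' precise).
#'
#' @param trials Trial table with `duration_ms` and `choice` coded
#'   `"short"`/`"long"` (or `"lower"`/`"upper"`); rows with missing choice
#'   are dropped.
#' @param gamma,lambda Guess and lapse rates, fixed (not estimated).
#' @param min_s Floor on the fitted scale; fits hitting it (e.g. perfectly
#'   separated data) are flagged, not errored.
#' @return An object of class `psychometric_fit`: `m`, `s`, `bp_ms`, `cv`,
#'   `n_trials`, `neg_log_lik`, `flags` (character; may note `"s_floor"`,
#'   `"bp_out_of_range"`, `"non_monotonic"`).
#' @examples
#' set.seed(2)
#' d <- rep(bisection_durations(), each = 40)
#' ch <- ifelse(runif(length(d)) < pgumbel_dur(d, log10(2000), 0.12),
#'              "long", "short")
#' fit_psychometric(data.frame(duration_ms = d, choice = ch))
#' @export
fit_psychometric <- function(trials, gamma = 0, lambda = 0, min_s = 0.005) {
  stopifnot(is.data.frame(trials),
            all(c("duration_ms", "choice") %in% names(trials)))
  trials <- trials[!is.na(trials$choice), , drop = FALSE]
  long <- trials$choice %in% c("long", "upper")
  if (!all(trials$choice %in% c("long", "short", "upper", "lower"))) {
    stop("'choice' must be coded short/long (or lower/upper)", call. = FALSE)
  }
  durs <- sort(unique(trials$duration_ms))
  if (length(durs) < 2L) {
    stop("need responses at >= 2 distinct durations", call. = FALSE)
  }
  n_long <- tapply(long, trials$duration_ms, sum)
  n_tot <- tapply(long, trials$duration_ms, length)
  if (sum(n_long) == 0L || sum(n_long) == sum(n_tot)) {
    stop("need at least one 'short' and one 'long' response", call. = FALSE)
  }
  ld <- log10(durs)
  p_obs <- as.numeric(n_long / n_tot)

  nll <- function(par) {
    s <- exp(par[2])
    p <- gamma + (1 - gamma - lambda) * pgumbel_dur(durs, par[1], s)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(n_long * log(p) + (n_tot - n_long) * log(1 - p))
  }

  # coarse starts: location near the empirical 50% crossing, several scales
  m0 <- ld[which.min(abs(p_obs - 0.5))]
  best <- NULL
  for (s0 in c(0.05, 0.12, 0.3)) {
    ans <- stats::optim(c(m0, log(s0)), nll, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || ans$value < best$value) best <- ans
  }
  m <- best$par[1]
  s <- exp(best$par[2])
  flags <- character(0)
  # perfect separation (no mixed-response duration): the scale MLE is 0
  separated <- all(p_obs %in% c(0, 1))
  if (s < min_s || separated) {
    s <- min_s
    flags <- c(flags, "s_floor")
  }
  bp <- qgumbel_dur(0.5, m, s)
  cv <- (qgumbel_dur(0.75, m, s) - qgumbel_dur(0.25, m, s)) / (2 * bp)
  if (bp < 0.5 * min(durs) || bp > 2 * max(durs)) {
    flags <- c(flags, "bp_out_of_range")
  }
  # orientation guard: proportion-long should increase with duration overall
  if (length(durs) >= 3L &&
      stats::cor(ld, p_obs, method = "spearman") < 0) {
    flags <- c(flags, "non_monotonic")
  }
  structure(list(m = m, s = s, bp_ms = bp, cv = cv,
                 n_trials = as.integer(sum(n_tot)),
                 neg_log_lik = best$value, flags = flags),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> m = %.4f, s = %.4f | BP = %.0f ms, CV = %.3f (n = %d)%s\n",
    x$m, x$s, x$bp_ms, x$cv, x$n_trials,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Psychometric fits per design condition
#'
#' Fits one curve per grouping cell (default: subject x amplitude x
#' frequency) and, optionally, collapsed variants that pool trials over one
#' of the design factors (e.g. per subject x frequency collapsed over
#' amplitude, as used for frequency contrasts and slope analyses).
#'
#' @param trials Filtered trial table (see [filter_rts]).
#' @param group_vars Columns defining one curve each.
#' @param min_trials Cells below this count are flagged `low_n` (and still
#'   fitted when possible); empty cells are skipped.
#' @return Data.frame with one row per cell: grouping keys, `m`, `s`,
#'   `bp_ms`, `cv`, `n`, `flags` (comma-joined, `""` if clean).
#' @examples
#' \donttest{
#' tt <- generate_experiment("auditory", n_subjects = 2, seed = 1)
#' fits <- curves_by_condition(filter_rts(tt))
#' head(fits)
#' }
#' @export
curves_by_condition <- function(trials,
                                group_vars = c("subject", "amplitude_N",
                                               "frequency_Hz"),
                                min_trials = 30) {
  stopifnot(is.data.frame(trials), all(group_vars %in% names(trials)))
  key <- interaction(trials[group_vars], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- trials[key == k, , drop = FALSE]
    keys <- sub[1L, group_vars, drop = FALSE]
    flags <- character(0)
    if (nrow(sub) < min_trials) flags <- c(flags, "low_n")
    fit <- tryCatch(fit_psychometric(sub), error = function(e) NULL)
    if (is.null(fit)) {
      cbind(keys, data.frame(m = NA_real_, s = NA_real_, bp_ms = NA_real_,
                             cv = NA_real_, n = nrow(sub),
                             flags = paste(c(flags, "unfit"),
                                           collapse = ",")))
    } else {
      cbind(keys, data.frame(m = fit$m, s = fit$s, bp_ms = fit$bp_ms,
                             cv = fit$cv, n = fit$n_trials,
                             flags = paste(c(flags, fit$flags),
                                           collapse = ",")))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
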