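#' Repeated-measures ANOVA for balanced one- or two-factor designs
#'
#' Classical within-subject sums-of-squares decomposition for fully
#' balanced designs (every subject observed once in every cell).  Each
#' effect is tested against its own subject-by-effect interaction error
#' term (A against A x S, B against B x S, A x B against A x B x S), with
#' partial eta squared `SS_effect / (SS_effect + SS_error)` as effect size.
#' Uncorrected degrees of freedom are reported by default;
#' Greenhouse-Geisser correction of the p-values is available behind
#' `gg_correction` (Box epsilon computed from orthonormal effect
#' contrasts).
#'
#' @param data Long-format data.frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject id column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param gg_correction Apply Greenhouse-Geisser correction (default
#'   FALSE).
#' @return Data.frame of class `rm_anova`: one row per effect with
#'   `effect`, `F`, `df1`, `df2`, `p`, `pes` (and `gg_epsilon`, `p_gg`
#'   when corrected).
#' @examples
#' d <- expand.grid(subject = 1:2, level = 1:3)
#' d$y <- c(1, 2, 2, 3, 3, 5)
#' rm_anova(d, "y", "subject", "level")   # F(2,2) = 19
#' @export
rm_anova <- function(data, dv, subject, within, gg_correction = FALSE) {
  stopifnot(is.data.frame(data), dv %in% names(data),
            subject %in% names(data), all(within %in% names(data)),
            length(within) %in% 1:2)
  y <- data[[dv]]
  if (any(!is.finite(y))) stop("non-finite response values", call. = FALSE)
  s <- factor(data[[subject]])
  if (nlevels(s) < 2L) stop("need >= 2 subjects", call. = FALSE)
  f <- lapply(within, function(w) factor(data[[w]]))
  cell <- if (length(f) == 1L) f[[1L]] else interaction(f[[1L]], f[[2L]])
  counts <- table(s, cell)
  if (any(counts != 1L)) {
    stop("design must be balanced: one observation per subject per cell",
         call. = FALSE)
  }

  if (length(within) == 1L) {
    res <- .rm_anova_1way(y, s, f[[1L]], within)
  } else {
    res <- .rm_anova_2way(y, s, f[[1L]], f[[2L]], within)
  }
  if (gg_correction) {
    res$gg_epsilon <- vapply(seq_len(nrow(res)), function(i) {
      .gg_epsilon(y, s, f, effect = res$effect[i], within = within)
    }, numeric(1))
    res$p_gg <- stats::pf(res$F, res$gg_epsilon * res$df1,
                          res$gg_epsilon * res$df2, lower.tail = FALSE)
  }
  class(res) <- c("rm_anova", "data.frame")
  res
}

.rm_anova_1way <- function(y, s, a, within) {
  gm <- mean(y)
  na <- nlevels(a); ns <- nlevels(s)
  ma <- tapply(y, a, mean)
  ms <- tapply(y, s, mean)
  ss_a <- ns * sum((ma - gm)^2)
  ss_s <- na * sum((ms - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_as <- ss_tot - ss_a - ss_s
  df1 <- na - 1L
  df2 <- (na - 1L) * (ns - 1L)
  f_val <- if (ss_a <= 1e-300) 0 else (ss_a / df1) / (ss_as / df2)
  data.frame(effect = within[1L], F = f_val, df1 = df1, df2 = df2,
             p = stats::pf(f_val, df1, df2, lower.tail = FALSE),
             pes = if (ss_a + ss_as > 0) ss_a / (ss_a + ss_as) else 0,
             stringsAsFactors = FALSE)
}

.rm_anova_2way <- function(y, s, a, b, within) {
  gm <- mean(y)
  na <- nlevels(a); nb <- nlevels(b); ns <- nlevels(s)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  msub <- tapply(y, s, mean)
  mab <- tapply(y, list(a, b), mean)
  mas <- tapply(y, list(a, s), mean)
  mbs <- tapply(y, list(b, s), mean)

  ss_a <- ns * nb * sum((ma - gm)^2)
  ss_b <- ns * na * sum((mb - gm)^2)
  ss_s <- na * nb * sum((msub - gm)^2)
  ss_ab <- ns * sum((mab - outer(ma, rep(1, nb)) -
                       outer(rep(1, na), mb) + gm)^2)
  ss_as <- nb * sum((mas - outer(ma, rep(1, ns)) -
                       outer(rep(1, na), msub) + gm)^2)
  ss_bs <- na * sum((mbs - outer(mb, rep(1, ns)) -
                       outer(rep(1, nb), msub) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs

  mk <- function(effect, ss_e, ss_err, df1, df2) {
    f_val <- if (ss_e <= 1e-300) 0 else (ss_e / df1) / (ss_err / df2)
    data.frame(effect = effect, F = f_val, df1 = df1, df2 = df2,
               p = stats::pf(f_val, df1, df2, lower.tail = FALSE),
               pes = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk(within[1L], ss_a, ss_as, na - 1L, (na - 1L) * (ns - 1L)),
    mk(within[2L], ss_b, ss_bs, nb - 1L, (nb - 1L) * (ns - 1L)),
    mk(paste(within, collapse = ":"), ss_ab, ss_abs,
       (na - 1L) * (nb - 1L), (na - 1L) * (nb - 1L) * (ns - 1L)))
}

# Box/Greenhouse-Geisser epsilon for one effect: project each subject's
# cell vector onto orthonormal contrasts spanning the effect space, then
# eps = tr(S)^2 / (k * sum(S^2)) on the covariance of the projections.
.gg_epsilon <- function(y, s, f, effect, within) {
  helm <- function(k) {
    cm <- stats::contr.helmert(k)
    sweep(cm, 2, sqrt(colSums(cm^2)), "/")
  }
  if (length(f) == 1L) {
    cmat <- helm(nlevels(f[[1L]]))
    cells <- f[[1L]]
  } else {
    ca <- helm(nlevels(f[[1L]])); cb <- helm(nlevels(f[[2L]]))
    ia <- matrix(1 / sqrt(nlevels(f[[1L]])), nlevels(f[[1L]]), 1)
    ib <- matrix(1 / sqrt(nlevels(f[[2L]])), nlevels(f[[2L]]), 1)
    cmat <- if (effect == within[1L]) kronecker(ib, ca) else
      if (effect == within[2L]) kronecker(cb, ia) else kronecker(cb, ca)
    cells <- interaction(f[[1L]], f[[2L]])  # kronecker order: b slow, a fast
  }
  wide <- tapply(y, list(s, cells), mean)
  proj <- wide %*% cmat
  S <- stats::cov(proj)
  k <- ncol(S)
  max(1 / k, min(1, sum(diag(S))^2 / (k * sum(S^2))))
}

#' @export
print.rm_anova <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s: F(%d,%d) = %.3f, p = %.4g, pes = %.3f\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i], x$pes[i]))
  }
  invisible(x)
}

#' Linear contrast across ordered within-subject levels
#'
#' Computes a per-subject contrast score with equally spaced centered
#' weights (e.g. -1, 0, 1 for three levels), then a one-sample t test of
#' the scores against zero.  Cohen's d is the mean contrast score divided
#' by its standard deviation.
#'
#' @param data Long-format data.frame (one value per subject per level;
#'   balanced).
#' @param dv,subject Column names of the response and subject id.
#' @param level Column name of the ordered factor; levels are coded by
#'   their rank order (1, 2, 3, ...), not by their numeric values.
#' @param weights Optional custom contrast weights (must sum to 0).
#' @return List of class `linear_contrast`: `t`, `df`, `p`, `cohen_d`,
#'   `scores` (per-subject).
#' @examples
#' d <- expand.grid(subject = 1:3, level = 1:3)
#' d$y <- d$level * rep(c(0.25, 0.5, 0.75), 3)
#' linear_contrast(d, "y", "subject", "level")
#' @export
linear_contrast <- function(data, dv, subject, level, weights = NULL) {
  stopifnot(is.data.frame(data), dv %in% names(data),
            subject %in% names(data), level %in% names(data))
  lv <- factor(data[[level]])
  k <- nlevels(lv)
  if (k < 2L) stop("need >= 2 levels", call. = FALSE)
  if (is.null(weights)) {
    weights <- seq_len(k) - (k + 1) / 2
  }
  if (length(weights) != k || abs(sum(weights)) > 1e-8) {
    stop("'weights' must have one entry per level and sum to 0",
         call. = FALSE)
  }
  s <- factor(data[[subject]])
  wide <- tapply(data[[dv]], list(s, lv), mean)
  if (any(is.na(wide))) stop("design must be balanced", call. = FALSE)
  scores <- as.numeric(wide %*% weights)
  names(scores) <- rownames(wide)
  if (stats::sd(scores) == 0) {
    stop("contrast scores have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(scores)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 cohen_d = mean(scores) / stats::sd(scores),
                 scores = scores),
            class = "linear_contrast")
}

#' @export
print.linear_contrast <- function(x, ...) {
  cat(sprintf("<linear_contrast> t(%g) = %.3f, p = %.4g, Cohen's d = %.3f\n",
              x$df, x$t, x$p, x$cohen_d))
  invisible(x)
}

#' Simple main effects of one factor within each level of a moderator
#'
#' Runs a one-factor repeated-measures ANOVA of `simple_factor` separately
#' within each level of `moderator` (e.g. the effect of tremor frequency
#' probed at each tremor amplitude).
#'
#' @inheritParams rm_anova
#' @param simple_factor Factor whose effect is probed.
#' @param moderator Factor whose levels stratify the probe.
#' @return Data.frame: one `rm_anova` row per moderator level, with a
#'   leading `moderator_level` column.
#' @export
simple_main_effects <- function(data, dv, subject, simple_factor,
                                moderator) {
  stopifnot(moderator %in% names(data))
  lv <- unique(data[[moderator]])
  out <- lapply(sort(lv), function(l) {
    sub <- data[data[[moderator]] == l, , drop = FALSE]
    res <- rm_anova(sub, dv, subject, simple_factor)
    cbind(data.frame(moderator_level = l), as.data.frame(res))
  })
  do.call(rbind, out)
}

#' Assign tremor directions to three angular bins
#'
#' Bins directions on [0, 180) degrees as: bin 1 for [0, 60], bin 2 for
#' (60, 120], bin 3 for (120, 180).  The boundary convention places the
#' integer edges 60 and 120 in the lower bin, matching an integer-degree
#' reading of 0-60 / 61-120 / 121-180.
#'
#' @param direction_deg Numeric vector in [0, 180).
#' @return Integer vector of bins in {1, 2, 3}.
#' @examples
#' direction_bins(c(0, 60, 61, 90, 120.5, 179.9))
#' @export
direction_bins <- function(direction_deg) {
  if (any(!is.finite(direction_deg)) || any(direction_deg < 0) ||
      any(direction_deg >= 180)) {
    stop("'direction_deg' must lie in [0, 180)", call. = FALSE)
  }
  ifelse(direction_deg <= 60, 1L, ifelse(direction_deg <= 120, 2L, 3L))
}

#' Mann-Whitney comparison of per-subject slopes between groups
#'
#' Two-sided Mann-Whitney U test of two independent samples (e.g.
#' per-subject CV-versus-frequency slopes from two modality groups), with
#' the rank-biserial correlation `1 - 2U/(n1*n2)` as effect size.  U counts
#' the pairs in which a group-a value exceeds a group-b value, so
#' rank-biserial is +1 when every a falls below every b and -1 in the
#' reverse order; swapping the groups flips its sign.  The exact null
#' distribution is used when both groups have at most `exact_max`
#' observations and there are no ties; the normal approximation (with
#' continuity correction) otherwise.
#'
#' @param slopes_a,slopes_b Numeric vectors (non-empty).
#' @param exact_max Largest group size for which the exact test is used
#'   (default 20).
#' @return List of class `slope_comparison`: `U`, `p`, `rank_biserial`,
#'   `n` (c(n_a, n_b)), `exact`.
#' @examples
#' slope_comparison(c(1, 2, 3), c(4, 5, 6))   # U = 0, rank-biserial = 1
#' @export
slope_comparison <- function(slopes_a, slopes_b, exact_max = 20) {
  if (length(slopes_a) == 0L || length(slopes_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(slopes_a); n2 <- length(slopes_b)
  ties <- any(duplicated(c(slopes_a, slopes_b)))
  exact <- n1 <= exact_max && n2 <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(slopes_a, slopes_b, exact = exact, correct = TRUE))
  u <- unname(wt$statistic)
  structure(list(U = u, p = wt$p.value,
                 rank_biserial = 1 - 2 * u / (n1 * n2),
                 n = c(n1, n2), exact = exact),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf(
    "<slope_comparison> U = %g, p = %.4g, rank-biserial = %.3f (n = %d, %d%s)\n",
    x$U, x$p, x$rank_biserial, x$n[1], x$n[2],
    if (x$exact) ", exact" else ""))
  invisible(x)
}

#' Per-subject slope of a measure across ordered levels
#'
#' Ordinary least-squares slope of `dv` against the rank-coded level
#' (1, 2, 3, ...) for each subject; used for CV-versus-frequency and
#' parameter-versus-frequency slopes.
#'
#' @inheritParams linear_contrast
#' @return Data.frame with `subject` and `slope`, one row per subject;
#'   subjects missing a level are dropped with a message.
#' @export
per_subject_slopes <- function(data, dv, subject, level) {
  stopifnot(is.data.frame(data), dv %in% names(data))
  lv <- factor(data[[level]])
  s <- factor(data[[subject]])
  wide <- tapply(data[[dv]], list(s, lv), mean)
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    message(sprintf("dropping %d subject(s) with missing levels",
                    sum(!complete)))
  }
  x <- seq_len(ncol(wide))
  xc <- x - mean(x)
  slopes <- as.numeric(wide[complete, , drop = FALSE] %*% xc / sum(xc^2))
  data.frame(subject = rownames(wide)[complete], slope = slopes,
             stringsAsFactors = FALSE)
}
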