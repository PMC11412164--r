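#' Sensory (or motor) duration estimate
#'
#' A single channel's estimate of elapsed duration, summarised by the mean
#' and width (standard deviation) of its internal distribution.  The scale
#' (seconds or log-seconds) is up to the caller; all cue-combination
#' arithmetic is scale-agnostic and never converts units.
#'
#' @param mu Mean of the estimate distribution; must be positive.
#' @param sigma Width (standard deviation) of the estimate; must be positive.
#' @param label Optional modality tag, e.g. `"auditory"`, `"movement"`.
#' @return An object of class `sensory_estimate` with fields `mu`, `sigma`,
#'   `label`.
#' @examples
#' sensory_estimate(2.0, 0.17, "auditory")
#' @export
sensory_estimate <- function(mu, sigma, label = "") {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(sigma),
            length(sigma) == 1L)
  if (!is.finite(mu) || mu <= 0) {
    stop("'mu' must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("'sigma' must be a positive finite number", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, label = as.character(label)),
            class = "sensory_estimate")
}

#' @export
print.sensory_estimate <- function(x, ...) {
  cat(sprintf("<sensory_estimate%s> mu = %g, sigma = %g\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$mu, x$sigma))
  invisible(x)
}

#' Reliability weight for one channel of a two-channel combination
#'
#' Inverse-variance weighting: the weight a channel receives is the other
#' channel's variance divided by the sum of the two variances, so the more
#' reliable (narrower) channel dominates the combined estimate.
#'
#' @param sigma_self Width (SD) of the channel whose weight is requested.
#' @param sigma_other Width (SD) of the other channel.
#' @return The weight on the "self" channel, strictly inside (0, 1).
#' @examples
#' cue_weight(0.2, 0.2)        # symmetric channels share the weight
#' cue_weight(0.17, 0.24)      # the narrower channel gets the larger weight
#' @export
cue_weight <- function(sigma_self, sigma_other) {
  .check_width(sigma_self, "sigma_self")
  .check_width(sigma_other, "sigma_other")
  sigma_other^2 / (sigma_self^2 + sigma_other^2)
}

.check_width <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must contain positive finite widths", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Optimally combine two duration estimates
#'
#' Fuses two independent Gaussian duration estimates by inverse-variance
#' weighting.  The combined mean is the weighted average of the input means;
#' the combined variance is the product of the input variances over their
#' sum, equivalently \eqn{1/\sigma^2_{SM} = 1/\sigma^2_S + 1/\sigma^2_M}
#' (precisions add).  The combined width is therefore always strictly
#' smaller than either input width.
#'
#' @param est_a,est_b Objects of class [sensory_estimate], or bare lists
#'   with `mu` and `sigma` fields.
#' @return An object of class `combined_estimate` with fields `mu`, `sigma`,
#'   `w_first`, `w_second` (weights sum to 1), and `labels`.
#' @examples
#' s <- sensory_estimate(2.2, 0.24, "visual")
#' m <- sensory_estimate(1.8, 0.17, "movement")
#' combine_estimates(s, m)
#' @export
combine_estimates <- function(est_a, est_b) {
  est_a <- .as_estimate(est_a)
  est_b <- .as_estimate(est_b)
  w_a <- cue_weight(est_a$sigma, est_b$sigma)
  w_b <- cue_weight(est_b$sigma, est_a$sigma)
  va <- est_a$sigma^2
  vb <- est_b$sigma^2
  structure(list(
    mu = w_a * est_a$mu + w_b * est_b$mu,
    sigma = sqrt(va * vb / (va + vb)),
    w_first = w_a,
    w_second = w_b,
    labels = c(est_a$label, est_b$label)
  ), class = "combined_estimate")
}

.as_estimate <- function(x) {
  if (inherits(x, "sensory_estimate")) return(x)
  if (is.list(x) && all(c("mu", "sigma") %in% names(x))) {
    return(sensory_estimate(x$mu, x$sigma,
                            if (!is.null(x$label)) x$label else ""))
  }
  stop("expected a sensory_estimate (or list with mu and sigma)",
       call. = FALSE)
}

#' @export
print.combined_estimate <- function(x, ...) {
  cat(sprintf("<combined_estimate> mu = %g, sigma = %g (weights %.3f/%.3f)\n",
              x$mu, x$sigma, x$w_first, x$w_second))
  invisible(x)
}

#' Combined width as the second channel grows noisier
#'
#' Holds one channel's width fixed at `sigma_base` and sweeps the other
#' channel's width over `noise_grid`, returning the combined width at each
#' grid point.  The curve is non-decreasing in the grid value and bounded
#' above by `sigma_base`; its total rise over a fixed grid grows with
#' `sigma_base`, i.e. noise injected into one channel hurts a low-precision
#' base modality more than a high-precision one.
#'
#' @param sigma_base Fixed width of the base channel (> 0).
#' @param noise_grid Strictly increasing vector of positive widths for the
#'   varying channel.
#' @return A data.frame with columns `noise_sigma`, `combined_sigma`,
#'   `base_sigma`.
#' @examples
#' noise_response_curve(0.24, c(0.1, 0.2, 0.4))
#' @export
noise_response_curve <- function(sigma_base, noise_grid) {
  .check_width(sigma_base, "sigma_base")
  if (length(noise_grid) == 0L) {
    stop("'noise_grid' must be non-empty", call. = FALSE)
  }
  .check_width(noise_grid, "noise_grid")
  if (length(noise_grid) > 1L && any(diff(noise_grid) <= 0)) {
    stop("'noise_grid' must be strictly increasing", call. = FALSE)
  }
  vb <- sigma_base^2
  vg <- noise_grid^2
  data.frame(noise_sigma = noise_grid,
             combined_sigma = sqrt(vb * vg / (vb + vg)),
             base_sigma = sigma_base)
}

#' Observed-to-predicted width ratio
#'
#' Simple suboptimality index: the ratio of an empirically observed
#' combined width to the width predicted by optimal inverse-variance
#' combination.  1 indicates optimal fusion; values above 1 indicate a
#' noisier-than-optimal combination.  No suboptimality model is fitted.
#'
#' @param observed_sigma Observed combined width (> 0).
#' @param predicted_sigma Predicted optimal width (> 0).
#' @return Non-negative ratio `observed_sigma / predicted_sigma`.
#' @export
optimality_ratio <- function(observed_sigma, predicted_sigma) {
  .check_width(observed_sigma, "observed_sigma")
  .check_width(predicted_sigma, "predicted_sigma")
  observed_sigma / predicted_sigma
}
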