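#' Experimental design configuration
#'
#' The temporal bisection design: 7 log-spaced stimulus durations between
#' 1,000 and 4,000 ms, fully crossed with 3 tremor amplitudes (1, 2, 3 N)
#' and 3 tremor frequencies (4, 8, 12 Hz), 6 repetitions per cell, giving
#' 7 x 3 x 3 x 6 = 378 trials per session; 24 subjects per modality.
#'
#' @param durations_ms Exactly 7 stimulus durations (ms).
#' @param amplitudes_N Tremor amplitudes (Newton).
#' @param frequencies_Hz Tremor frequencies (Hz).
#' @param reps_per_cell Repetitions of each design cell per session.
#' @param n_subjects Subjects per modality.
#' @return List of class `design_config`; `trials_per_session` is derived.
#' @examples
#' design_config()$trials_per_session  # 378
#' @export
design_config <- function(durations_ms = bisection_durations(),
                          amplitudes_N = c(1, 2, 3),
                          frequencies_Hz = c(4, 8, 12),
                          reps_per_cell = 6, n_subjects = 24) {
  if (length(durations_ms) != 7L) {
    stop("the design uses exactly 7 stimulus durations", call. = FALSE)
  }
  stopifnot(reps_per_cell >= 1, n_subjects >= 1)
  structure(list(
    durations_ms = durations_ms,
    amplitudes_N = amplitudes_N,
    frequencies_Hz = frequencies_Hz,
    reps_per_cell = as.integer(reps_per_cell),
    n_subjects = as.integer(n_subjects),
    trials_per_session = length(durations_ms) * length(amplitudes_N) *
      length(frequencies_Hz) * as.integer(reps_per_cell)
  ), class = "design_config")
}

#' Generative observer configuration
#'
#' Parameters of the simulated observer that turns the design into choices
#' and RTs.  A sensory channel of width `sigma_sensory` (auditory narrower
#' than visual) is fused with a motor channel whose width grows with
#' tremor frequency: `sigma_M = sigma_motor_base * gain_eff(frequency,
#' amplitude)` where `gain_eff = 1 + (freq_gain - 1) * amp_gate`.  The
#' amplitude gate lets frequency bite at every amplitude (auditory,
#' gate = 1) or only at the highest amplitude (visual default gate
#' 0/0/1), planting the amplitude-by-frequency interaction.  The fused
#' width sets the per-trial drift of a Levy-flight diffusion,
#' `v = k * (log d - log bp_true) / sigma_combined`, so wider combined
#' estimates yield shallower psychometric curves (higher CV) with an
#' unchanged bisection point.
#'
#' @param modality `"auditory"` or `"visual"`.
#' @param sigma_sensory Sensory channel width; defaults 0.17 (auditory) /
#'   0.28 (visual).  The visual/auditory ratio (~1.65) is chosen so the
#'   planted cross-modal difference in noise-frequency slopes is detectable
#'   at 24 subjects per group with 42-trial condition fits.
#' @param sigma_motor_base Motor width at the lowest tremor frequency.
#' @param freq_gain Multiplier on the motor width per frequency level
#'   (non-decreasing), named by frequency.
#' @param amp_gate Gate in [0, 1] per amplitude level scaling the
#'   frequency gain.
#' @param k Drift scaling constant (calibrated so baseline auditory CV is
#'   about 0.17).
#' @param a,z,t0,alpha Diffusion parameters shared across trials.
#' @param bp_true True bisection point (ms); drifts cross zero here, so no
#'   BP shift is planted in any condition.
#' @param subject_sigma_sd,subject_t0_sd SDs of log-normal subject-level
#'   multipliers on the channel widths and nondecision time.
#' @return List of class `observer_config`.
#' @export
observer_config <- function(modality = c("auditory", "visual"),
                            sigma_sensory = NULL,
                            sigma_motor_base = 0.20,
                            freq_gain = c("4" = 1, "8" = 2, "12" = 4),
                            amp_gate = NULL,
                            k = 0.56, a = 1.5, z = 0.5, t0 = 0.35,
                            alpha = 2, bp_true = 2000,
                            subject_sigma_sd = 0.15,
                            subject_t0_sd = 0.10) {
  modality <- match.arg(modality)
  if (is.null(sigma_sensory)) {
    sigma_sensory <- if (modality == "auditory") 0.17 else 0.28
  }
  if (is.null(amp_gate)) {
    amp_gate <- if (modality == "auditory") c("1" = 1, "2" = 1, "3" = 1)
    else c("1" = 0, "2" = 0, "3" = 1)
  }
  if (any(diff(freq_gain) < 0)) {
    stop("'freq_gain' must be non-decreasing in frequency", call. = FALSE)
  }
  stopifnot(sigma_sensory > 0, sigma_motor_base > 0, all(freq_gain > 0),
            all(amp_gate >= 0), all(amp_gate <= 1), k > 0)
  structure(list(modality = modality, sigma_sensory = sigma_sensory,
                 sigma_motor_base = sigma_motor_base,
                 freq_gain = freq_gain, amp_gate = amp_gate,
                 k = k, a = a, z = z, t0 = t0, alpha = alpha,
                 bp_true = bp_true,
                 subject_sigma_sd = subject_sigma_sd,
                 subject_t0_sd = subject_t0_sd),
            class = "observer_config")
}

#' Combined sensorimotor width for one tremor condition
#'
#' Evaluates the observer's motor-channel width at the given amplitude and
#' frequency and fuses it with the sensory width via inverse-variance
#' combination ([combine_estimates]).  Non-decreasing in frequency.
#'
#' @param observer An [observer_config].
#' @param amplitude_N,frequency_Hz Condition levels (must be named in the
#'   observer's gain/gate tables).
#' @return The combined width (same scale as the channel widths).
#' @examples
#' ob <- observer_config("auditory")
#' condition_sigma(ob, 1, 4) < condition_sigma(ob, 1, 12)
#' @export
condition_sigma <- function(observer, amplitude_N, frequency_Hz) {
  stopifnot(inherits(observer, "observer_config"))
  gain <- observer$freq_gain[as.character(frequency_Hz)]
  gate <- observer$amp_gate[as.character(amplitude_N)]
  if (any(is.na(gain)) || any(is.na(gate))) {
    stop("amplitude/frequency level not in the observer configuration",
         call. = FALSE)
  }
  gain_eff <- 1 + (gain - 1) * gate
  sigma_m <- observer$sigma_motor_base * gain_eff
  vs <- observer$sigma_sensory^2
  vm <- sigma_m^2
  unname(sqrt(vs * vm / (vs + vm)))
}

#' Generate the trial skeleton for one or more subjects
#'
#' Fully crossed duration x amplitude x frequency x repetition design per
#' subject, with a tremor direction drawn uniformly on [0, 180) degrees for
#' every trial and trial order shuffled within subject.  No responses are
#' attached.
#'
#' @param design A [design_config].
#' @param n_subjects Number of subjects (default from the design).
#' @return Data.frame with `subject`, `trial`, `duration_ms`,
#'   `amplitude_N`, `frequency_Hz`, `direction_deg`.  Uses R's global RNG.
#' @export
generate_design <- function(design = design_config(),
                            n_subjects = design$n_subjects) {
  stopifnot(inherits(design, "design_config"))
  one <- expand.grid(duration_ms = design$durations_ms,
                     amplitude_N = design$amplitudes_N,
                     frequency_Hz = design$frequencies_Hz,
                     rep = seq_len(design$reps_per_cell),
                     KEEP.OUT.ATTRS = FALSE)
  one$rep <- NULL
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    ord <- sample.int(nrow(one))
    df <- one[ord, , drop = FALSE]
    df$subject <- sprintf("S%02d", i)
    df$trial <- seq_len(nrow(one))
    df$direction_deg <- stats::runif(nrow(one), 0, 180)
    df
  }))
  rownames(out) <- NULL
  out[, c("subject", "trial", "duration_ms", "amplitude_N",
          "frequency_Hz", "direction_deg")]
}

#' Generate a full synthetic experiment (trial table with responses)
#'
#' Draws subject-level multipliers (log-normal on the channel widths and
#' nondecision time), computes each trial's combined sensorimotor width
#' via [condition_sigma], maps it to a drift rate
#' `v = k * (log(duration) - log(bp_true)) / sigma_combined`, and
#' simulates the choice and RT of every trial with the Levy-flight
#' diffusion.  Placeholder movement kinematics columns (`move_length_cm`,
#' `move_force_N`) are emitted with no planted structure.
#'
#' @param modality `"auditory"` or `"visual"`.
#' @param n_subjects Subjects to simulate.
#' @param seed Integer seed; the whole table is a deterministic function
#'   of it.
#' @param design A [design_config].
#' @param observer An [observer_config]; defaults to the modality's
#'   default observer.
#' @param dt,max_t Diffusion integration settings.
#' @return Trial table: `subject`, `modality`, `trial`, `duration_ms`,
#'   `amplitude_N`, `frequency_Hz`, `direction_deg`, `choice`
#'   ("short"/"long"; NA when censored), `rt_ms`, `censored`,
#'   `move_length_cm`, `move_force_N`.
#' @examples
#' \donttest{
#' tt <- generate_experiment("auditory", n_subjects = 2, seed = 42)
#' nrow(tt)  # 2 * 378
#' }
#' @export
generate_experiment <- function(modality = c("auditory", "visual"),
                                n_subjects = NULL, seed = 1,
                                design = design_config(),
                                observer = NULL,
                                dt = 0.001, max_t = 10) {
  modality <- match.arg(modality)
  if (is.null(observer)) observer <- observer_config(modality)
  stopifnot(inherits(observer, "observer_config"))
  if (is.null(n_subjects)) n_subjects <- design$n_subjects
  set.seed(as.integer(seed))

  skel <- generate_design(design, n_subjects)
  skel$modality <- modality

  subj <- unique(skel$subject)
  sig_mult <- stats::rlnorm(length(subj), 0, observer$subject_sigma_sd)
  t0_mult <- stats::rlnorm(length(subj), 0, observer$subject_t0_sd)
  names(sig_mult) <- names(t0_mult) <- subj

  # combined width per design cell (precomputed), then per-trial drift
  cells <- expand.grid(amplitude_N = design$amplitudes_N,
                       frequency_Hz = design$frequencies_Hz)
  cells$sigma <- mapply(function(a, f) condition_sigma(observer, a, f),
                        cells$amplitude_N, cells$frequency_Hz)
  key <- paste(skel$amplitude_N, skel$frequency_Hz)
  sig_cell <- cells$sigma[match(key, paste(cells$amplitude_N,
                                           cells$frequency_Hz))]
  sigma_trial <- sig_cell * sig_mult[skel$subject]
  v_trial <- observer$k *
    (log(skel$duration_ms) - log(observer$bp_true)) / sigma_trial

  out_list <- lapply(subj, function(s) {
    i <- which(skel$subject == s)
    sim <- cpp_simulate_levy(v_trial[i], observer$a, observer$z,
                             observer$t0 * t0_mult[s], observer$alpha,
                             dt, max_t)
    df <- skel[i, , drop = FALSE]
    df$choice <- ifelse(is.na(sim$choice), NA_character_,
                        c("short", "long")[sim$choice + 1L])
    df$rt_ms <- sim$rt * 1000
    df$censored <- sim$censored
    df
  })
  out <- do.call(rbind, out_list)
  # placeholder kinematics, no planted structure
  out$move_length_cm <- stats::rlnorm(nrow(out), log(40), 0.25)
  out$move_force_N <- stats::rlnorm(nrow(out), log(3), 0.25)
  rownames(out) <- NULL
  out[, c("subject", "modality", "trial", "duration_ms", "amplitude_N",
          "frequency_Hz", "direction_deg", "choice", "rt_ms", "censored",
          "move_length_cm", "move_force_N")]
}
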