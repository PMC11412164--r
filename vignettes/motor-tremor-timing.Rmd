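---
title: "Modelling motor-tremor effects on duration judgments: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling motor-tremor effects on duration judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tremortime)
```

This vignette is the package's account of the models it implements, the
assumptions behind them, the parameters that matter, and the numerical and
design choices that were genuinely open.  Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The cue-combination model

Duration estimates from two channels — a sensory modality (auditory or
visual) and the motor system — are modelled as Gaussians with means
$\mu_S, \mu_M$ and standard deviations $\sigma_S, \sigma_M$.  Optimal
fusion weights each channel by the other's variance,

$$w_M = \frac{\sigma_S^2}{\sigma_S^2 + \sigma_M^2}, \qquad
\mu_{SM} = w_S\mu_S + w_M\mu_M, \qquad
\sigma_{SM}^2 = \frac{\sigma_S^2\,\sigma_M^2}{\sigma_S^2 + \sigma_M^2},$$

equivalently $1/\sigma_{SM}^2 = 1/\sigma_S^2 + 1/\sigma_M^2$.  Three
consequences drive everything downstream: the fused width is strictly
below both inputs; adding noise to one channel degrades the fusion at most
to the other channel's width (a ceiling at $\sigma_S$); and the *rise* of
the fused width over a fixed noise sweep grows with the base width, so a
less precise base modality has more to lose.  `noise_response_curve()`
tabulates these prediction curves.

**Scale.**  The package stores widths as standard deviations (squaring
internally) and is agnostic about whether estimates live on linear or
logarithmic duration; it never converts between scales.  This was left
open deliberately: every combination identity used here is scale-free.

## 2. The Lévy-flight drift-diffusion model

Choice and RT in temporal bisection are modelled as evidence accumulation
between absorbing boundaries at $0$ ("short") and $a$ ("long"), starting
at $za$, with drift $v$ and i.i.d. momentary noise.  Per Euler step of
size $\Delta t$,

$$x \leftarrow x + v\,\Delta t + \Delta t^{1/\alpha}\,\xi,$$

where $\xi$ is symmetric alpha-stable with exponent
$\alpha \in (1, 2]$.  RT is the absorption time plus a nondecision time
$t_0$.

Numerical choices, each of which was open:

- **Noise standardisation.**  Stable variates are drawn by the
  Chambers–Mallows–Stuck construction and rescaled by $1/\sqrt 2$ so that
  $\alpha = 2$ yields exactly unit-variance Gaussian increments.  This
  pins the $\alpha = 2$ case to the unit-diffusion Wiener process, whose
  absorption probability $(1 - e^{-2vza})/(1 - e^{-2va})$ and mean exit
  time are closed-form — the quantitative oracle for the whole simulator.
  Other Lévy-diffusion implementations may scale increments differently;
  comparisons of fitted $\alpha < 2$ parameters across implementations are
  therefore approximate.
- **Boundary treatment.**  At $\alpha = 2$ the simulator applies the exact
  Brownian-bridge within-step crossing probability
  ($e^{-2(a-x_{old})(a-x_{new})/\Delta t}$ and its lower-boundary
  analogue), which removes the $O(\sqrt{\Delta t})$ Euler first-passage
  bias; this is what lets a 1 ms (or, in fitting, 4 ms) step match the
  closed form within Monte-Carlo error.  No analogous exact correction
  exists for $\alpha < 2$, where plain Euler absorption is used.
- **Step and horizon.**  Default $\Delta t = 1$ ms; decision time is
  capped at 10 s and capped trials are flagged `censored`, never silently
  dropped.  Censoring is absent at the parameter ranges the package uses.
- **CV versus alpha is not globally monotone.**  Under this
  standardisation, lowering $\alpha$ narrows the central body of the noise
  while thickening its tails; near $\alpha \approx 1.5$–$1.75$ the two
  effects nearly cancel, and the precision loss becomes clear only below
  that.  The scaling-study signature "lower alpha, higher CV" is therefore
  asserted between the endpoints of the 0.75 cascade
  ($\alpha = 2$ versus $\alpha = 1.125$), not strictly across all three
  levels.

**Stimulus coding.**  Each of the 7 durations carries its own signed
drift, antisymmetric in log duration about the 2,000 ms geometric mean
(`bisection_drifts()`); positive drifts point to "long".  The scaling
study (`simulate_scaling_study`) multiplies one target parameter
(`v`, `a`, or `alpha`) by 0.75 per level — e.g. drifts 2, 1.5, 1.125 —
holding everything else fixed; `z` is stored as a fraction of `a` so
boundary scaling preserves relative bias.  Alpha cascades that would leave
$(1, 2]$ are clipped to 1.01 with a warning.

## 3. Psychometric fitting and its limits

Curves are fit by binomial maximum likelihood of the cumulative Gumbel on
log10 duration,

$$F(x) = 1 - \exp\{-\exp[(\log_{10}x - m)/s]\},$$

with guess/lapse rates fixed at 0 (configurable), the orientation fixed as
written (the mirrored "Gumbel" variant exists; this one is increasing in
$x$ with quantiles $F^{-1}(p) = 10^{\,m + s\ln(-\ln(1-p))}$).  BP is
$F^{-1}(0.5)$ and CV is $[F^{-1}(0.75) - F^{-1}(0.25)]/(2\,\mathrm{BP})$.
Perfectly separated data have an unbounded scale likelihood; the fit is
then floored at `min_s` and flagged rather than rejected.  Curves with
fewer than 30 trials are flagged `low_n`.

Two honest limitations, both verified in the test suite:

- **Small-sample error floor.**  At the design's 42 trials per condition
  cell, the maximum-likelihood BP and CV estimates carry median absolute
  errors of roughly 5% and 20% respectively — and this is
  information-limited, not an optimiser artefact: an independent route to
  the same MLE (a binomial GLM with cloglog link, an exact
  reparameterisation) lands on the same floor.  The errors shrink as
  $1/\sqrt{n}$ and reach ~2%/~7% at ten times the trials.  Analyses that
  need precise per-cell CVs should pool (the pipeline's collapsed
  per-frequency fits use 126 trials).
- **Family offset of the BP.**  Fitting the asymmetric Gumbel to data
  generated by a log-symmetric observer shifts the fitted 0.5 point a few
  percent upward — identically in every condition, so condition
  *differences* in BP (the quantity of scientific interest) are
  unaffected.

RT filtering applies the absolute 200–2,000 ms window first and the
per-subject 3 SD rule on log RT second, computed on the windowed data, so
gross outliers cannot inflate the SD; the exclusion log counts each rule
separately, and the procedure is idempotent.

## 4. Diffusion-parameter estimation at desk scale

Hierarchical MCMC is out of scope; parameters are estimated per condition
by quantile-probability fitting: observed response proportions and RT
quantiles at $\{.1,.3,.5,.7,.9\}$ define 12 bins per duration (6 per
choice; a choice with fewer than 5 trials contributes its proportion as a
single bin), and a chi-square discrepancy against model bins is minimised.
Model bins are computed by simulating 2,000 trials per duration at each
proposal under common random numbers (the same RNG substream every
evaluation), which makes the objective deterministic and optimisable by
Nelder–Mead.  Design choices:

- Drift per duration; `a`, `z`, `t0` (and `alpha`) shared per condition.
- Multi-start (default 4) around a data-driven start (`t0` near the
  fastest RTs; drifts from choice proportions through the Wiener
  absorption formula), with box bounds `v` ∈ ±8, `a` ∈ [0.3, 4],
  `z` ∈ [0.05, 0.95], `t0` ∈ [0.01, 2] s — the plausible range for
  seconds-scale bisection data — and the simulation horizon capped at
  1.5× the slowest observed RT.
- Fitting simulations use a 4 ms step: the bridge correction keeps
  $\alpha = 2$ unbiased at any step, and 4 ms is far finer than the
  ~100 ms quantile-bin widths being matched.
- `alpha`, when freed, is profiled on the grid
  $\{1.2, 1.4, 1.6, 1.8, 2.0\}$ and refined continuously around the best
  grid point, because the objective is noisy in `alpha`.

Recovery at $n = 5{,}000$ trials (the scale the acceptance script uses)
returns drift and boundary with single-digit-percent median error and
$t_0$ within a few ms; on Wiener-generated data a freed `alpha` stays near
2 rather than absorbing spurious structure.

## 5. Behavioural statistics

`rm_anova` implements the classical balanced within-subject decomposition
(each effect tested against its subject-by-effect interaction), reporting
uncorrected degrees of freedom by default — Greenhouse–Geisser correction
(Box's epsilon from orthonormal effect contrasts) sits behind a flag.
Unbalanced input is an error, never imputed; with balanced data the
sum-of-squares "types" coincide, which is why the simple balanced
computation suffices.  Linear contrasts use rank-coded, centered level
weights (−1, 0, 1 for three levels) — the package codes frequency by level
index, not Hz.  The Mann–Whitney slope comparison uses the exact null
distribution up to group size 20 without ties, the continuity-corrected
normal approximation otherwise, and reports the rank-biserial correlation
$1 - 2U/(n_1 n_2)$, positive when the first group's values sit below the
second's.  Tremor directions bin as [0, 60], (60, 120], (120, 180) —
integer edges land in the lower bin, matching an integer-degree reading of
0–60 / 61–120 / 121–180.

## 6. The generative observer: what it emulates and what it does not

`generate_experiment` produces complete sessions with the two experiments'
design: 378 trials per subject (7 log-spaced durations 1,000–4,000 ms × 3
amplitudes × 3 frequencies × 6 repetitions), tremor direction uniform on
[0, 180)°, trial order shuffled per subject, 24 subjects per modality.

The observer chain is: motor width
$\sigma_M = \sigma_{M,\mathrm{base}} \cdot g_{\mathrm{eff}}$, with
$g_{\mathrm{eff}} = 1 + (g_f - 1)\,\gamma_a$ — a frequency gain $g_f$
gated by amplitude $\gamma_a$ — fused with $\sigma_S$ by the equations of
section 1; the fused width sets each trial's drift
$v = k\,(\ln d - \ln 2000)/\sigma_{SM}$, and choice/RT come from the
diffusion of section 2.  Because drifts cross zero at 2,000 ms in every
condition, no BP shift is planted anywhere, while wider fused estimates
flatten the psychometric curve (higher CV).  The gate is implemented as a
scaling of the frequency *gain* rather than of $\sigma_M$ itself, since a
multiplicative gate on $\sigma_M$ cannot express "frequency matters only
at high amplitude".

Defaults, chosen once:

- $\sigma_S$: 0.17 (auditory), 0.28 (visual).  Auditory-better-than-visual
  is the well-documented ordering; the ratio (~1.65) is set so the planted
  cross-modal difference in CV-versus-frequency slopes is detectable at 24
  subjects per group given the ~20% CV estimation noise of 42-trial fits
  (section 3) — with a smaller ratio the fusion ceiling leaves too little
  slope separation for the rank test to find.
- $\sigma_{M,\mathrm{base}} = 0.20$, frequency gains $(1, 2, 4)$ at 4, 8,
  12 Hz.  The motor channel is comparable to the sensory widths at
  baseline and degrades past them at high frequency — the regime in which
  fusion hands weight back to the sensory channel and the noise effect
  saturates toward $\sigma_S$, reproducing the "noise hurts the weaker
  base modality more" geometry by construction rather than by tuning.
- Amplitude gates: auditory $(1, 1, 1)$ (frequency bites at every
  amplitude; no amplitude effect), visual $(0, 0, 1)$ (frequency bites
  only at 3 N — the planted interaction probed by simple main effects).
- Diffusion: $a = 1.5$, $z = 0.5$, $t_0 = 0.35$ s, $\alpha = 2$;
  $k = 0.56$, calibrated once so baseline auditory CV ≈ 0.17.
- Subject heterogeneity: log-normal multipliers, SD 0.15 on the channel
  widths (a shared precision trait) and 0.10 on $t_0$.
- Movement kinematics columns (`move_length_cm`, `move_force_N`) are
  placeholders with no planted structure; their analyses are out of scope.

**What passing tests do and do not show.**  The generator emulates the
*statistical* structure the analysis assumes — planted precision effects,
a null accuracy effect, subject heterogeneity, RT distributions from a
plausible decision model.  It does not emulate tremor physics, movement
trajectories, attention lapses, sequential effects, or learning across a
session; recovery of planted effects here demonstrates that the pipeline
detects what it is supposed to detect at the published sample sizes, not
that real data contain such effects.

## 7. Problem sizes

The test suite and acceptance script run at desk scale, chosen as the
package's own defaults: 100 replicate experiments (24 subjects each) for
planted-effect detection rates in the suite (60 in the acceptance script),
50,000 trials per level for the scaling study, $10^5$ trials for the
simulator-versus-closed-form check, 500 replicates for psychometric
recovery, and 12–20 seeds at $n = 5{,}000$ for diffusion recovery.  The
full-scale variant of the scaling study (1.4 million trials per level) is
a single argument change (`n_per_level`).
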