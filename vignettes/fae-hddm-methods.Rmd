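---
title: "Modeling gender face aftereffects with a hierarchical drift diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gender face aftereffects with a hierarchical drift diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faeddm)
```

## The experiment and the scientific question

In a gender face-aftereffect (FAE) task, a participant adapts to a face
(either androgynous, 50% male, or clearly male, 98% male) and then
classifies a briefly shown test face — morphed to 20, 40, 60, or 80% male —
as male or female. Prolonged exposure to the male adaptor biases subsequent
judgments toward "female": the aftereffect. Comparing the size and dynamics
of this bias between an autistic and a neurotypical group probes whether
perceptual priors and sensory evidence are weighted differently in autism.

`faeddm` implements the full analysis chain for such two-group experiments:
a synthetic-data generator emulating the design (two adaptor blocks of 128
trials each: 32 repetitions x 4 morph levels), trial- and participant-level
exclusion rules, a model-free mixed ANOVA on response proportions, a
hierarchical Bayesian drift diffusion model (hDDM) with a Wiener
first-passage-time likelihood, posterior contrast tests with FDR-adjusted
credible intervals, and posterior predictive checks. Because clinical data
of this kind are typically not deposited, the package treats parameter
recovery on synthetic cohorts as its primary validation surface.

## The diffusion model

Each trial is modeled as noisy evidence accumulating between two absorbing
boundaries separated by $a$ (response caution), starting at a fraction
$b \in (0,1)$ of that distance (response bias; the upper boundary is "male"
throughout the package), drifting at rate $v$ (positive toward "male"), with
a non-decision time $t$ added to the first-passage time. The diffusion
coefficient is fixed at 1 — the scaling convention under which all four
parameters are interpreted; any other choice would only rescale $a$ and $v$.

The trial likelihood is the defective Wiener first-passage-time (wfpt)
density over (choice, RT) pairs, written on *signed* reaction times:
positive RTs are male responses, negative RTs female responses. The density
is evaluated through the two complementary series expansions — the
small-time expansion over mirrored start points and the large-time sine
series — switching automatically to whichever needs fewer terms for a
truncation error of 1e-10 per evaluation. Evaluation is in C++
(`src/wfpt.cpp`) because the sampler needs tens of millions of density
calls per fit.

Two simulators are provided. The default draws exactly from the
first-passage distribution by numerically inverting the two defective CDFs,
tabulated by trapezoidal quadrature on an 8192-point grid whose extent
adapts outward for heavy tails and inward when the mass is concentrated
near zero (extreme drifts or tiny boundaries). We chose exact inversion
over the common Euler–Maruyama path simulation as the default because it
has no discretization bias and is orders of magnitude faster when many
trials share one parameter set; Euler–Maruyama (`method = "euler"`, default
step 1e-4 s) is retained and the two are cross-checked against each other
and against the density in the test suite (Kolmogorov–Smirnov distance at
n = 1e5, alpha = 0.01).

Closed-form companion: the probability of absorbing at the male boundary is
$P = \mathrm{expm1}(-2vab)/\mathrm{expm1}(-2va)$, with the drift-free limit
$P = b$ handled analytically.

## What the generator emulates — and what it does not

`fae_config()` fixes the study conditions: 29 + 39 participants, 32
repetitions per morph per condition (128 trials/condition), adaptor block
order counterbalanced by participant parity, and a 2200 ms response window
(200 ms test face + 2000 ms response screen; responses beyond the window
are recorded as omissions, since how late responses were handled is not
part of the design description). Contaminants are injected at plausible
rates chosen once: 2% omissions, 1% fast guesses uniform on (0, 250) ms
with a random key, and 1% slow outliers uniform on the last quarter of the
response window. Group-level truths place drift means on an increasing
scale from -1.5 (20% male) to +1.5 (80% male), with the male adaptor
shifting drift downward at every morph (0.4 at the extremes, 0.9-1.0 at the
ambiguous interior morphs, where aftereffects are behaviorally largest) and
shifting the start point from 0.50 to 0.45. Between-subject spread uses
precisions tau_a = 8, tau_t = 100, tau_b = 100, tau_v = 2 — SDs of roughly
0.35, 0.1, 0.1, and 0.7, typical for adolescent cohorts in two-choice
tasks. The `male_drift_reduction` scenario lowers the AUT group's drift
means by 0.5 at the predominantly male morphs (60/80%) only; `null` makes
the groups identical with no adaptor effect.

Subject-level draws falling outside a parameter's domain are *truncated*
(clamped, with a logged count) rather than resampled, so that a fixed seed
always consumes the same random numbers.

The generator deliberately does not emulate: trial-by-trial adaptation
dynamics (each trial is exchangeable within its cell), sequential effects,
fatigue or learning drifts, attentional lapses beyond the uniform
contaminants, and inter-trial parameter variability (the extended DDM's
sv/st/sz — the fitted model has none, so the generator matches it). Passing
recovery tests therefore demonstrates that the estimation machinery is
correct under the model's own assumptions, not that real data meet them.

A known, intentional mismatch: the response window censors slow trials into
omissions and the exclusion chain truncates at the slow-RT cutoff, but the
wfpt likelihood models neither. Maximum-likelihood probes show this biases
the boundary downward by a few hundredths of an evidence unit at the
default settings — visible as a small negative bias on `mu_a` in recovery
reports, well inside the posterior spread at the cohort sizes used.

## Exclusion rules

The chain mirrors standard practice in this paradigm, in a fixed
attribution order so reports are deterministic: (1) the first three trials
of each participant's *condition block* — each block is a fresh adaptation
context, which is why the rule is applied per block rather than per session
(a configuration switch, since either reading is defensible); (2) response
omissions; (3) RTs below 250 ms; (4) RTs above the pooled mean + 3 SD of
all surviving responded trials — pooled across groups because a single
global cutoff is the convention this analysis follows. Participants are
excluded at the study level when more than a third of their trials are
omissions, and at the model level when fewer than 50% of their trials
survive (exactly 50% is kept). The slow threshold is always recomputed from
data and recorded in the report; note that a mean + 3 SD rule re-estimated
on its own output necessarily shrinks, so "re-running the chain changes
nothing" holds with respect to the *recorded* threshold, which the report
carries for exactly that purpose.

## The model-free analysis

Male-response proportions per participant x adaptor x morph cell (responded
trials only) feed a 2 (Group, between) x 2 (Adaptor) x 4 (Morph) mixed
ANOVA. Proportions rather than counts are the response so that cells with
different numbers of surviving trials remain comparable. Sums of squares,
df, and F come from the balanced least-squares decomposition
(`stats::aov` error strata); participants with an empty cell are dropped
and reported. Greenhouse–Geisser epsilon is computed from the pooled
within-group covariance of orthonormalized within-subject contrast scores
and applied *unconditionally* to every effect involving the four-level
morph factor — simpler and slightly conservative compared to correcting
only after a significant Mauchly test (the conditional variant is just a
matter of reading the uncorrected column; both are reported). Mauchly's W
and its chi-square approximation are reported for the morph and
adaptor x morph effects (a two-level factor is spherical by construction,
W = 1, epsilon = 1), and Levene's test (absolute deviations from the group
mean of participant-mean proportions, `car::leveneTest` with mean
centering) checks between-group homogeneity. The implementation is verified
against an explicit marginal-means oracle to 1e-10 and against
`car::Anova`'s epsilon and corrected p-values.

## The hierarchical model and its sampler

Every participant $p$ has one boundary $a_p$ and non-decision time $t_p$,
one start point $b_{p,\mathrm{adaptor}}$ per adaptor, and one drift
$v_{p,\mathrm{adaptor},\mathrm{morph}}$ per cell; each is drawn from the
normal distribution of its group-level cell with mean $\mu$ and precision
$\tau$. With two groups this yields 2 + 2 + 4 + 16 = 24 group-level cells.
The $\mu$ cells get broad normal hyperpriors truncated to the parameter
domain (centers a = 1.5, t = 0.3 s, b = 0.5, v = 0; scales 2, 1, 1, 3) and
the $\tau$ cells gamma(0.1, 0.1) hyperpriors (mean 1, variance 10) — all
exposed as configuration, since reference defaults for this model family
are conventional rather than derived.

The sampler is Metropolis-within-Gibbs, blocked so every proposal touches
only the trials it affects: subject-level parameters move by adaptive
random-walk Metropolis (step sizes tuned toward 44% acceptance during
burn-in, separately per subject and parameter), while all 48 group-level
cells are updated by *exact* conjugate Gibbs draws — truncated-normal for
each $\mu$ given its subjects, gamma for each $\tau$. Chains are
independent given distinct sub-seeds and bit-reproducible. Convergence is
monitored with the split-chain Gelman–Rubin statistic (each chain halved
before computing the between/within variance ratio — stricter than the
unsplit original) at the conventional 1.01 threshold; a failed check raises
a recoverable warning that still carries all draws and diagnostics.

Default run lengths follow the reference configuration (2 chains x 20,000
iterations, 15,000 burn-in, 5,000 retained per chain). The test suite and
the acceptance script run scaled-down problems chosen as this package's own
validation sizes: 8 participants/group with 16 trials per morph per
condition for convergence and recovery (2 chains, 12,000-24,000
iterations), 20 recovery replicates, and 30 null replicates for
false-discovery calibration. Correctness of the machinery is established
separately by a conjugate reduction: with the likelihood swapped for a
unit-variance Gaussian (a built-in test hook), the marginal posterior of a
cell mean has a closed form that the sampler reproduces within Monte Carlo
error.

A note on prior-predictive behavior: with the deliberately weak gamma(0.1,
0.1) precision hyperpriors, raw prior draws of *subjects* can be arbitrarily
dispersed — that is what weakly-informative means here. Prior-predictive
sanity is therefore assessed at the hyperprior-drawn *cell means* (the
central subject of each draw), where typical simulated RTs fall inside the
response window.

## Contrast testing

Hypothesis tests are iteration-wise posterior differences: for cells A and
B, the 10,000 pooled draws (5,000 x 2 chains, aligned by chain and
iteration) of A - B; interactions use nested subtractions
(A1 - A2) - (B1 - B2). Each contrast gets a two-sided posterior tail
probability $p = 2\min(\Pr(d \le 0), \Pr(d \ge 0))$, floored at the draw
resolution. One Benjamini–Hochberg step-up threshold is computed over the
whole family tested in a run — the standard 16-member drift family comprises
the 8 cell-wise group differences plus the 8 adaptor (aftereffect)
differences — and every member's credible interval is then taken at the
adjusted coverage: threshold $p^* $ gives the central
$(1-p^*)$ interval, e.g. $p^* = 0.027$ gives the 97.3% interval with
bounds at the 1.35th and 98.65th percentiles. A contrast is credible when 0
lies outside its interval; when nothing passes the step-up rule, intervals
are reported at the unadjusted level and nothing is credible.

The interval is *equal-tailed* rather than highest-density: symmetric
percentile bounds are only generally compatible with the former, and the
family-wide threshold-to-percentile mapping above presumes them. A
highest-density variant is available behind the `hdi` flag for skewed
difference distributions. Quantiles use linear interpolation (type 7).

## Posterior predictive checks and the recovery harness

`posterior_predict()` simulates whole datasets: each replicate draws *one*
posterior iteration and re-simulates every observed trial from that
iteration's subject-level parameters, preserving per-cell trial counts
exactly — mixing draws within a replicate would understate predictive
dispersion. Summaries compare observed male-choice proportions and signed
RT quantiles (10/50/90%) per group x adaptor x morph cell against central
predictive bands; signed RTs (negative = female) are also the plotting
convention.

`recovery_study()` is the package's acceptance surface: it loops
generate → exclude → fit → contrast on a preset scenario and reports
per-cell bias, RMSE, and 95%-interval coverage of the generative truth,
plus the sign and credibility pattern of the male-morph group drift
contrast. Under the default scaled-down conditions the injected drift
reduction's sign is recovered in essentially every replicate while the null
scenario's 16-contrast family stays quiet at the nominal false-discovery
level.

## Numerical choices, degenerate inputs, limitations

* Series truncation error 1e-10 per density evaluation; density values are
  clamped at 0 against negative truncation residue.
* The inverse-CDF grid fails loudly (informative error) if the
  first-passage mass cannot be represented — reachable only for absurd
  parameter corners.
* Degenerate contrast draws (all equal) yield a zero-width credible
  interval without error; single-chain fits return `NA` diagnostics rather
  than pretending convergence was assessed.
* Out-of-domain Metropolis proposals are rejected via the likelihood's
  -Inf, so the subject-level priors remain plain normals as specified.
* Known limitations: response-window censoring and slow-trial truncation
  are not modeled in the likelihood (small downward bias on the boundary);
  the model omits inter-trial variability parameters by design; ANOVA
  F-tests on proportions near 0 or 1 inherit the usual variance
  instability, which the paired model-based analysis does not.
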