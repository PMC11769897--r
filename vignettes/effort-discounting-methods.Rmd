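---
title: "Modelling intrinsic and extrinsic control of effort-based motivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intrinsic and extrinsic control of effort-based motivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortdm)
```

## The task and the behavioural model

`effortdm` analyses an effort-based decision-making task in which the locus
of control over effort is manipulated. On *extrinsic* trials the environment
offers a number of button presses (up to a cap of 70) for an offered outcome
and the participant accepts or rejects the offer; on *intrinsic* trials the
participant self-generates the number of presses they are willing to perform
for the offered outcome. Outcomes are monetary ($0.25–$2.00) or social
(25–200 points), as wins or losses, split evenly across 228 trials, with 30%
of trials randomly selected for actual effort execution. Money and social
outcomes are mapped to a common axis by dividing each magnitude by the
maximum of its own scale, so curves are fit against a normalized outcome
`x ∈ (0, 1]`.

The central object is the effort-by-outcome discount curve: the effort `y`
(presses) a subject is willing to exert for outcome `x`. Three families are
implemented:

* linear: `y = m·x + c`;
* sigmoid: `y = c / (1 + exp(−(x − bias)/sigma))`;
* Weibull: `y = A·(1 − 2^(−(x·L)^S))`.

In the sigmoid family — the family of scientific interest — `bias` is the
outcome threshold for effort initiation (higher bias ⇒ lower motivation,
i.e. avolition) and `sigma` is the curve's width (higher sigma ⇒ a flatter
curve, i.e. lower outcome sensitivity). `flatness_order()` makes the latter
interpretation executable.

## Observation models

The task's source description does not state a likelihood linking curves to
responses, so the observation models are the package's own design choice,
picked as the minimal noise models that make both response types generative
from a single curve. The curve value at `x` is treated as the subject's
indifference effort:

* extrinsic trials: `P(accept) = 1 / (1 + exp(−(y(x) − e)/τ))` for an offer
  of `e` presses, with choice temperature `τ` (presses);
* intrinsic trials: the reported effort is Gaussian around `y(x)` with sd
  `σ_obs` (presses).

Curve evaluation itself is never clamped; clamping to `[0, 70]` happens only
at the observation stage (likelihoods and simulation), where predictions
must live on the feasible press range. Each condition involves exactly one
of the two noise parameters, and since each subject × condition block is fit
independently, τ and σ_obs are estimated per subject per condition rather
than shared across conditions — sharing would require a joint fit across
blocks, which the fit architecture deliberately avoids.

## Hierarchical empirical-Bayes fitting

Curves are fit per subject × condition (extrinsic/intrinsic × win/loss,
pooling money and social trials) inside a mixed-effects loop:

1. **Subject level.** MAP estimation in a transformed parameter space
   (log transforms for all positivity-constrained parameters; `bias`
   untransformed so it can exit `(0, 1)` for never/always-motivated
   subjects) by BFGS with deterministic multi-start (default 4 starts:
   the prior mean plus jittered copies, jitter seeded). The posterior
   covariance is the inverse Hessian at the optimum and the log model
   evidence is the Laplace approximation
   `log p(D|θ̂) + log p(θ̂) + (d/2)·log 2π − ½·log|H|`. A singular Hessian
   falls back to the prior covariance with a logged warning.
2. **Population level.** The Gaussian prior over transformed parameters is
   re-estimated per condition as (mean of posterior means, between-subject
   covariance of posterior means + average within-subject posterior
   covariance), regularized to symmetric positive definite.
3. Steps 1–2 alternate until the group log evidence (sum over all fits)
   gains less than 0.01 nats, up to 16 rounds; non-convergence sets a flag
   rather than raising.

This replaces a free-form variational scheme with MAP + Laplace under the
same fixed-form Gaussian posterior family and the same iterated
empirical-prior structure, which keeps every component separately testable
(prior update against a two-pass moment oracle, MAP against grid search,
evidence monotonicity across rounds, shrinkage of round-k estimates toward
the group mean relative to round-1 no-pooling fits).

The round-1 prior is weakly informative: bias 0.5, sigma 0.2, asymptotes at
0.75 × cap, noise 5 presses, sd 1 per transformed coordinate. For the linear
family's untransformed press-scale `m` and `c`, sd 1 would be near-delta, so
sd 25 is used there instead. Subjects making the same extrinsic button
response on every trial are excluded before fitting (they carry no choice
information), mirroring the standard deterministic-responder exclusion.

## Model comparison

Family selection uses random-effects Bayesian model selection on the
subjects × families matrix of summed log evidences (conditions pooled per
subject; a per-condition comparison is available by running the machinery
per condition). The variational Dirichlet-multinomial update starts from a
flat `α0 = 1`; exceedance probabilities are Monte-Carlo estimates from the
Dirichlet posterior (default 10^6 seeded samples, verified against the Beta
closed form at K = 2); the Bayes omnibus risk compares the free energies of
the null (equal-frequency) and random-effects models, and the protected
exceedance probability is `PXP = EP·(1 − BOR) + BOR/K`. One behaviour worth
knowing: a subject with perfectly uniform evidences does *not* pull expected
frequencies toward uniform — under the variational update its attribution
follows the group — it only concentrates frequencies less than an
evidence-aligned subject would.

## The synthetic-cohort generator

No raw data accompany the task description, so the generator is a
first-class module that encodes the study conditions. Defaults:

* groups HC (n = 74), MDD (n = 63), ANX (n = 44); online-style cohorts are
  a single unlabeled group;
* sigmoid truth per condition. Baseline HC bias: 0.35/0.45/0.55/0.65 for
  extrinsic-win/extrinsic-loss/intrinsic-win/intrinsic-loss (extrinsic more
  motivating than intrinsic, wins more than losses). Group offsets of ±0.1
  encode the qualitative effects: MDD +0.1 on extrinsic conditions (lower
  extrinsic motivation) and +0.1 on loss conditions (lower loss avoidance);
  ANX the mirror image, plus +0.4 on log sigma intrinsically (outcome
  insensitivity). Bias variance splits into a subject intercept (sd 0.20)
  and condition-level noise (sd 0.15), so the offsets are ≈ 0.4 of the total
  sd — effect magnitudes are free knobs chosen once, since only effect
  *directions* are constrained by the reported results;
* symptom scores (TEPS anticipatory/consummatory, STICSA
  cognitive/somatic, PSS, QIDS) are truncated normal within instrument
  ranges with group means/sds matching the published sample
  characteristics, and linear Gaussian couplings to standardized curve
  parameters; a coupling of `r` yields population correlation `r` between
  score and parameter. Defaults: anticipatory anhedonia ↔ extrinsic bias
  (−0.20, −0.21), consummatory anhedonia ↔ intrinsic log sigma (−0.30,
  −0.25), perceived stress ↔ intrinsic-win bias (+0.30);
* reaction times are lognormal with intrinsic trials slower (+0.45 on the
  log scale), losses slower (+0.08), and group offsets (MDD +0.12, ANX
  −0.12) reproducing the reported ordering;
* observation noise τ = σ_obs = 5 presses.

What the generator does **not** emulate: learning or feedback dynamics
(the task provides none by design), sequential effects, attention lapses,
fatigue from effort execution, item-level symptom structure, or any
particular effect *magnitudes* from real cohorts. Passing tests therefore
demonstrate that the pipeline recovers what this generative structure
encodes — not that real data satisfy the model.

## Group and symptom statistics

The statistics layer mirrors the analysis plan: univariate repeated-measures
ANOVA (control × valence within; group between when present — group
analyses run only for labeled cohorts) via `Error()`-stratified `aov`; with
2-level within factors sphericity is automatic, so no Greenhouse–Geisser
correction is implemented. Tukey post-hoc contrasts use the studentized
range. Symptom relations use partial correlations controlling for age, sex
and medication status (binary indicators), with scale-wise Bonferroni
(0.0125 for four conditions at α = 0.05). Differences between two
correlations sharing a variable use the Meng–Rosenthal–Rubin Z; printed
pairs in the source report imply one-sided p values, so `p_one_sided` is the
primary output with the two-sided value alongside. Reliability uses
Cronbach's alpha over the four condition-wise estimates and paired t tests
for test–retest data, with explicit conventions for zero-variance
differences.

## Numerical choices and problem sizes

* Convergence: Δ group log evidence < 0.01 nats, max 16 rounds.
* Multi-start: 4 jittered starts by default; the test-suite and example
  runs use 1–2 starts and 2–5 rounds at 10–40 subjects, sizes chosen to
  exercise every code path at desk scale while the defaults remain the
  full-strength settings.
* Monte-Carlo EP: 10^6 samples by default (MC error ≈ 10^-3), seeded.
* Ties in model attribution are broken by the fixed family order
  linear < sigmoid < weibull and flagged.
* Degenerate inputs have defined behaviour throughout: empty fit blocks
  return the prior with zero evidence (test mode), singular Hessians fall
  back to the prior covariance, zero-variance paired differences map to
  t ∈ {0, ±∞}.

## A worked run

```{r, eval = FALSE}
cohort <- generate_cohort(seed = 1)          # 181 subjects, 228 trials each
fits <- lapply(c(linear = "linear", sigmoid = "sigmoid",
                 weibull = "weibull"),
               fit_hierarchical, dataset = cohort,
               settings = fit_settings(seed = 1))
bms <- protected_ep(rfx_bms(evidence_matrix(fits), seed = 1))
bms$pxp                                       # sigmoid should dominate

est <- fits$sigmoid$estimates_table
lt <- long_table(est, cohort$subjects, dv = "bias")
rm_anova(lt, between = "group")
symptom_correlations(est, cohort$subjects)
```

`run_pipeline(run_config(seed = 1, out_dir = "run"))` performs the same
sequence end to end and writes every stage artifact (CSV/JSON) plus a run
manifest; identical config and seed reproduce identical numeric outputs.

## Known limitations

* The intrinsic report likelihood is a continuous Gaussian while simulated
  reports are rounded to integer presses; at σ_obs ≥ 1 press the
  discretization is negligible, but likelihoods at σ_obs ≪ 1 would be
  miscalibrated.
* Asymptotes are fit per condition; a shared-asymptote variant would need a
  joint subject-level fit across blocks.
* The empirical-Bayes covariance update ignores uncertainty in the prior
  parameters themselves (no hyperprior), as is standard for parametric
  empirical Bayes.
* Offered-effort levels and outcome grids default to 6 and 8 equally spaced
  levels over the published ranges; the true item lists were not published,
  so these are design choices, configurable in `schedule_config()`.
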