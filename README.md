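# effortdm

Effort-based decision making under intrinsic and extrinsic control:
simulation, discount-curve modelling, Bayesian model selection, and group
statistics.

## The problem

Effort-based tasks usually measure *extrinsic* control of motivation: the
environment offers "this much effort for this much outcome" and the
participant accepts or rejects. This package analyses a task that adds an
*intrinsic* control condition — the participant self-generates the effort
level they are willing to exert for an offered outcome — crossed with
win/loss valence and monetary/social outcomes. It is aimed at computational
psychiatry researchers who want to quantify amotivation and outcome
(in)sensitivity in clinical groups (e.g. depression, anxiety) and relate
them to symptom dimensions such as anticipatory vs. consummatory anhedonia.

Behaviour is summarised by an effort-by-outcome discount curve, the effort
*y* (button presses, capped at 70) a subject will exert for a normalized
outcome *x* ∈ (0, 1]. Three families are implemented:

* linear: *y = m·x + c*
* sigmoid: *y = c / (1 + exp(−(x − bias)/σ))*
* Weibull: *y = A·(1 − 2^(−(x·L)^S))*

In the sigmoid family, **bias** is the outcome threshold for effort
initiation (higher bias = lower motivation) and **sigma** is the curve
width (higher sigma = flatter curve = lower outcome sensitivity).

Curves are fit per subject × condition inside a hierarchical
empirical-Bayes loop (MAP + Laplace evidence, with the population
distribution of subject posteriors iterated as the prior for the next
round), families are compared by random-effects Bayesian model selection
with the **protected exceedance probability** (PXP = EP·(1−BOR) + BOR/K) as
the selection metric, and the winning family's parameters feed
repeated-measures ANOVAs, Tukey post-hoc tests, covariate-adjusted partial
correlations with scale-wise Bonferroni correction, dependent-correlation Z
tests, Cronbach's alpha and paired test–retest t tests. Because no raw data
are distributed with the task description, a synthetic-cohort generator is
a first-class, tested module: it encodes the task design and the
qualitative group/symptom effect structure so that every downstream stage
is testable end to end.

## A worked example

```r
library(effortdm)

# a small synthetic cohort: 8 subjects, the full 228-trial schedule
cohort <- generate_cohort(
  list(group_spec("HC", 8,
                  bias_mean = c("extrinsic-win" = 0.35,
                                "extrinsic-loss" = 0.45,
                                "intrinsic-win" = 0.55,
                                "intrinsic-loss" = 0.65))),
  seed = 2)

st <- fit_settings(max_rounds = 4, n_starts = 2, seed = 1)
fits <- lapply(c(linear = "linear", sigmoid = "sigmoid",
                 weibull = "weibull"),
               fit_hierarchical, dataset = cohort, settings = st)
fits$sigmoid
bms <- protected_ep(rfx_bms(evidence_matrix(fits), n_samples = 1e5,
                            seed = 1))
bms
```

```
Hierarchical fit: sigmoid | 8 subjects | 4 round(s), converged: FALSE
Group log evidence: -1885.19 -> -1756.68 -> -1741.98 -> -1736.71
Random-effects BMS over 3 families, 8 subjects
              linear sigmoid weibull
expected freq 0.0909  0.8025  0.1065
EP            0.0021  0.9946  0.0032
PXP           0.0117  0.9756  0.0127
BOR: 0.02883
```

The group log evidence rises over empirical-Bayes rounds as the population
prior tightens around the cohort; the sigmoid family — the generating
family — wins the comparison: a protected exceedance probability of 0.98
means it is almost certainly the most frequent data-generating family in
the population after correcting for chance evidence differences (the Bayes
omnibus risk, 0.029, is that chance probability). Two subject blocks in
this run report a singular-Hessian fallback to the prior covariance — the
documented behaviour for weakly identified blocks, warned about and
carried through.

```r
est <- fits$sigmoid$estimates_table
m <- merge(est, truth_table(cohort), by = c("subject_id", "condition"),
           suffixes = c("_hat", "_true"))
cor(m$bias_hat, m$bias_true)
```

```
[1] 0.957
```

Fitted bias tracks the generating bias closely even at 8 subjects. On a
full labeled cohort, `rm_anova()`, `tukey_posthoc()` and
`symptom_correlations()` provide the group and symptom statistics, and
`run_pipeline(run_config(seed = 1, out_dir = "run"))` executes the whole
chain (simulate → fit → compare → infer), writing every stage artifact as
CSV/JSON plus a run manifest.

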