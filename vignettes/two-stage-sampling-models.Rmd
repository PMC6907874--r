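---
title: "Modeling costly information sampling with two-stage decision models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling costly information sampling with two-stage decision models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadsampling)
```

## The task and the ideal observer

In the bead-sampling task an observer faces two jars with complementary
color ratios (60:40 or 80:20 pink to blue). One jar has been preselected;
the observer may draw up to 20 beads from it, one at a time with
replacement, each draw costing `c` points (0, 0.1 or 0.4), and then judges
which jar it was. A correct judgment pays the 10 starting points minus the
accumulated sampling cost.

For an observer who judges by majority color (guessing on ties), the
probability of a correct judgment after `n` draws is the binomial upper
tail in the majority count plus half the tie probability, and the expected
gain is `(10 - n c) p(n | q)`. `optimal_policy()` scans `n = 0..20`:

```{r}
prof <- optimal_policy(condition(0.4, 0.8))
prof$n_opt
round(prof$expected_gain, 3)
```

Accuracy is identical for `2k - 1` and `2k` draws (the extra bead either
breaks or creates a tie, with no net effect under fair tie-guessing), so at
zero cost the gain curve plateaus over each odd/even pair and the argmax is
a set; we break ties toward the largest maximizing `n`, which makes the
zero-cost optimum the sampling cap -- sampling more is never harmful there
and this matches the task's incentive structure. At positive cost the
plateaus tilt and the argmax is unique.

Behavioral optimality is summarized per participant and condition by
`efficiency()` (mean expected gain of the chosen sample sizes divided by
the attainable maximum), and by `sampling_bias_and_variability()` (mean
deviation of the sample count from the optimum; its standard deviation
across trials). `flag_noncompliant()` implements the boxplot screen
(1.5 IQR beyond the quartiles, linear-interpolation quantiles) used to
drop likely-noncompliant participant-condition observations.

## Choice models

Every stop/continue decision (after `j` beads, before the forced stop at
20) is a Bernoulli draw whose stop probability is a logistic function of
decision variables (DVs):

* **cost DVs** (5 weights): one intercept per cost level, the number of
  beads drawn `j`, and the total cost `j c`. Level-specific intercepts
  rather than a global intercept plus dummies keep the weight count at the
  canonical 11 for the two-stage models and avoid collinearity.
* **evidence DVs** (6 weights): a stage intercept, the unit log evidence
  `ln(q/(1-q))`, the absolute decayed cumulative information `|CI|`, the
  total log evidence `ln(q/(1-q)) |CI|`, and the previous trial's
  correctness and sample count. `CI` is the signed pink-minus-blue count,
  leaky with rate `alpha` (`CI' = alpha CI +/- 1`); models "without decay"
  fix `alpha = 1` so a single code path serves both.

Previous-trial correctness is coded 0/1 with a neutral 0.5 on each
participant's first trial (with `prev_n = 0`); the coding is not pinned
down by the task itself, so it is fixed here once and documented.

One-stage models use the cost DVs, the evidence DVs, or both (the combined
models drop the redundant evidence intercept). Two-stage models give each
stage its own DV set and combine them through a second-thought probability
`p_sec`: when continuing triggers the second stage,
`p_stop = p1 + (1 - p1) p_sec p2`; when stopping triggers it,
`p_stop = p1 (1 - p_sec) + p1 p_sec p2`. `p_sec` is either one free
probability per cost level, one per evidence level, or the flexible rule
`logit(p_sec) = gamma logit(p1) + phi`. Crossing stage order x trigger x
rule gives 12 two-stage models; with the 4 one-stage models the registry
(`model_registry()`) holds 16. The best-supported architecture in this
family -- cost first, continue-triggered, cost-conditioned second thoughts
-- carries 11 stage weights, 3 second-thought probabilities and 1 decay
rate.

`choice_loglik()` sums `ln p_stop` over stop choices and `ln(1 - p_stop)`
over continue choices; the forced stop at the 20-bead cap is not a choice
and is excluded. Degenerate predicted probabilities are clamped at 1e-12
and reported by a warning, never silently.

## Decision times

Only the latencies of continue choices are modeled. Each stage contributes
a lognormal latency whose expected value,
`exp(b0 + b1 (1 - p) + b2 p (1 - p))` for continuing (with `p` replaced by
`1 - p` for stopping), tracks decision difficulty through the quadratic
term; there is no separate non-decision constant -- the stage baselines
`exp(b0)` absorb it. A continue choice finalized in the second stage takes
the first-stage time (continue or stop time, depending on the trigger)
plus a second-stage increment of the same form. The observed DT of a
continue choice is therefore a two-component lognormal mixture whose
weights are the posterior probabilities that the choice was finalized in
stage 1 versus stage 2 (`stage_posteriors()`), and the joint likelihood of
a choice and its DT factorizes exactly into the choice likelihood times
the DT mixture likelihood -- `joint_loglik()` is their sum on the log
scale, and the test suite verifies the identity numerically.

## Fitting

Estimation is per participant and model, in two steps: choice parameters
are fit first by bounded maximum likelihood (second-thought probabilities
and the decay rate in [0, 1]; weights nominally unbounded, clipped at
+/-50 purely to prevent overflow); DT parameters are then fit with the
choice-derived stage probabilities frozen, so decision times never adjust
choice parameters. The optimizer is a bounded quasi-Newton search
(`nlminb`) with an analytic gradient (implemented in C++ alongside the
likelihood), a relative objective tolerance of 1e-6, and multi-start:
one fixed heuristic start plus randomized restarts whose seeds derive
deterministically from the base seed and a participant-model hash, so
results are reproducible and independent of execution order. DT baselines
`b0` and scales `sigma` are bounded positive.

Model evidence uses AICc and BIC with the observation count defined as the
number of decision times modeled for the participant (after outlier
exclusion). Fixed-effects comparison anchors each participant at their
best model (`delta_criterion()`); random-effects comparison
(`group_bms()`) treats each participant's model identity as drawn from a
population with Dirichlet-distributed frequencies (uniform prior,
pseudo-count 1), iterates the variational posterior to 1e-6, estimates
exceedance probabilities by Monte Carlo from the posterior Dirichlet, and
protects them against the null of uniform frequencies through the Bayesian
omnibus risk: `pEP = EP (1 - BOR) + BOR / K`, with the null evidence
computed exactly by log-sum-exp. Log model evidence is approximated as
`-AICc / 2`, the standard surrogate when information criteria stand in for
marginal likelihoods; this bridge is a package decision and is stated here
prominently because frequencies and exceedance probabilities inherit it.

The cost-evidence strategy index (`strategy_index()`) is the participant's
mean AICc over the six cost-first two-stage models minus the mean over the
six evidence-first models; negative values mean cost-first architectures
fit better. The analogous contrasts on the trigger and rule dimensions are
exposed by `dimension_index()` but only the stage-order contrast is tied
to a documented empirical phenomenon.

## Behavioral statistics

`preprocess_dts()` log-transforms the continue DTs and excludes points
beyond 1.5 IQR of the pooled distribution's quartiles; fences are computed
on the pooled (all-participant) distribution by default, with a per-group
option. `fit_logdt_mixture()` fits one- and two-component Gaussian
mixtures to the included log DTs by EM (via mclust). `dip_test()`
implements Hartigan's dip statistic -- the smallest sup-norm distance
between the ECDF and the class of unimodal distribution functions -- with
a bootstrap p-value under the uniform null. The dip is computed by
iterative modal-interval narrowing on the ECDF staircase: the greatest
convex minorant and least concave majorant are fit on the current
interval, the interval narrows at their largest gap while the convex and
concave fit errors of the excluded outer regions accumulate, and the
statistic is half the largest accumulated error once the residual gap is
covered (a jump at the mode bridges any single-point remainder). The
implementation is validated against exactly derivable values and against a
brute-force linear-programming solution of the defining optimization on
small samples.

`cluster_permutation_curve()` tests a running Spearman correlation curve:
participants are ranked by an index, the correlation with a covariate is
recomputed as the inclusion count grows (from 10 by default; the exact
start is a convention), pointwise significance uses the t-approximation
against zero (or an inclusion-order Monte Carlo null against the overall
correlation), adjacent same-signed significant points form clusters sized
by the absolute sum of Fisher-z values (no minimum extent), and cluster
p-values come from the permutation distribution of the maximum cluster
size under index shuffling. For the overall-reference variant the
pointwise Monte Carlo null and the cluster null reuse one set of
inclusion-order shuffles.

## The synthetic population

`simulate_population()` generates the full study design: 288 trials in
three blocked cost conditions (six block-order permutations,
counterbalanced across agents), evidence conditions mixed within block,
jars and sides counterbalanced, AQ scores drawn from a normal distribution
with mean 69.97 and SD 10.48 (rounded, clipped to the questionnaire range)
matching the scale of the emulated sample of 104 participants. Each agent
mixes a cost-first and an evidence-first two-stage process per trial with
probability `pi_costfirst = logistic(1 + 1.5 zAQ)`, so high-AQ agents are
near-pure cost-first while low-AQ agents are balanced -- the generative
embodiment of the strategic-diversity construct this pipeline is built to
detect. Per-trial mixing is the simplest mechanism that produces near-zero
strategy indices for balanced agents.

Default generative parameters (`default_agent_params()`) are package
choices, not estimates: they were tuned once so that mean sample sizes per
condition are realistic (roughly 10-12 at zero cost, 4-7 at low cost, 2-3
at high cost, lower under strong evidence), stopping hazards stay in a
plausible range, and the two DT stages (`exp(b0)` baselines of about 1.2 s
and an increment of about 1.6 s, `sigma` 0.25-0.3) are separated enough
that pooled log DTs are bimodal. Two identifiability-driven design choices
deserve emphasis. First, the evidence (second) stage of the cost-first
generators is sharp (|CI| weight 0.6, total-evidence weight 0.7): with a
soft second stage the second-thought probability trades off against the
evidence weights along a nearly flat likelihood ridge and choice-only
maximum likelihood cannot recover it, whereas a sharp stage makes the
stop-probability plateau reveal `p_sec`. Second, the representative
evidence-first generator uses the evidence-conditioned second-thought rule,
so that cost reaches stopping only through the second stage; with the
cost-conditioned rule, cost acts through both the recruitment probability
and the stage structure and the stage order is close to unidentifiable
from 288 trials. Across agents, second-thought probabilities are drawn
from Beta distributions around the defaults with concentration 5, giving
the wide across-participant spread that recovery studies need to resolve
ranks and that per-participant second-thought estimates typically show in
this paradigm; decay rates, stage intercepts and DT baselines also vary
across agents.

What the simulator deliberately does not emulate: learning or fatigue
across trials, sequential dependencies beyond the previous-trial
covariates, response-key or lapse processes, and any non-lognormal DT
contamination. Passing recovery tests on these populations therefore shows
that the estimation and comparison machinery works when the generative
assumptions hold; it does not certify the models against real-data
violations of those assumptions.

## Scales, tolerances and degenerate inputs

The test suite exercises the pipeline at reduced but statistically
meaningful scales, chosen as the package's own design points: 1e6
Monte-Carlo draws for the ideal-observer check (3 standard errors);
likelihood identities to 1e-12 (closed forms vs. tree enumeration) and
1e-10 (joint factorization); parameter recovery on 20 single-model agents
at 288 trials (second-thought rank correlation above 0.7, mixture
component means within 0.2 log-seconds of the generative stage means);
model recovery on 10 agents per generative model (majority assignment by
AICc across four representative models); BMS calibration on synthetic
evidence; the cluster permutation test's null false-positive rate over
1000 simulations at 120 permutations each (bounded by 0.07, binomial slack
over the nominal 0.05); and the three signature phenomena (bimodal pooled
log DTs, a positive mean-DT/second-thought association, and a negative
strategy-index-AQ correlation) on a 24-agent mixed population fit with all
12 two-stage models.

Known limitations: `p_sec` at the high-cost level remains weakly
identified (trials there are short, so few decision states inform the
second stage); AICc requires more modeled DTs than parameters plus one and
is reported as missing otherwise; the `-AICc/2` evidence bridge ignores
parameter-prior volume; and the two-step fit, by design, lets choice
parameters cap the attainable DT likelihood, which is what makes choices
and decision times mutually independent tests of the two-stage
architecture.
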