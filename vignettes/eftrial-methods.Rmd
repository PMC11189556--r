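---
title: "Simulating and analysing a school-based executive-function training trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a school-based executive-function training trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eftrial)
```

## What this package models

`eftrial` is a complete in-silico replica of the computational side of a
two-arm pilot randomised controlled trial of classroom-delivered digital
executive-function (EF) training in 6–8 year-olds. Simulated children carry
latent abilities in eight domains (response inhibition, interference
control, verbal and visuospatial working memory, switching, matching,
everyday EF, social-emotional wellbeing), perform the trial's six
assessment tasks trial-by-trial at three occasions (pre-intervention T1,
post-intervention T2, 3-month follow-up T3), and are analysed exactly the
way the trial's analysis plan prescribes: blocked randomisation with a
demographic balance check, descriptive outcome tables, chained-equation
imputation of missing outcomes, Bayesian latent change score (LCS) models
across a four-model group-invariance ladder, Bayes factors with a
threshold of 3, compliance classification at 16 of 20 training sessions,
and auxiliary analyses (intra-class correlations by classroom, family-wise
error control, range-restriction correction).

Because the generator's truth is known and configurable — including a true
intervention effect of exactly zero — the whole pipeline can be calibrated:
type-I behaviour of the decision rules, recovery of injected effects,
estimator bias, and staircase convergence are all testable properties
rather than assumptions.

## The cohort generator

Latent ability for child $i$, domain $d$, occasion $t$ is

$$z_{idt} = u_{c(i)} + a_{id} + e_{idt} + \delta_{dt}\,\mathbb{1}[\text{arm}_i = \text{intervention}]$$

with classroom intercepts $u_c \sim N(0, \rho_{cl})$, stable traits
$a_{id}$ drawn from an exchangeable multivariate normal with cross-domain
correlation 0.3 (the field's default assumption of correlated EFs — the
trial itself reports no generative model), and occasion noise $e_{idt}$
splitting the remaining variance so that the test-retest share is
`stability` (default 0.7). Marginal variance is 1, so the configured
`effect_sizes` are standardized latent effects; the intervention shift
$\delta$ applies at T2 and is retained at T3 in proportion
`retention_t3` (default 1, the "sustained effects" reading). Demographics
match the trial's baseline table: IQ $\sim N(104.75, 14.22)$ truncated
above the screening floor of 70, age centred at 7.46 (SD 0.61) within
6–9 years, 55% male. The continuous `ses_index` is a synthetic stand-in
(the trial reports only categorical caregiver education), used solely as an
imputation auxiliary and compliance covariate.

Adherence propensity is logit-normal (mean 0.405, SD 0.8 on the logit
scale); sessions completed are binomial over the 20 scheduled sessions,
which calibrates the cohort mean to about 12 sessions — the adherence the
trial observed. Missingness defaults are MCAR at the trial's observed
rates: 45% for the stop-signal task (software corruption in the real
study), 32% for the parent EF rating, 20% for parent wellbeing ratings,
5–8% elsewhere. A missing-at-random hook exists (`mechanism = "MAR"`)
but is off by default because the trial's missing-values analysis
supported MCAR.

## From latent ability to behaviour

`make_responder()` is the monotone link: one SD of latent ability buys a
fixed improvement in every ability-linked behavioural parameter, anchored
at `responder_defaults()` for an exactly-average child. The anchors are
set to what this age group typically produces: true stopping latency
250 ms (−50 ms per SD), go-lift SD 60 ms around the 800 ms target,
flanker conflict cost 100 ms (−30 ms per SD) with 150 ms trial noise,
backwards verbal span capacity 3.5 and spatial span 4.5 (+1 item per SD),
card-sorting perseveration probability 0.45 and lapse rate 0.20, and
per-phase rule-application accuracies for the dimensional-change task
(92%/90%/75% at the mean). Rating-scale generators emit raw subscale
values whose composites centre near the trial's baseline table (executive
composite ≈ 51, wellbeing totals ≈ 9 parent / 7 teacher). These choices
make the simulated outcome table land near the trial's descriptive
statistics, though the generator is deliberately simpler than children:
no practice effects beyond the configurable retention drift, no
ex-Gaussian RT tails, no item-level questionnaire structure. Simulated
card-sorting error rates (~0.28 at the mean) run below the trial sample's
(~0.55), because the simulated learner recovers from rule switches faster
than real 6-8 year-olds; the measurement-noise structure, which is what
the analysis calibration depends on, is unaffected.

## Task engines

Each engine consumes a policy and a seed and emits a trial-by-trial log;
every engine is deterministic given both. Key mechanics:

* **Stop-signal (anticipated response).** A planned lift time races the
  stop process, which finishes at SSD + true SSRT; ties count as
  successful inhibition (a race needs a deterministic tie rule). Schedule:
  10 practice go, 20 mixed practice (15/5), three test blocks of 60 at
  75%/25%; SSD staircase starts at 500 ms, steps ±50 ms, and is clamped
  to [300, 700] ms after every update. The source description leaves open
  whether those bounds clamp the staircase or only the initial sampling
  range; they are implemented as hard clamps and exposed in
  `staircase()`.
* **Flanker / attention network.** 24 practice + 3×48 experimental
  trials balanced over congruency and the four cue conditions. RTs are
  additive: base + conflict cost − alerting benefit (any cue) − orienting
  benefit (spatial cue) + Gaussian noise, so the three scored
  subtractions each recover one generative parameter in expectation.
* **Backwards digit span.** Spans ascend from 2 with exactly two trials
  per span, advancing on ≥1 correct and discontinuing when both trials of
  a span fail — the minimal schedule consistent with the stated
  discontinue rule (the source does not fix trials per span).
* **Corsi block tapping.** Advance requires two *consecutive* correct at
  a length (as stated); a 1-of-2 split earns one resolving third trial
  (hard cap 3 per length), after which an unresolved window discontinues.
  This interpretation is a documented, configurable decision.
* **Card sorting.** 48 non-ambiguous cards, criterion cycling
  colour→shape→number (standard administration order; configurable),
  unannounced switch after 6 consecutive correct. The responder keeps a
  believed dimension, perseverates with its policy probability after
  errors, and otherwise shifts belief deterministically to the next
  dimension in the cycle (so the zero-lapse learner is exactly traceable
  by brute force) or randomly.
* **Dimensional change card sort.** 6 pre-switch + 6 post-switch trials;
  the 12-trial cued advanced phase is administered only on ≥5/6
  post-switch correct. The pre-switch pass criterion is never stated in
  the source; ≥5/6 is used by analogy and flagged here.
* **Training exercises.** Six adaptive games per session, randomised
  order, 3 minutes each: stop staircase (±50 ms in [300, 700]), flanker
  levels (distractor count and onset-delay steps), ±1-item span
  adaptation, switching levels with rule-reversal events at advanced
  levels, and the matching change-frequency ladder (criterion changes
  after 12, 8, 6, then 4 consecutive correct). Difficulty persists across
  the 20 sessions. Trials per 3-minute block default to 40 — a simulation
  parameter, since the program fixes minutes rather than trial counts.

## Scoring

`ssrt_integration()` implements the integration method: the respond rate
on stop trials picks a quantile of the go lift-time distribution
(omissions replaced by the maximum observed lift, the consensus-guide
convention) and mean SSD is subtracted. The empirical inverse-CDF
(type-1) quantile is used and documented because SSRT moves by a few
milliseconds across quantile conventions. Respond rates of 0 or 1 are
degenerate and flagged rather than estimated. Quality control fails an
administration on any of: go response rate < 75%, go accuracy < 60%, mean
go RT < 400 ms. Two points the source leaves open are resolved and
flagged: go "accuracy" for an anticipated-response task is defined as a
lift within ±150 ms of the 800 ms target (the standard convention for
this paradigm, window configurable), and the "RT < 400 ms" rule is read
as applying to the mean RT rather than single trials. Flanker scores
exclude sub-100 ms responses and omissions before any mean; span totals
are longest span × number correct; card-sorting errors are perseverative
when they match the *immediately preceding* criterion (the stricter of
the two possible readings, flagged); the 0–3 phase ladder and advanced
total follow the stated pass rules; rating composites are raw sums
(wellbeing total excludes the prosocial subscale) or item means. These
identities are asserted property-style on every simulated log in the test
suite.

## Trial operations

Randomisation is 1:1 in permuted blocks of 10 with a partial final block
balanced to within one. The trial re-randomised on demographic imbalance
without quantifying "balance"; the defaults here are |standardized age
difference| ≤ 0.2 and gender proportion difference ≤ 0.15, configurable,
with an iteration cap and explicit failure diagnostics. Power analysis
uses the exact noncentral-t two-sample two-sided formulation (both
rejection tails) and reproduces the published design values: 105 per
group for d = 0.5 at 95% power, 42 for d = 0.8, and 83.6% / 99.7% power
at 70 per group. Missingness summaries flag measures above the 20%
retention threshold and test MCAR by logistic regression of each
missingness indicator on covariates with a likelihood-ratio test — a
documented choice, as the trial names no specific test; under MCAR these
p-values are uniform, which the suite verifies. Imputation is
fully-conditional-specification with Bayesian-draw normal regressions
(the chained-equations approach the trial used), run once (m = 1) to
mirror the trial, with m > 1 available; observed cells are never
altered, and a light ridge keeps the conditional regressions stable when
predictors approach collinearity.

## The latent change score ladder

Each analysis family pairs a two-indicator Near factor (inhibitory:
flanker conflict + stop-signal SSRT; working memory: Corsi + digit span;
flexibility: card sorting + dimensional change) with a two-indicator Far
factor (executive composite + the mean of parent and teacher wellbeing
ratings). First loadings are fixed to 1, second loadings free with no
sign constraint (the stop-signal indicator empirically loads negatively),
invariant over time and group. Occasion-2 factors decompose into baseline
plus an explicit latent change; the structural model regresses ΔNear on
Near(0) and Far(0), and ΔFar on Far(0), Near(0) and ΔNear, with IQ and
age as covariates on both changes. The ladder: Model 1 fully invariant
over arms; Model 2 frees the two change intercepts (+2 parameters);
Model 3 additionally the four baseline→change regressions (+4); Model 4
additionally the ΔNear→ΔFar coupling (+1). The trial's text mentions
single-indicator factors while its results tables show estimated second
loadings; the two-indicator version implemented here matches the tables,
and `covariates`/indicator choices are configurable rather than
adjudicated.

Estimation marginalises the latent variables analytically — the model is
linear-Gaussian, so each arm's data are 8-variate normal with structured
moments — and samples the posterior by independence Metropolis with a
multivariate-t proposal centred on the posterior mode with
Laplace-approximation covariance, interleaved with a local random-walk
step every fifth iteration. Priors are weakly informative on the
standardized scale: unit normals on locations, regressions and loadings,
half-normal(1) on SDs, uniform on the baseline factor correlation; all
indicators are standardized against the pooled baseline mean and SD
before fitting. Two chains of 500 warmup + 1500 retained iterations are
the default; split-chain R-hat and effective sample sizes are reported,
a fit is flagged (never silently accepted) when any R-hat exceeds 1.05,
and a flagged fit is automatically re-run once with doubled iterations.
The 1.05 flag is a pragmatic threshold for this sampler's chain lengths;
the reported R-hat values let stricter users apply their own cutoff.

Model criticism follows the trial's plan: a posterior predictive p-value
with a likelihood-based discrepancy (−2 log-likelihood of observed versus
replicated data at each retained draw; values near 0.5 indicate the model
reproduces its own discrepancy distribution), and leave-one-out
cross-validation from the pointwise log-likelihoods via truncated
importance sampling, reported on the LOOIC deviance scale with pairwise
differences and standard errors from the pointwise spread. The Bayes
factor for the arm effect is a Savage–Dickey density ratio on the Model-2
arm-offset parameter (prior N(0, 1)); the marginal posterior density at
zero uses a Gaussian approximation by default (a kernel estimate is
available), which is accurate here because that margin is asymptotically
normal and empirically indistinguishable from it at these sample sizes.

## Calibration results the suite computes

The test suite (and `scripts/acceptance.R`) recompute, from scratch, the
properties this design promises: exact schedule counts (135/45 go/stop
test trials) and power values; integration-method SSRT recovery within
20 ms of a known 200 ms truth over 500 simulated administrations (bias in
practice < 1 ms); 1-up-1-down staircase convergence to a stop-respond
rate in [0.45, 0.55]; pooled 95%-interval coverage ≥ 90% over replicate
fits of every ladder model at n = 400 (10 replicates per model in the
shipped smoke version; the fuller 50-replicate study is the same code
with a larger loop); leave-one-out preferring the generating model beyond
2 SE in ≥ 80% of misspecification replicates; and the full pipeline
honouring the trial's decision rules — BF01 ≥ 3 in the majority of
zero-effect replicates and BF10 ≥ 3 in the majority of replicates with a
0.8-SD injected inhibitory effect (3 replicates each at 150 per arm in
the shipped suite; the acceptance script runs one of each and reports the
Bayes factors themselves). Problem sizes in the shipped suite were chosen
as the smallest that make each property statistically decisive.

## Known limitations

The generator is MCAR-by-default and normal-in-the-tails; it will not
reproduce floor/ceiling pile-ups (the Thorndike Case 2 utility exists for
exactly that situation in real data), informative missingness, practice
effects beyond the retention drift, or rater disagreement structure
beyond independent noise. Passing calibration here demonstrates that the
pipeline's logic and estimators behave as designed under the trial's
stated assumptions — not that the trial's data satisfy those assumptions.
The LCS sampler is specialised to the two-occasion, two-indicator,
two-group design; three-occasion growth models and frequentist SEM are
out of scope.
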