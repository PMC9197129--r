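---
title: "Modelling charity choice under ingroup and outgroup social information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling charity choice under ingroup and outgroup social information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r}
library(socialddm)
```

## The decision process

Each trial presents two charity options as a 2x2 table of donor counts:
for every option, how many of 100 ingroup members and how many of 100
outgroup members already donated to it.  We model the choice between the
two options as a Wiener diffusion: evidence `X(t)` starts at `z * a`,
accumulates with mean drift `v` (and unit diffusion coefficient) and the
response is triggered when `X(t)` first hits `0` or `a`.  The **lower
boundary codes the ingroup-compliant response** — the option with the larger
ingroup/outgroup donor ratio — so negative drift means evidence sampling
toward conformity.  Observed response time is the first-passage time plus a
non-decision constant `t0`.  With across-trial drift variability `sv > 0`,
each trial's drift is drawn from `N(v, sv^2)`.  Start-point and
non-decision-time variability are not modelled: no variant in the model
space frees them.

The likelihood kernel is the defective first-passage density at the chosen
boundary.  `wiener_pdf()` evaluates it with the standard pair of series
expansions — the image-charge (small-time) sum and the sine eigenfunction
(large-time) sum — choosing whichever needs fewer terms for a truncation
error below `eps` (default `1e-7`) at each evaluation.  The `sv`-marginal
has a closed Gaussian form, so no quadrature enters the likelihood:

```
f_sv(t) = f_0(t) / sqrt(1 + sv^2 (t - t0)) *
          exp((a^2 z^2 sv^2 - 2 v a z - v^2 (t - t0)) / (2 (1 + sv^2 (t - t0))))
```

where `f_0` is the zero-drift density.  Tests verify the marginal against
brute-force quadrature of the fixed-drift density weighted by the Gaussian,
the density's integral against the closed-form absorption probability
`(e^{-2va} - e^{-2vza}) / (e^{-2va} - 1)` on a parameter grid (tolerance
`1e-6`), and the Euler-Maruyama simulator against the analytic conditional
RT distribution by a Kolmogorov-Smirnov test.

### Scale convention

The diffusion coefficient is fixed at 1 (not 0.1).  Under this convention
boundary separations near 2 and drift magnitudes of 1-3 — the ranges the
synthetic agents use — produce accuracies and sub-second response times in
the empirically typical range; it is also the convention of the R estimation
ecosystem this analysis style comes from.

## The stimulus design

`generate_stimuli()` builds the three-type design: ingroup counts for the
two options range over `[92,98] x [12,18]` (type 1), `[92,98] x [52,58]`
(type 2) and `[52,58] x [12,18]` (type 3); the outgroup counts fill each
option to 100.  The 7 x 7 grid gives 49 canonical stimuli per type; each is
emitted once more with the columns swapped (mirrored presentation), for 294
in total.  `code_compliance()` marks the option with the strictly larger
ingroup/outgroup ratio; `code_equality()` marks the option with the smaller
absolute ingroup-outgroup difference.  By construction the two codings
coincide on type 3, conflict on type 2, and type 1 offers no near-equal
option.  `build_session()` shuffles all 294 stimuli and cuts the order into
six 49-trial blocks; since the experiment interleaves stimulus types, we
shuffle at the session level rather than within blocks, and treat the block
category labels as cosmetic metadata that never enter the likelihood.  The
mirrored presentation is treated as a pure column swap; presentation side
enters no analysis.

## Trial information and the drift decomposition

Five codings reduce a group's row of the table to one covariate: `A - B`,
`A/(A - B)`, `A/B`, `A/(A + B)`, and a dichotomous indicator.  Group-1
models write the drift as `v = b0 + b1 * ingrInfo` or
`v = b0 + b1 * ingrInfo + b2 * outgrInfo`.

Two conventions are under-determined by the verbal description, and we fixed
them as follows:

* **Covariate orientation.** Because the response boundaries are
  compliant/non-compliant rather than left/right, `A` in every formula
  denotes the *compliant option's* cell and `B` the other option's cell,
  separately within the ingroup row (`ingrInfo`) and the outgroup row
  (`outgrInfo`).  This is the only orientation under which a single weight
  has a consistent meaning across trials and mirroring, and it reproduces
  the expected sign pattern: with the `A/(A+B)` coding, a negative `b1`
  drives evidence toward the compliant boundary as the compliant ingroup
  share rises.  Tests assert covariate invariance under mirroring.
* **Dichotomous coding.** The indicator is computed table-wide: 1 if the
  largest of the four cells lies in the queried group's row (the most
  literal reading of "the highest number in the trial table belongs to the
  ingroup").  The outgroup covariate is then necessarily the complement of
  the ingroup covariate, so in models with `b2` the two dichotomous
  covariates are perfectly collinear; `b1` and `b2` are then identified only
  through their sum.  We document rather than reinterpret this.

`model_space()` enumerates the 30 group-1 variants (5 codings x 3 fixation
schemes for `z`/`sv` x with/without `b2`) and the 21 group-2 variants (7
subsets of `{a, t0, v}` varying over stimulus types x 3 fixation schemes),
with ids 1-51 matching the published table layout so that "model 22" and
"model 35" mean the same thing in reports.

## Preprocessing, estimation and selection

`preprocess_trials()` drops, per subject: censored trials (no response
within the 5 s window), responses faster than 200 ms, and trials outside
three interquartile ranges of the quartiles of the log-transformed RTs.
Timeout handling is not specified by the experimental description beyond
"the next trial starts"; we exclude censored trials from the likelihood and
count them in the preprocessing report rather than modelling the censoring
mass.

`fit_subject()` minimises the negative log-likelihood with `nlminb` under
box constraints `a in [0.3, 5]`, `t0 in [0.05, min(rt) - 0.01]`,
`z in [0.05, 0.95]`, `sv in [0, 5]`, drifts and drift weights in
`[-20, 20]`.  The `t0` upper bound follows from the likelihood: any
proposed `t0` above the fastest kept response has zero density.  Restarts
use one heuristic start (`a = 1.5`, `t0 = 0.9 * min(rt)`, `z = 0.5`, drifts
0, `sv = 0.5`) plus seeded uniform draws; the draws use the full boxes for
`a`, `t0`, `z` but moderate ranges for drift-like parameters (`[-5, 5]`)
and `sv` (`[0, 2]`), because starts in the extreme corners of the formal
bounds put the optimizer on a flat, density-floored plateau and waste the
restart.  Invalid interior evaluations return a large finite penalty (the
density is floored at `1e-300`), never an error.  `BIC = k ln(n) - 2
logLik` uses the post-removal trial count `n` — the sample the likelihood
actually saw.  `select_model()` averages per-subject BICs within each model
id for cohort-level selection and breaks ties by fewer free parameters,
then lower id.

## The synthetic cohort

`simulate_cohort()` generates the study conditions the pipeline assumes: 39
subjects (28 ingroup-driven, 11 equality-driven) x 294 trials, 5 s window,
responses and RTs drawn from per-subject diffusion parameters.  Agent
parameters are drawn uniformly from strategy-specific boxes centred on the
fitted subgroup point estimates of the type-varying-drift model: shared
`a in [1.7, 2.3]`, `z in [0.42, 0.55]`, `t0 in [0.27, 0.40]` s, `sv = 0`,
and type-specific drifts near `(-2.0, -1.6, -0.9)` for ingroup-driven
agents (ordered so type 1 pulls hardest) and near `(-0.4, +1.0, -1.2)` for
equality-driven agents (type-2 drift positive: away from conformity).  Only
point estimates are available to anchor these boxes — no across-subject
distribution is published — so the half-widths (about 0.3-0.4 in each
coordinate) are our choice of a plausible between-subject spread, exposed as
configuration rather than hard-coded.  `make_info_agent()` provides the
analogous generator for information-coupled (group-1) ground truth, centred
on the fitted percent-information coefficients.  A contamination option
injects uniform fast guesses (RT below 200 ms, response at chance) to
exercise the outlier filters; it defaults to off.

What the generator does **not** emulate: slow contaminants and attention
lapses, sequential effects (learning, fatigue, post-error slowing),
between-block context effects, start-point or non-decision-time
variability, and any questionnaire-level structure (group identification,
empathy).  Passing recovery tests therefore show that the estimation and
selection machinery is correct and well-conditioned at realistic parameter
values and trial counts — not that real participants satisfy the model's
assumptions.

## Validation experiments

`recovery_experiment()` runs simulate -> preprocess -> fit -> select ->
classify against ground truth.  The test suite and the acceptance script
use:

* **Parameter recovery** — 20 subjects (14:6 mix), 294 trials each,
  refitted with the type-varying-drift model (id 35), 5 restarts.  Frozen
  tolerances: median absolute error at most 0.20 (`a`), 0.05 s (`t0`), 0.07
  (`z`), 0.50 (each drift), and true-estimate correlation at least 0.8 per
  drift.  Observed errors sit well inside these (drift MAEs near 0.1).
* **Selection recovery** — five replicates per scenario on reduced cohorts
  (6 subjects) and candidate sets: data generated with type-specific drifts
  fitted with candidates {31, 34, 35, 46} must select a varying-`v` variant
  ({34, 35, 36}) in the majority of replicates; data generated with
  percent-information drift fitted with {3, 4, 21, 22} must select a
  percent-information variant ({21, 22}).  The difference-information
  competitors are structurally unable to separate types 2 and 3 (their
  covariates coincide there), which is what the comparison detects.
* **Strategy classification** — on a default 28:11 cohort the type-2 rule
  (compliant fraction at most 50% -> equality driven) must reach accuracy
  0.9; generating type-2 choice probabilities of the two strategies sit on
  opposite sides of 0.5 by construction, and observed accuracy is 1.0.

Problem sizes (20 recovery subjects, 6-subject selection cohorts, 5
replicates, 4-5 restarts) are the package's validation defaults: large
enough that the binomial/Monte-Carlo noise is far from the decision
thresholds, small enough to run routinely.

## Analysis utilities

`summarize_behavior()` aggregates per subject first (the subject is the
unit): reported means and SDs are over per-subject means, and reported
medians are means of per-subject medians; cells where a subject lacks a
response category are omitted with a warning.  `classify_subjects()`
implements the 50%-inclusive type-2 rule.  `quantile_gof()` compares
observed compliant-response RT quantiles (0.1-0.9) per stimulus type with
quantiles obtained by inverting the fitted defective CDF normalised within
the compliant response; for group-1 fits the predicted distribution is the
mixture over the subject's per-trial drifts.  As is typical for diffusion
fits, agreement is good through the 0.7 quantile and degrades at 0.9 where
RT variability is largest.  `min_detectable_d()` solves the exact
noncentral-t power equation for the smallest detectable paired effect size
(the normal approximation is visibly off at n = 11, which is why the exact
distribution is used); at `n = 11`, `alpha = 0.05`, power 0.80 it returns
0.9377, i.e. 0.94 to two decimals.

## Known limitations

* The dichotomous-coding collinearity described above makes `b1`/`b2`
  jointly unidentified in dichotomous models with an outgroup weight.
* Censored trials are excluded rather than contributing a censoring
  probability; with the default agents censoring is rare (well under 1%),
  but heavy-tailed subjects would bias `a` slightly downward.
* The Euler simulator has O(sqrt(dt)) boundary-crossing bias; the default
  step (1e-4 s) keeps it an order of magnitude below the binomial noise of
  the validation runs, and the step is configurable.
* Fitting is per-subject maximum likelihood; no hierarchical pooling,
  standard errors, or credible intervals are provided.
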