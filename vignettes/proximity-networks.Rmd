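---
title: "From mote pings to maternal fitness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From mote pings to maternal fitness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motenet)
```

## The analysis this package implements

Wearable proximity sensors ("motes") worn by every member of a
hunter-gatherer camp emit a ping every two minutes; any other mote within
about three metres records it. Over a five-to-nine-day deployment this
yields a near-complete record of close-range dyadic interaction, from
which one can ask whether a mother's *position* in her camp's contact
network predicts her reproductive success (number of currently living
offspring) and her recent sickness burden.

The chain is:

1. **Ingest.** Directed ping records are restricted to the daytime
   window `[05:00, 20:00)` (overnight pings mostly record co-sleeping),
   and reciprocal detections within a slot are collapsed to a single
   dyad-slot event. One-sided detections count by default: radio loss is
   asymmetric, and requiring reciprocity would discard real contacts
   (a `reciprocal` mode exists for sensitivity analysis).
2. **Network construction.** Each camp becomes an undirected weighted
   graph whose edge weights are interaction *rates*: dyad-slot events
   divided by the dyad's daytime co-presence hours, so people who
   arrived late or left early are not penalized. Only individuals aged
   12 years and over enter the network; younger children are care
   recipients rather than independent social actors in these camps.
3. **Centrality.** Five standard measures: degree (tie count),
   strength (summed tie weights), eigenvector centrality, betweenness
   and closeness. Because camps are small and dense, degree is counted
   only over ties whose weight strictly exceeds 1% of the camp
   network's total summed edge weight. All measures are z-standardized
   within camp, so a score says "central relative to one's own camp".
4. **Age-residualized fertility.** Living-offspring counts are
   Poisson-regressed (log link) on age and age squared; response-scale
   residuals (observed minus fitted) carry age-adjusted reproductive
   success. Zero means age-typical fertility.
5. **Models.** OLS regressions of the fertility residuals on one
   centrality measure at a time (two-SD standardized), with camp fixed
   effects, an optional centrality-by-age interaction pruned at
   p > 0.05, a joint degree + betweenness + closeness model guarded by
   variance inflation factors (ceiling 2.5), and sickness models
   (0--2 reported instances) with household controls and a
   dependent-count mediation check.

No field data ship with the package; a synthetic generator emulates the
study design with *planted* effects, so that every stage can be
validated by parameter recovery.

## Design choices where the method was genuinely open

**Edge weights to distances.** Geodesic measures need costs, while
contact rates are affinities; we use `d = 1/w`, the conventional choice
for frequency-weighted social networks. An unweighted reading of the
geodesic measures can be obtained by binarizing weights upstream.
Betweenness is unnormalized and closeness is the unnormalized inverse
distance sum: per-camp z-standardization makes affine normalizations
irrelevant.

**The 1% degree threshold.** "Greater than 1% of recorded weighted
interactions" is read as a *camp-level* rule: an edge survives when its
weight strictly exceeds 1% of the camp network's total summed edge
weight. The boundary is strict (an edge at exactly 1% is dropped). An
alternative ego-level reading (share of either endpoint's strength) is
available via `threshold_for_degree(mode = "ego")`. Only degree uses
the thresholded graph; all other measures use the full weighted graph.

**Eigenvector centrality on disconnected graphs** is computed on the
largest connected component with other nodes scoring zero, normalized
to a maximum of one; power iteration includes a small diagonal shift so
bipartite components cannot oscillate (the shift leaves the eigenvector
unchanged). Closeness sums distances within a node's component, and
isolates score zero. Camps are near-complete, so these conventions
rarely bind, but they are the documented behaviour.

**Response-scale residuals.** Fertility residuals are observed minus
fitted counts (not Pearson or deviance residuals): "two offspring above
average for her age" is the interpretable quantity, and the Poisson
score equations make these residuals sum exactly to zero and be exactly
orthogonal to age and age squared — the formal content of "the
residuals have no remaining age relationship". The curve is fitted by
iteratively reweighted least squares with a Newton polish that drives
the score below 1e-10, so those identities hold to numerical precision.

**Sickness model family.** The 0--2 sickness count is modelled by OLS
with two-SD standardized predictors, which yields symmetric CIs and
betas comparable across predictors; a Poisson mode
(`fit_sickness_model(family = "poisson")`) is provided for sensitivity.
The "number of dependents" control is the living-offspring count; the
survey's "children in the household" is treated as the same variable.

**Standardization conventions.** Continuous predictors are centered at
the in-sample mean and divided by twice the sample SD, making their
coefficients directly comparable to untransformed binary predictors;
age is centered at the in-sample mother mean. Interaction columns are
built from the standardized mains. No multiple-testing correction is
applied anywhere; with five correlated measures this is a deliberate,
documented choice rather than an oversight — the models are read as five
views of one network position, not five independent hypotheses.

## The synthetic generator

`sim_config()` fixes the study conditions. The defaults emulate the
field design: multi-camp populations of 18--24 people (at least five
mothers per camp; mothers aged 17--55, other members 1--75 with
under-12s excluded from networks downstream), seven days of two-minute
slots in a 15-hour daytime window, and one presence interval per person
with a 20% late-arrival/early-departure fraction.

Contacts are per-slot Bernoulli, independent across slots: dyad `i, j`
interacts in a slot with probability
`clamp(base_rate * household_boost^same_household * kin_boost^kin * g_i * g_j, 0, 1)`,
with a base rate of 0.002 per slot, a household boost of 10, a kin boost
of 3 on a 5% flagged fraction of cross-household dyads, and log-normal
individual gregariousness (log-SD 0.6). Households vary in size
(Poisson around four members, minimum two), which — together with
gregariousness — is what gives thresholded degree its within-camp
variance. Each directed record is lost with probability 0.1,
emulating asymmetric radio loss. These rates produce dense, household-
structured camp networks in which almost everyone has some interaction
— the regime the field data describe — but they are plausible defaults,
not calibrated to the two study populations, whose dyadic contact-count
distributions are not published.

Because replicate studies only consume per-dyad event *counts*, the
generator also has a count-level path (`simulate_dyad_counts()`):
a dyad co-present for `n` daytime slots yields
`Binomial(n, p * (1 - drop^2))` events, exactly the distribution of the
record-level path after one-sided collapse. The record-level path is
used for round-trip, determinism and equivalence tests; the count-level
path makes 500--1000 replicate pipelines affordable.

**Planting on realized centrality.** Outcome effects are planted on the
*realized* camp-standardized centrality scores, two-SD standardized
over the mother sample — the exact columns the downstream regressions
use — and additively on the expected count:

```
offspring ~ Poisson( max(0.01, mu0(age) + beta_f * x + beta_int * x * a) )
mu0(age)  = exp(-0.678 + 0.1098 * age - 0.00122 * age^2)
```

with `x` the standardized centrality and `a` standardized age. The
additive response-scale planting is deliberate: the pipeline's OLS
estimand then *equals* the planted coefficient, so parameter recovery
has an exact target rather than a link-function-dependent
approximation. The baseline curve `mu0` peaks near six living offspring
at age 45 and stays above two across 15--75, a realistic high-fertility
forager profile; it also keeps the additive rate positive except in a
negligible clamp region. Sickness counts follow the same logic,
truncated to the survey's 0--2 range:

```
sickness ~ min(2, Poisson( max(0, s0 + b_c * x_closeness + b_d * (dependents - mean)) ))
```

**The mediation scenario.** To reproduce the qualitative sickness
structure — a betweenness association carried entirely by number of
dependents, and a closeness association independent of family size —
the two planted pathways must be statistically independent. Betweenness
and closeness are strongly positively correlated in these networks
(as they are in the field data), so a dependents pathway planted on raw
betweenness would leak into the closeness model: writing `u` for the
mediated slope and `b_c` for the direct closeness effect, the two
attenuation requirements imply `u * r < b_c / 4` and `b_c * r < u / 4`,
which is impossible unless the correlation `r < 1/4`. The scenario
therefore plants the dependents pathway on the component of betweenness
orthogonal to closeness, and the effect sizes
(`beta_dependents_betweenness = 2.5` offspring per two SD,
`beta_dependents_sickness = 0.3` per offspring,
`beta_closeness_sickness = 0.09`) follow from that leakage algebra with
the direct closeness effect set near `u(1 - r^2) / (6r)` so the
betweenness attenuation target is met with margin at the correlations
these networks produce. Replicate summaries use the ratio of
Monte-Carlo mean coefficients (not the mean of per-replicate ratios),
which stays stable when single-replicate denominators are near zero.

## Validation studies and their problem sizes

The test suite validates the pipeline at these scales, chosen to give
tight Monte-Carlo error while remaining quick on a single core:

* *Centrality oracles*: 200 random connected weighted graphs (4--8
  nodes, one quarter with integer weights to force geodesic ties),
  checked against a Floyd-Warshall + combinatorial path-counting oracle
  and, on a subset, exhaustive all-simple-paths enumeration; eigenvector
  scores are checked against the eigen-equation residual and the star
  closed form.
* *Recovery*: a planted betweenness-to-fertility effect of 1.0 per two
  SD, 25 camps x 24 people (200 mothers), 500 replicates.
* *Null calibration*: all effects zero, 12 camps of 18--24 people,
  1000 replicates, all five measures (rejection rate at alpha = 0.05
  and the interaction-pruning rate).
* *Mediation*: 50 camps (400 mothers), 200 replicates.

What passing these studies shows — and what it does not: the generator
realizes the analysis' own modelling assumptions (independent slots,
per-camp homogeneity apart from households, kinship and gregariousness,
outcomes linear in realized standardized centrality). Real proximity
data have temporally clustered contacts, day-to-day behavioural
variation, migration between camps, and centrality that is itself an
outcome of unobserved mother quality; recovery under the generator
demonstrates the *pipeline* is consistent and calibrated, not that the
field estimates are unconfounded.

## Numerical conventions and known limitations

* Geodesic tie detection uses a relative tolerance of 1e-12; equal-length
  geodesics receive fractional credit.
* Power iteration: tolerance 1e-10 in max-norm on max-normalized
  iterates, 1000-iteration cap, error (with residual) on
  non-convergence.
* IRLS: relative deviance tolerance 1e-8, then Newton steps until the
  maximum absolute score component is below 1e-10; non-convergence is
  an error carrying the deviance trace.
* Zero-variance or singleton camps make z-scores undefined and raise an
  error naming the camp; degenerate (constant) sickness outcomes are
  refused likewise. Perfect collinearity reports an infinite VIF with a
  warning, and rank-deficient model designs are errors naming the
  aliased terms.
* The analytic t-based CIs of the second-stage OLS treat the fertility
  residuals as data: they cannot see first-stage uncertainty in the
  fitted age curve, nor the Poisson mean-variance coupling, so CI
  coverage for planted effects sits slightly below the nominal 95%.
  This is a property of the two-step residual-on-covariate method
  itself, not of this implementation.
* Mote-swap corrections are applied by timestamped id remapping before
  any aggregation; signal-strength-based distance estimation, temporal
  or dynamic networks, and causal mediation estimation are out of
  scope.

## A worked run

A single recovery-scale study (25 camps, 200 mothers, planted
betweenness effect of 1.0 per two SD):

```{r example}
study <- simulate_study(recovery_scenario(seed = 1))
study

study$age_fit

fit <- prune_interaction(
  fit_fertility_model(study$mothers, "betweenness", interaction = TRUE))
fit
```

The fitted age curve is close to the generator's
(`-0.678 + 0.1098 age - 0.00122 age^2`), the planted effect's CI covers
1.0, and the (truly absent) age interaction was pruned. A mediation
scenario shows the dependents pathway being absorbed:

```{r mediation}
ms <- simulate_study(mediation_scenario(seed = 3))
mediation_check(
  fit_sickness_model(ms$mothers, "betweenness"),
  fit_sickness_model(ms$mothers, "betweenness", include_dependents = TRUE))
```

Single-replicate attenuation ratios are noisy when the without-term
beta is small; the replicate studies (`run_mediation_study()`,
`summarize_mediation()`) summarize with ratios of Monte-Carlo means for
that reason.
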