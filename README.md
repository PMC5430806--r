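# motenet

Social-network analysis of wearable proximity-sensor ("mote") data from
small residential camps, built around one question: does a mother's
position in her camp's close-range contact network predict her
reproductive success and her sickness burden?

Motes worn by every camp member emit a ping every two minutes; any
other mote within ~3 m records it. Restricted to a 05:00–20:00 daytime
window over a 5–9 day deployment, these logs become per-camp weighted
undirected networks whose tie weights are interaction *rates* — dyadic
slot-events per hour of joint presence in camp — over individuals aged
12 and up. From each network the package computes five centrality
measures and standardizes them within camp:

* **degree** — number of ties, counted after discarding ties whose
  weight is not strictly greater than 1% of the camp's total edge
  weight (camps are dense; raw degree saturates);
* **strength** — sum of tie weights;
* **eigenvector centrality** — leading eigenvector of the weighted
  adjacency matrix, max-normalized;
* **betweenness** — fractional count of weighted geodesics
  (edge distance 1/w) through a node, unnormalized;
* **closeness** — inverse sum of geodesic distances to all reachable
  nodes.

Reproductive success is the number of currently living offspring,
age-adjusted by Poisson regression on age and age², with response-scale
residuals r = y − μ̂(age) that are exactly orthogonal to the age basis
(the Poisson score equations). The modelling layer fits

  r ~ β·x + camp,  optionally + standardized age + x·age,

by OLS, where x is the camp-z centrality standardized over **two**
standard deviations so β is comparable to a binary predictor's
coefficient; age interactions are pruned at p > 0.05, joint
degree+betweenness+closeness models are guarded by variance inflation
factors (ceiling 2.5), and sickness models (0–2 reported instances,
with age, settledness, mobility and belongings controls) support a
dependent-count mediation check by coefficient attenuation.

No field data are distributed. A synthetic generator
(`sim_config()`, `simulate_study()`) emulates the study design —
multi-camp populations, household/kin/gregariousness-structured
per-slot Bernoulli contacts, asymmetric radio dropout, late arrivals —
and plants known effects on the *realized* standardized centrality, so
the entire pipeline is validated by parameter recovery, null
calibration and mediation-structure studies.

## A worked example

```r
library(motenet)

study <- simulate_study(recovery_scenario(seed = 1))  # 25 camps, 200 mothers,
study                                                 # planted beta = 1.0
#> Synthetic mote study: 25 camp(s), 600 individuals, 200 mothers

study$age_fit
#> Poisson age-fertility curve (log link):
#>   log E[offspring] = -0.8624 + 0.1144*age + -0.001232*age^2
#>   n = 200 mothers, deviance 187.669, 4 IRLS iteration(s)

fit <- prune_interaction(
  fit_fertility_model(study$mothers, "betweenness", interaction = TRUE))
fit
#> Standardized fertility model (n = 200)
#>   betweenness            beta    1.320  [0.764, 1.876]  p <1e-04
#>   adjusted R^2 0.151
#>   age interaction pruned (p > 0.05)
```

The fitted age curve tracks the generator's quadratic
(−0.678 + 0.1098·age − 0.00122·age²); the planted betweenness effect of
1.0 extra offspring per two SD of camp-standardized betweenness is
recovered with a CI covering the truth (point estimates scatter around
1.0 across replicates — `run_fertility_study()` measures that
distribution); and the age interaction, truly absent here, is pruned.

A mediation scenario (dependents driven by betweenness, sickness driven
by dependents and independently by closeness) reproduces the
attenuation structure:

```r
ms <- simulate_study(mediation_scenario(seed = 3))
mediation_check(
  fit_sickness_model(ms$mothers, "betweenness"),
  fit_sickness_model(ms$mothers, "betweenness", include_dependents = TRUE))
#> Mediation check for betweenness:
#>   without dependents: beta = 0.346 (p = 1.32e-05) *
#>   with dependents:    beta = -0.021 (p = 0.762)
#>   proportional attenuation: 106.0%
```

See `vignette("proximity-networks")` for the model, the generator's
assumptions, and every numerical convention.

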