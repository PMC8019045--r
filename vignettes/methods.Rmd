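---
title: "Models and methods: temporal association networks in multi-level societies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clannet)
```

This vignette explains the statistical machinery the package implements,
the choices made where the methods literature leaves options open, what the
synthetic-society generator does and does not emulate, and the known
limitations — including one validation property that the field's standard
post-dispersal test cannot, in principle, attain.

## The data and the association index

The observational unit is a *scan*: an instantaneous record, taken every
two hours during a focal follow (07:00–16:00, five scans per day), of which
core units lie within the association radius of the focal unit. A unit is
*present* in a scan if it is the focal or a recorded associate; there is no
chaining of association across scans.

For units $A$ and $B$ the simple association index is

$$\mathrm{AI}(A,B) \;=\; \frac{N_{AB}}{N_{A\text{-only}} + N_{B\text{-only}} + N_{AB}},$$

the fraction of scans containing both among scans containing at least one.
This denominator (the union of sightings) is the only one compatible with
the index's anchor semantics — 1 when the dyad is always together, 0 when
never — and is the default. The raw-sum variant $N_{AB}/(N_A+N_B)$, which
tops out at $1/2$ for an always-together dyad, is provided behind
`denominator = "sum"` for sensitivity analysis, because field reports
sometimes print that formula while describing the union semantics. Dyads
whose members were never sighted at all have no defined index; they are
flagged, enter clustering and network construction as similarity 0, and are
excluded from CV-type statistics — absence of data is not evidence of
avoidance.

## Clans: clustering on the AI scale

Units are clustered agglomeratively on AI similarity. Internally this is
ordinary hierarchical clustering on the distance $d = 1 - \mathrm{AI}$ with
merge heights mapped back to the AI scale, so that the clan cutoff (default
0.05) retains its meaning as an association index. Four linkages are
offered (average, Ward, complete, single); the cophenetic correlation
coefficient — the Pearson correlation between the input AIs and the
AI-scale height of each dyad's lowest common merge — selects among them,
with exact ties resolved in a fixed order (average first). Ward's method
uses the standard recurrence on this non-Euclidean distance without
checking Euclidean embeddability, mirroring common practice in the field's
toolchains; its heights are therefore not interpretable on the AI scale and
it is never the cutoff linkage in practice.

Clan extraction joins all merges at height $\ge$ the cutoff. It is
implemented as a union over the merge list rather than a height cut, which
makes it robust to the tiny height inversions floating-point ties can
produce and well-defined even for non-monotone linkage heights. Merge-order
ties are broken by presenting units in lexicographic order, so the tree is
deterministic. Cross-period comparison uses the adjusted Rand index;
"moved" units are identified by greedily peeling the unit with the most
co-membership disagreements until the partitions agree — the minimal
explanation of a between-period change.

## Preferred association: permutation nulls

The test statistic is the coefficient of variation (population SD over
mean) of the defined dyadic AIs; heterogeneous AIs relative to chance
indicate preferred and avoided companionships, so the test is right-tailed,
with the add-one estimator $p = (k+1)/(n+1)$.

Two null schemes are implemented. The *data-stream* scheme randomizes the
observation stream itself: a sequential chain of checkerboard swaps
exchanges two associates between two scans whenever neither unit already
occurs in the other scan, preserving every scan's group size and every
unit's total sighting count; focal units never leave their own follows.
Scan pairs and unit pairs are proposed uniformly over associate placements,
which keeps the transition kernel symmetric, so the chain's stationary
distribution is uniform over the reachable margin-preserving datasets. The
*node-label* scheme permutes each unit's presence pattern across scans
independently (focal placements fixed), preserving sighting counts but not
group sizes; it is the cheap node-level null. Both reject decisively on a
clan-structured society.

Two defaults here deviate from the obvious first choices, for measured
reasons:

* **Swap constraint.** Restricting swaps to scans of the same day is a
  common guard against diurnal confounds, but under a
  one-focal-unit-per-day design all of a day's scans share their focal, so
  day-constrained swaps can only rearrange associates among scans with the
  same focal — which nearly fixes every focal–associate joint count and
  leaves the test with almost no power (on a strongly clan-structured
  simulation, $p \approx 0.17$ day-constrained versus $p \approx 0.005$
  unconstrained). The default is therefore unconstrained; `constraint =
  "day"` remains available for designs with several focals per day.
* **Chain thinning.** With 100 accepted swaps between samples, successive
  permuted datasets are visibly autocorrelated and the realized null
  rejection rate is anticonservative (0.08–0.10 at $\alpha = 0.05$). The
  defaults are 500 accepted swaps between samples after 2,000 of burn-in,
  at which the measured rate over 200 null societies is 0.060, within
  Monte-Carlo error of nominal.

`null_density_band()` applies the same chain per sliding window to give the
2.5th–97.5th percentile band of edge density expected from chance
encounters given the margins.

## Temporal networks

Sliding windows are half-open, $[s, s + w)$ with defaults $w = 31$ days and
shift 31 days; incomplete trailing windows are dropped (the 2017-08-28 to
2019-05-13 span yields exactly 20 windows). Edge presence means AI $> 0$ —
degree, density and the clustering coefficient are defined by presence of
association, strength by the raw AI weights; a weight threshold is an
option. The clustering coefficient is binary global transitivity
($3 \times$ triangles over connected triples) and is undefined, not zero,
when the graph has no connected triple.

Cosine similarity between two windows is the normalized dot product of
their edge-weight vectors over the union of dyads (zero-padded), with the
convention that an edgeless network has similarity 0 to everything.
Stability series report each window's similarity to the previous window
(short-term) and to the first (long-term). Uncertainty comes from
resampling scans with replacement within the window and summarizing the
replicate statistics by the highest-density interval — the narrowest
interval containing the requested mass — which is appropriate for the
skewed, boundary-hugging distributions density and similarity produce.

Window-size selection formalizes "maximize variability in edge density":
for each candidate size the *signal* is the variance of density across
windows and the *noise* is the mean within-window bootstrap variance; the
candidate maximizing signal/noise wins, with ties toward the smaller
window. A pure-variance criterion is available; the ratio is the default
because raw variance always favors tiny windows whose density estimates are
mostly sampling noise.

## Ecological covariates and AR1 regressions

The food availability index for a plant-part group in a month is
$\sum_{\text{species}} \bar{s} \times \mathrm{BA}$: the mean phenology
score (0–4 canopy-cover scale) over the species' sampled trees times the
species' total basal area, summed over food species. "Fruit" pools ripe and
unripe fruit with equal weight (a ripeness weighting is an option); a
species unsampled in a month is missing, not zero, at the score level, but
contributes zero to the additive index with a warning. Covariates
(fruit FAI, young-leaf FAI, rainfall) are joined by month and standardized
with the population SD over the analyzed months; pairwise correlations
above $|r| = 0.7$ — the usual multicollinearity threshold — trigger a
warning.

Network-level metrics are regressed on the standardized covariates with
AR1-autocorrelated errors,
$y_t = \beta_0 + x_t^\top\beta + \varepsilon_t$,
$\varepsilon_t = \phi\,\varepsilon_{t-1} + \eta_t$. Estimation is exact
maximum likelihood: given $\phi$, quasi-differencing makes the innovations
independent, so $\beta$ and $\sigma$ have closed forms and the concentrated
likelihood is a one-dimensional search over $\phi$. Intervals are
$t$-based on the residual degrees of freedom with the GLS covariance at
$\hat\phi$; over 500 simulated series of length 100 with $\phi = 0.6$ the
realized 95% CI coverage of a known slope is ~0.95. Node-level metrics add
a unit random intercept, with the AR1 applying within each unit's residual
series independently (the natural reading of repeatedly measured nodes);
the likelihood is concentrated into a two-dimensional search over
$(\phi, \tau^2/\sigma^2)$ with per-unit block covariances. Fits
cross-check against `nlme::gls`/`nlme::lme` in the test suite.

Estimation is maximum likelihood throughout rather than MCMC. The effect of
weakly informative normal(0, 1) slope priors on standardized predictors is
available as an equivalent ridge penalty (`ridge = TRUE`), iterating the
$\sigma^2$ plug-in; posterior diagnostics are out of scope. $R^2$ is the
variance of fitted values over fitted-plus-residual variance, with a
parametric-bootstrap interval (simulate from the fitted model, refit,
recompute). Windows with undefined metrics are dropped listwise with a
message; the reported "error" column is the ML standard error.

## Dispersal analyses

A transfer is dated by the month containing the most days of its
last-seen/first-seen range, ties to the earlier month (a documented
determinism choice). Monthly male transfer counts (each male counts, even
in parallel transfers; females excluded) are correlated with each
ecological covariate by Spearman's rho on mid-ranks with a two-sided
Monte-Carlo p-value — robust to the heavy ties that zero-transfer months
produce — under a Bonferroni-corrected level ($0.05/3$, displayed 0.017).

For each dispersal event (one event per origin–destination–month, however
many males moved), the dyad's AI in each of the three following calendar
months is compared against *baseline* AIs: the AIs, in that same evaluation
month, between each involved unit and every third unit it associated with
during the transfer month. The test is a one-sided exact Wilcoxon
signed-rank test of the differences (dyad minus baseline), zeros dropped,
ties mid-ranked, exact enumeration up to $n = 15$ and a tie-corrected
normal approximation beyond. The directional alternative follows the
substantive question: transfers should *elevate* the dyad.

**A calibration caveat that matters.** The one-sample Wilcoxon here
compares one shared random quantity (the dyad's monthly AI) against $n$
baselines, so the $n$ "differences" all contain the same single draw. Under
a no-bond null the realized rejection rate is therefore far above the
nominal level (about 0.35 in simulation) — the test answers "is this dyad's
value in the upper tail of the baselines" rather than providing a
calibrated $\alpha$-level test. This is a property of the method as used in
the field, reproduced faithfully here. Consequences: per-event post-
dispersal significance flags should be read as descriptive placements, and
a joint validation pattern of the form "significant at offsets 1–2 but not
at offset 3 in $\ge 80\%$ of simulated studies" is unattainable — the
offset-3 false-positive floor (~0.2–0.35 across all regimes we searched),
combined with the 45-day bond half-life leaving ~30% of the initial effect
at offset 3, caps the joint rate near 0.3. The corresponding acceptance
check is retained at its stated threshold and fails by design; the bond
preset is parameterized for realism (dyad AI near 0.5 in the first
post-dispersal month against baselines near 0.08), not to chase that
threshold.

## The synthetic-society generator

The generator emulates the sampling design — one focal unit per day in
round-robin, five scans per day at 2-hour spacing, an optional observation
schedule of `obs_days_per_month` days spread evenly through each month
(field studies rarely sample daily; the design this emulates observed 243
of 624 days, about 12 per month) — and a pairwise-independent Bernoulli
association model: non-focal unit $j$ joins focal $i$'s scan with
probability

$$p_{ij} = \operatorname{logit}^{-1}\!\big(\beta_0 + \beta_{\text{clan}}\,[\text{same clan}] + \beta_{\text{fruit}}\, z_{\text{fruit}}(t) + \beta_{\text{bond}} \cdot 2^{-\Delta t / h}\big),$$

where the bond term applies to dyads linked by a dispersal $\Delta t$ days
earlier with half-life $h$ (default 45 days). Monthly ecology is a sinusoid
with two peaks per year (a bimodal rainy season) plus noise, clipped at
zero; dispersal counts are Poisson with rate
$\lambda_0 \exp(c \cdot z_{\text{fruit}})$, origin and destination uniform
over distinct pairs, date ranges of at most 14 days.

Default effect sizes are design choices, not field estimates, fixed once by
a design-time power analysis of the generative model: $\beta_0 = -4$ puts
between-clan association safely below the 0.05 clan cutoff,
$\beta_{\text{clan}} = 2.5$ puts within-clan AIs near 0.1 (so the cutoff
separates clans with margin), and the bond preset's $\beta_0 = -2.5$,
$\beta_{\text{bond}} = 4$ reproduce the observed magnitudes after real
transfers. `generate_dataset()` writes the full set of study inputs plus a
`ground_truth.json` sidecar (clan partition, every generative parameter,
the dispersal list, the seed); the phenology/basal-area pair is constructed
so the food availability indices recompute the simulated fruit and leaf
series up to the integer rounding of the 0–4 score scale.

What the generator does **not** emulate: explicit 50 m spatial geometry
(association is dyadic and pairwise-independent, so higher-order group
structure beyond what clans induce is absent), within-unit individual
behavior, female dispersal out of the band, observation error in unit
identification, and unit fission/formation (a split can be emulated by
editing rosters between two generated periods). Validation against it
therefore demonstrates the pipeline's correctness and calibration under the
stated generative model, not the realism of that model for any particular
field system.

## Problem sizes used in validation

The test suite validates at sizes chosen to exercise the methods while
keeping a full run comfortably interactive: enumeration oracles are
exhaustive over all graphs with up to 6 nodes and random scan sets with up
to 6 units and 50 scans; permutation-test calibration uses 200 null
societies of 8 units over 60 days at 1,000 permutations; clan recovery uses
100 seeds of the 180-day strong-clan preset; AR1 coverage uses 500 series
of length 100; the dispersal analyses use 100–500 replicates of the bond
and fruit-driven presets. Exact Wilcoxon enumeration is tested for all
$n \le 10$ against an independent sign-vector enumeration.

## Known limitations

* The post-dispersal Wilcoxon is descriptive, not calibrated (above); a
  placement test treating the dyad as exchangeable with its controls would
  be calibrated but would depart from the field-standard method and is not
  the default surface.
* Ward heights are not on the AI scale; linkage selection by CCC almost
  always prefers average linkage, matching field practice.
* The AR1 fitters assume equally spaced windows and, at node level,
  independent per-unit AR1 residual series; missing windows are dropped
  listwise rather than modeled.
* Data-stream permutation mixes by local swaps; for pathological inputs
  with no legal swaps (all scans identical) the chain reports zero mixing
  and the test degenerates to $p = 1$ with a warning rather than failing.
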