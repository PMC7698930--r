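---
title: "Wild-bee diversity across semi-natural habitats: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wild-bee diversity across semi-natural habitats: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snhbees)
options(snhbees.verbose = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## The setting

Agricultural landscapes hold several kinds of uncropped, semi-natural
habitat (SNH). Herbaceous SNH — permanent grasslands — are well known to
support wild bees; wooded SNH — hedgerows and forest edges — are less
studied but carry a distinct flora (woody strata, flowering shrubs) that
may feed bee species grasslands cannot. The analyses here quantify three
things on long-format survey data: (1) how bee and plant community
composition differs between and within the three SNH types, (2) whether
bees harvest some pollen taxa out of proportion to their availability, and
(3) how much of the site-wide bee–pollen interaction network depends on
each habitat type.

## Beta-diversity partitioning

All composition analyses use presence/absence. For two communities with
`a` shared taxa and `b ≤ c` taxa unique to the poorer/richer community,

$$\beta_{sor} = \frac{b+c}{2a+b+c},\qquad
  \beta_{sim} = \frac{b}{a+b},\qquad
  \beta_{sne} = \beta_{sor}-\beta_{sim}
             = \frac{c-b}{2a+b+c}\cdot\frac{a}{a+b}.$$

$\beta_{sim}$ (Simpson dissimilarity) measures species replacement and is
insensitive to richness differences; $\beta_{sne}$ captures dissimilarity
that arises because one community is (close to) a subset of the other. The
additive identity holds exactly and is asserted to `1e-12` on fuzzed pairs.

Open design points, resolved as follows:

* **"Poorer" community** = the one with fewer unique taxa (`b = min`),
  matching the min/max form of Simpson dissimilarity. A tie gives
  `b = c`, hence $\beta_{sne}=0$ automatically.
* **One empty community**: no species is replaced, so $\beta_{sim}=0$ and
  all dissimilarity is richness-driven ($\beta_{sor}=\beta_{sne}=1$). Two
  empty communities have no defined dissimilarity and raise an error.
* **Inter-habitat values** are computed on pooled (union) communities, one
  value per habitat pair — this matches reporting a single dissimilarity
  per pair rather than a mean over per-landscape pairings.
* **Intra-habitat variability** is the set of pairwise $\beta_{sor}$
  values over sampling points of one habitat, summarized by the median.
  Point pairs where both communities are empty are excluded and counted;
  an empty point against a non-empty one legitimately contributes full
  dissimilarity.

### Permutation null model

A pooled dissimilarity can look large purely through uneven sampling. The
null model permutes sampling-point-to-habitat labels (points, never taxa,
are shuffled), keeping group sizes fixed, and recomputes the pooled
$\beta_{sor}$; the one-sided p-value uses the add-one convention
$p = (1+\#\{\beta^{null} \ge \beta^{obs}\})/(1+n_{perm})$, which can never
be zero. Defaults: `n_perm = 999`, one-sided upper tail; both are exposed.

Two caveats the test suite makes explicit. Exchangeability requires equal
sampling effort per point: unequal per-habitat bee abundance is itself a
habitat effect and the test will (correctly) reject under it, so the
type-I calibration world uses equal abundance means. And $\beta_{sor}$ is
discrete; with small species pools the tied null distribution makes the
add-one p conservative, so the calibration study uses a species-rich pool
where the statistic is near-continuous.

## Rarefaction and extrapolation

Individual-based expected richness at subsample size `m` uses the exact
hypergeometric form
$E[S_m] = S_{obs} - \sum_i \binom{n-x_i}{m}\big/\binom{n}{m}$ (computed on
the log scale for stability); it is checked against exhaustive enumeration
of every subsample for every abundance composition with `n ≤ 8`. Beyond
`n`, the curve extrapolates with the Chao1 estimate of undetected richness
$\hat f_0 = \frac{n-1}{n}\frac{f_1^2}{2f_2}$ (with the standard
$f_1(f_1-1)/2$ fallback when $f_2 = 0$), approaching $S_{obs}+\hat f_0$
asymptotically. Extrapolation is bounded at `2n` by default, common
practice beyond which the estimator is unreliable.

Confidence bands are bootstrap percentile intervals over multinomial
resamples of the `n` individuals (`n_boot = 200` by default). The default
level is **84%**, following the rule that non-overlap of two such bands
approximates a pairwise test at an error rate of 0.05. The bands are
clamped to contain the point estimate; multinomial resampling loses rare
species, so the raw bootstrap curve is biased slightly low — the bands are
honest for curve comparison, not for absolute richness inference.

## Pollen selection

For each plant taxon `i` found as pollen:

* **Availability** `PA_i` = occurrence records of `i` (a record is a
  (taxon, sampling point) presence, layers collapsed) divided by the total
  records among the included taxa, so included PAs sum to 1. The default
  inclusion set is the taxa actually found on bees — the taxa that supply
  the pollen; a switch widens it to all entomophilous taxa, because
  neither convention is uniquely implied by how small printed
  availabilities were derived, and forcing agreement would be dishonest.
* **Harvest rate** `HR_i` = number of bees carrying `i` divided by the
  total number of pollen records (default; HRs sum to 1) or by the number
  of bees examined (switch). The per-bee convention is what reproduces a
  minimum harvest rate of `1/349 ≈ 0.003` at the reference study's sample
  sizes, and the acceptance suite exercises both.
* **Jacobs' index** $D_i = \frac{HR_i-PA_i}{HR_i+PA_i-2\,HR_i PA_i} \in
  [-1,1]$: 0 when use matches availability, +1 for a taxon always
  harvested despite negligible availability, −1 for complete avoidance.
  The formula is antisymmetric in (HR, PA), strictly increasing in HR and
  decreasing in PA; undefined only at (0,0) and (1,1), which are rejected.

Confidence intervals resample **bees, carrying their whole pollen loads**
(loads within one bee are not independent), recompute HR per replicate,
and hold PA fixed — the botanical survey is a census of availability, not
part of the resampled consumption data. Defaults: 5000 replicates,
percentile 2.5/97.5 bounds. A taxon is `over_selected` if its lower bound
exceeds 0, `under_selected` if the upper bound is below 0, else `neutral`
(CI-excludes-zero is the significance criterion). Pollen taxa that match
no flora taxon after genus-level harmonization cannot receive an
availability and are excluded from D, reported separately. Taxa absent
from more than half of the replicates are flagged `unstable`.

## Interaction network and habitat removal

The site-level bipartite network takes one edge per unique
(bee species, pollen taxon) pair, built from the abundant bee species only
(more than 4 individuals in the whole dataset — rare species' loads
confound specific diets with habitat effects). Frequency (supporting
record count) is retained for reporting and plotting only; uniqueness is
species-level.

Robustness to losing a habitat is measured under equal effort: habitats
differ in the number of sampling points, so each replicate draws 24 points
per habitat *without replacement* (a habitat at exactly 24 enters as-is; a
switch enables classical with-replacement resampling), builds the full
network on the drawn points, then the reduced network excluding the
removed habitat's points. Remnant percentages are relative to the
**per-replicate** full network — the equal-effort baseline, which is the
point of the resampling; a single full-data baseline is computable by
disabling subsampling. A species survives only if it retains at least one
interaction. Per replicate, the remnant interaction percentage plus the
percentage of edges unique to the removed habitat is exactly 100, an
identity the tests verify through two independent code paths.

## The synthetic generator: a stated world

`simulation_config()` fixes a generative world once; its defaults are not
tuned to make tests pass.

* **Species pools.** Each habitat's plant and bee pool is a shared block
  plus exclusive taxa: `round(overlap × pool_size)` taxa common to all
  three habitats. Pairwise pool overlap is therefore exact and the
  ground-truth partition is analytic (`a` = shared block, `b = c`, so
  $\beta_{sne}=0$ and $\beta_{sor}=\beta_{sim}=1-\text{overlap}$), which
  makes beta-diversity tests deterministic rather than statistical.
* **Detection.** Plants occur at a site independently with
  `detection_prob`; Braun-Blanquet codes are decorative (presence-only
  downstream). Entomophily is a per-taxon coin flip (default 0.75,
  roughly the entomophilous share of farmland floras).
* **Bees.** Captures per site are negative-binomial (overdispersed, as
  capture counts are), with per-habitat means; species are drawn with
  rank-skewed weights (`rank^-1`), giving the usual few-dominant /
  many-rare structure.
* **Pollen.** Examined bees (species above the abundance threshold) carry
  `k` taxa with default mass {0: 0.15, 1: 0.55, 2: 0.25, 3: 0.05} — about
  15% carry nothing and ~94% of carriers hold one or two taxa, matching
  reported load marginals, which constrain the margins but not the
  mechanism. Taxa are drawn without replacement with probability
  proportional to preference × local availability at the bee's sampling
  point; the preference structure is the ground truth for selection
  (uniform by default — no selection).
* **Seeding.** One stream per generate call, consumed in a fixed stage
  order (sites, plants, bees, pollen); same seed, same bytes.

`emulate_study_design()` is the study-scale preset: 30 landscapes, pruned
deterministically to exactly 30 hedgerow / 29 grassland / 24 forest-edge
points; grassland capture means about twice the wooded ones (10 vs 4 and
4.8 per point, ≈ 525 bees in expectation); plant pools of 130 per habitat
with 35% overlap (≈ 300 taxa site-wide). The exact 30/29/24 design is
reached by removing one grassland and six forest edges chosen from the
seed, not by tuning missingness probabilities, so the counts hold at every
seed.

What the generator does **not** emulate: phenology and within-season
turnover, spatial autocorrelation between neighbouring landscapes,
layer-structured vegetation differences between habitats, bee movement
between habitats of one landscape (a bee's pollen reflects only its
capture site's flora), identification uncertainty, and the grassland
botanical surveys' split across years. A green test therefore establishes
that the estimators recover a known, simplified world — not that any
field-data conclusion is correct.

## Numerical and testing choices

* Rarefaction binomials on the log scale; partition identities asserted to
  `1e-12`; sums of PA and HR to `1e-12`.
* Bootstrap and permutation p-values use add-one conventions; all
  stochastic stages take explicit seeds and log them to standard error.
* The recovery study for selection runs the bootstrap at 1000 replicates
  instead of the 5000 default: classification is CI-sign-based and stable
  well below 5000, and the saving keeps the suite inside its time budget.
  Those recovery worlds set `entomophilous_prob = 1` so the random
  entomophily flag cannot erase the boosted taxon's ground truth.
* The null-model calibration uses 199 permutations per replicate (the
  count is config-exposed; 999 is the analysis default).
* Configuration files are JSON; genus merges are validated to be conflict-
  and chain-free, and harmonization is idempotent.

## Known limitations

* No multiple-site (three-community) partition, no abundance-based
  (Bray–Curtis) decomposition, no Hill numbers beyond richness.
* No weighted network robustness or secondary-extinction cascades; node
  loss is purely topological.
* The survey schema carries no year field, so multi-year grassland surveys
  cannot be distinguished (documented schema limitation).
* Percentile bootstrap CIs can misbehave for taxa carried by very few
  bees; such taxa are flagged rather than silently trusted.
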