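---
title: "Methods: multi-scale community structure along a distance-to-water gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale community structure along a distance-to-water gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piosphere)
```

## The problem

In arid savannas, distance to the nearest perennial water is one of the
dominant local environmental gradients.  Ground-dwelling arthropod
communities — sampled here in the form of pitfall-trap surveys of ant
morphospecies — respond to it through vegetation, soil and microclimate,
and the response can take qualitatively different forms: a change in how
*many* animals are caught, in how many *kinds*, in how *even* the catch
is, in how *variable* composition is among traps, and in how species
*organise* themselves across the gradient (nested subsets versus
distinct local modules).  `piosphere` implements this entire analysis
chain for a hierarchical survey design — transects running away from the
water, discrete distance categories along each transect, sample points
within categories, traps within points, repeated in a wet and a dry
season — together with a synthetic-survey generator that makes every
stage testable without field data.

The default design constants are those of a 1-km transect layout: 6
transects, distance categories at 0, 50, 100, 150, 250, 500 and 1,000 m,
5 sample points per category, 3 traps per point, 2 seasons.

## Alpha metrics

Per trap and season we report abundance (individuals), taxonomic
richness (morphospecies with at least one capture), and the effective
number of morphospecies — the Hill number of order 1,
$\exp(-\sum_i p_i \ln p_i)$ on the within-trap relative abundances.
The exponential makes the quantity independent of the logarithm base
and puts it on the intuitive "equivalent number of equally common
species" scale, bounded between 1 and the richness.  Empty traps
propagate as missing diversity rather than zero: the entropy of an
empty community is undefined, and silently coding it as 0 would bias
category means downward exactly where the gradient effect is strongest.

## Beta diversity as multivariate dispersion

Beta diversity is quantified as the mean distance from traps to the
centroid of their grouping in a principal-coordinate (PCoA) embedding of
modified Gower dissimilarities:

* **Modified Gower.** Counts are transformed to $\log_{10}(x) + 1$ for
  $x > 0$ (0 for absences) and pairs of traps are compared by the mean
  absolute difference over species that are not absent from both.  With
  base 10, a tenfold change in one species' abundance contributes
  exactly as much as a presence–absence change — the property that
  motivates the transform.  The base is an argument (`log_base`); 10 is
  the default because the order-of-magnitude equivalence is the stated
  rationale of the method.  A pair of entirely empty traps has no
  species to compare and is an error by design; the multi-scale driver
  excludes empty traps up front and reports how many it removed.

* **PCoA with imaginary axes.** The modified Gower dissimilarity is
  semi-metric, so the Gower-centred matrix of $-\tfrac12 d^2$ values can
  have negative eigenvalues.  We keep axes of both signs and use the
  signed decomposition $d^2_{ij} = \|x_i - x_j\|^2_+ - \|x_i - x_j\|^2_-$,
  which reproduces the input dissimilarities to numerical tolerance for
  *any* input.  Distances to group centroids combine the two blocks the
  same way, $\sqrt{\max(d^2_+ - d^2_-, 0)}$; the rare clamped cases are
  counted and reported in the run manifest.  Dropping the negative axes
  instead would bias dispersion systematically downward.

* **Four scales, one embedding.** All traps of a season are embedded
  once, and centroids are taken per transect, per distance category
  (pooled across transects), per distance category within transect, and
  per sample point.  Computing centroids inside a single season-wide
  embedding (rather than re-ordinating each subset) keeps the four
  scales commensurable.

A useful exact property used in the tests: for exchangeable traps the
expected squared distance to a size-$n$ group centroid is proportional
to $1 - 1/n$, so the four scales are only comparable after that
correction — and under exchangeability they agree after it.

## Interaction-matrix structure

For every transect and season, counts are pooled into a morphospecies ×
distance-category matrix.  Two complementary statistics describe its
spatial organisation.

**Weighted nestedness (WIN / WINE).**  The matrix is packed — rows and
columns sorted by decreasing totals, ties broken by original index — and
every occupied cell is scored by its closeness to the generalist corner,
$1 - \sqrt{(i-1)^2 + (j-1)^2} / \sqrt{(n_r-1)^2 + (n_c-1)^2}$.  WIN is
the cell-value-weighted mean closeness: 1 when everything sits in the
corner, low when weight is parked far from it.  Two numerical choices
matter here:

* The per-cell score uses *Euclidean* distance.  Against nulls that fix
  both margins, any statistic linear in packed position has a null mean
  exactly equal to the observed matrix's independence projection, so a
  linear (Manhattan) score cannot distinguish a checkerboard from
  random.  The Euclidean score is strictly convex, and weight
  concentrated along the anti-diagonal then scores *below* the same
  weight spread at random — restoring the anti-nestedness signal.
* The normalising maximum is the most-packed matrix *with the observed
  margins*: the transportation-problem optimum of
  $\sum w_{ij} c_{ij}$ under the row and column totals, computed by
  greedy allocation (optimal because the closeness surface satisfies
  the Monge condition).  Using an unconstrained packing instead makes
  the denominator unreachable by any margins-preserving matrix and
  squashes the estimator towards zero.

WINE normalises WIN against a margin-constrained null ensemble:
$(\mathrm{WIN}_{obs} - \overline{\mathrm{WIN}}_{null}) /
(\mathrm{WIN}_{max} - \overline{\mathrm{WIN}}_{null})$ — about 0 when
the margins alone explain the observed packing, near 1 at maximal
packing, negative for anti-nested (checkerboard-like) structure.  A
z-score and the one-tailed $p = \Pr(\mathrm{WIN}_{null} \ge
\mathrm{WIN}_{obs})$ accompany it.

**Weighted bipartite modularity.**  The two-mode Barber-type objective
$Q = F^{-1} \sum_{ij} (A_{ij} - k_i d_j / F)\,\delta(g_i, g_j)$ is
maximised over joint partitions of species and distance categories by
simulated annealing (single-node relabellings plus module merges under
geometric cooling, then greedy refinement, over independent restarts;
the annealer is compiled and uses R's RNG stream, so runs are fully
reproducible from a seed).  The reported Q is always re-derived from
the reported partition.  The module cap is $\min(n_r, n_c)$: a module
lacking one mode cannot contribute positive Q.  Default schedule:
`cooling = 0.85`, `t_min = 1e-5`, `15 * (rows + cols)` proposals per
temperature, 10 restarts; on matrices small enough to enumerate, this
schedule attains the exhaustive optimum essentially always (tested),
and it recovers planted two-block partitions reliably.

**Null-model inference.**  Significance for both statistics comes from
ensembles of random matrices with exactly the observed row and column
totals (Patefield's algorithm, via `stats::r2dtable`), 1,000 draws per
matrix by default.  Null modularity fits reuse the identical annealing
budget as the observed fit — unequal search effort would bias the
z-score.  One caveat stated plainly: a fixed-margin null is a *sharp*
reference.  Overdispersed (negative-binomial) counts are genuinely
"more structured than Patefield" even without planted pattern, so
significant z-scores on noisy count data indicate departure from the
margins-only model, not necessarily planted spatial organisation; the
package's type-I calibration of the machinery therefore uses self-null
(Patefield-drawn) matrices, where the test is exact.

**Seasonal comparison.**  Following the deviation-from-null approach,
each season's statistic yields D-values (null value − observed value,
one per draw); the wet−dry difference of mean D is tested by a
two-sample label permutation of the pooled D-values, two-sided, with
the identity permutation counted in numerator and denominator (p is
never 0; identical inputs give p = 1, and 9,999 permutations by
default).  The test conditions on the observed statistics: its null
hypothesis is that the two seasons' D-values are draws from one common
distribution.

**Multiple testing.**  Families of p-values (per statistic across
transect × season; the seasonal comparisons) are adjusted by the
Benjamini–Hochberg step-up procedure (`stats::p.adjust`).

## The synthetic-survey generator

The generator emulates the survey's statistical structure so that every
downstream stage can be exercised and calibrated:

* **Counts.**  Negative binomial per trap × season × species with size
  0.5 — strongly aggregated, as pitfall counts of social insects are
  (a catch of ~5.5 × 10⁴ individuals over ~1,260 trap-samples implies
  heavy clumping).  The mean surface is scaled so the expected grand
  total equals `total_individuals` (default 55,000) exactly.
* **Species pool.**  150 morphospecies with log-series relative
  abundances (x = 0.999) by default — the classical long-tailed insect
  SAD; a lognormal alternative is available.  Species labels are
  assigned in decreasing abundance order.
* **Gradient and season.**  A log-linear trend per 100 m on expected
  trap counts, per season (default −0.1, i.e. an e-fold decline over
  the kilometre), and a multiplicative wet:dry ratio (default 2).
* **Planted structure.**  A strength dial in [0, 1] blends an
  unstructured weight surface with a fully structured one; weights are
  row-normalised so planting structure does not change expected totals.
  *Modular*: distance categories are partitioned (default near-water
  {0, 50, 100} m versus the rest) and species assigned round-robin; at
  strength 1 a species' counts are strictly confined to its block.
  *Nested*: structure is planted in the *weighted* (packing) sense —
  at strength 1 the expected matrix is the maximally corner-packed
  arrangement compatible with the species abundance distribution,
  obtained by aligning the rank-ordered SAD onto geometrically decaying
  category capacities (a northwest-corner transport).  This choice is
  deliberate: incidence-triangle ("classical") nestedness is almost
  entirely absorbed by the row and column totals that the null ensemble
  preserves, so it is invisible to margin-constrained inference by
  construction; what the weighted estimator can detect — and what the
  generator therefore plants — is packing beyond the margins'
  independence expectation.
* **What is not simulated.**  No spatial autocorrelation beyond the
  sampling hierarchy, no climate covariates, no trap loss.  Passing
  calibration on generated surveys therefore demonstrates correctness
  of the statistical machinery under the declared model, not robustness
  to every property of real field data.

## Problem sizes and reproducibility

The bundled test-suite and the acceptance script run everything at the
sizes a desk check needs: survey-scale analyses use the full default
design (6 transects, 150 species, 1,000 null draws, 9,999 permutations,
3–5 annealing restarts for ensemble fits); calibration simulations use
1-transect surveys of 30–40 species with 60–200 null draws, 50 seeds
for recovery rates, and 400–1,000 replicates for size/power of the
permutation test.  Every stochastic stage takes an explicit seed, the
pipeline derives per-stage sub-seeds from its master seed, and the run
manifest records config, seeds, package version and the
exclusion/clamp counters, so a run is reproducible from the manifest
alone.

## Known limitations

* The fixed-margin null conditions away abundance structure; see the
  caveat above on overdispersed counts.
* Mixed-model inference on the per-trap responses (distance × season
  fixed effects with sample-point nesting) is intentionally out of
  scope; the pipeline exports a model-ready long table
  (`model_ready.csv`) for external fitting.
* Distance categories are a discrete ordered factor throughout; no
  interpolation between categories is attempted.
* The D-value seasonal test compares deviation distributions, not the
  observed statistics directly; with very tight null distributions even
  small seasonal differences are declared significant.
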