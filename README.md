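# piosphere

Multi-scale analysis of ground-dwelling arthropod communities sampled
along discrete distance-to-water gradients.

In arid savannas, distance to perennial water is a dominant local
environmental gradient: it shapes vegetation, soil and microclimate, and
through them the abundance, diversity and spatial organisation of
ground-dwelling arthropods such as ants.  `piosphere` implements the
full analysis chain for hierarchical pitfall-trap surveys of such
gradients — transects running away from the water with traps at
discrete distance categories, sampled in a wet and a dry season — for
community ecologists who want the whole workflow reproducible from one
seed:

* **Data model** — validated long-format trap tables
  (transect / distance / sample point / trap / season / morphospecies /
  count), community matrices at three pooling levels, and per-transect
  morphospecies × distance-category interaction matrices.
* **Alpha metrics** — abundance, taxonomic richness and the effective
  number of morphospecies per trap, the Hill number of order 1:
  `exp(−Σ pᵢ ln pᵢ)`.
* **Beta diversity as dispersion** — modified Gower dissimilarity
  (counts transformed to `log10(x) + 1`, double zeros excluded, so an
  order-of-magnitude abundance change weighs exactly as much as a
  presence–absence change), embedded by principal coordinates with
  negative-eigenvalue (imaginary) axes retained, and distance to group
  centroids at four nested spatial scales: within transects, within
  distance categories, within distance categories × transects, within
  sample points.
* **Spatial structure** — weighted-interaction nestedness (WIN, with
  the WINE normalisation: ≈0 for margin-random, ≈1 for maximal packing,
  <0 for anti-nestedness) and weighted bipartite modularity
  `Q = F⁻¹ Σᵢⱼ (Aᵢⱼ − kᵢdⱼ/F) δ(gᵢ, gⱼ)` maximised by a compiled
  simulated-annealing search, both tested against null ensembles that
  conserve the observed row *and* column totals exactly (Patefield
  algorithm), with z-scores and one-tailed p-values.
* **Seasonal comparison** — per season, D-values (null − observed) for
  each statistic; wet vs dry compared by a two-sided two-sample
  permutation test on the pooled D-values.
* **Synthetic surveys** — a generator with log-series species
  abundances, negative-binomial trap counts, per-season log-linear
  distance trends, a wet:dry season effect, and plantable nested or
  modular structure with a strength dial and a retrievable planted
  truth, so every stage is testable without field data.
* **Pipeline** — `run_pipeline()` orchestrates everything, writes CSV
  artifacts (alpha and dispersion tables and summaries, structure
  results with Benjamini–Hochberg-adjusted p-values, module
  memberships, seasonal comparisons, a model-ready long table for
  external mixed-model fitting) plus a JSON run manifest with seeds and
  exclusion/clamp counters.

## Worked example

```r
library(piosphere)

# synthesise a one-transect survey with planted near-water modularity
cfg <- generator_config(design = survey_design(n_transects = 1),
                        n_species = 40, total_individuals = 9000,
                        structure = "modular", strength = 0.8, seed = 42)
survey <- generate_survey(cfg)
survey
#> Trap table: 8400 records, 8842 individuals, 40 morphospecies
#>   transects 1 | seasons wet,dry

# per-trap alpha metrics
cm <- build_community_matrix(survey, level = "trap")
head(alpha_metrics(cm)[, c("distance_m", "season", "abundance",
                           "richness", "effective_species")], 3)
#>             distance_m season abundance richness effective_species
#> 1/0/1/1/wet          0    wet        32       10          7.507120
#> 1/0/1/2/wet          0    wet       168       11          4.166902
#> 1/0/1/3/wet          0    wet        69       10          7.140161

# beta diversity: distance to centroid at four spatial scales
disp <- multiscale_dispersion(survey, season = "wet")
aggregate(distance ~ scale, disp, mean)
#>                  scale  distance
#> 1 distance_by_transect 0.6828004
#> 2    distance_category 0.6828004
#> 3         sample_point 0.5761918
#> 4             transect 0.7625542

# spatial structure of the wet-season interaction matrix
M <- build_interaction_matrices(survey)[["T1.wet"]]
ens <- patefield_null(M, n_draws = 1000, seed = 1)
wine(M, ens)
#> Weighted nestedness: WIN obs 0.837 / null 0.835 (max 0.851)
#>   WINE 0.123, z = 10.91, one-tailed p = 0.0000 (1000 null draws)
modularity_significance(M, ens, restarts = 10, seed = 2)
#> Weighted bipartite modularity: Q = 0.3342, 2 modules
#>   null mean 0.0354 (sd 0.0029), z = 101.79, one-tailed p = 0.0000 (1000 draws)
```

Reading the output: sampling variation (within sample points, mean
dissimilarity-space distance 0.58) is smaller than heterogeneity along
the transect (0.76), as the nested design implies.  The planted
modular structure is recovered — two modules, observed Q = 0.334 far
above the margin-conserving null (mean 0.035) — while nestedness
beyond what the matrix margins already impose is weak (WINE = 0.12),
exactly the contrast between modular and nested organisation the
analysis is designed to resolve.  The full pipeline over all transects,
seasons and scales is one call:

```r
rc <- run_config(generator_config(seed = 1), seed = 1, out_dir = "run1")
run_pipeline(rc)
```

A thin command-line wrapper with `generate` and `analyze` subcommands
ships in `inst/scripts/piosphere-cli.R`.

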