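# snhbees

Community-ecology toolkit for asking how different types of semi-natural
habitat (SNH) in agricultural landscapes — hedgerows, forest edges and
permanent grasslands — support wild-bee diversity. It is aimed at pollinator
ecologists working with long-format survey tables: sampling points, netted
bee individuals, botanical relevés (Braun-Blanquet, used strictly as
presence/absence), and the pollen taxa identified on each bee's body.

Four analysis stages, each usable on its own:

1. **Beta-diversity partitioning.** Pairwise Sørensen dissimilarity between
   presence/absence communities, decomposed after Baselga into spatial
   turnover (Simpson dissimilarity) and a nestedness-resultant component:

   βsor = (b + c) / (2a + b + c),  βsim = b / (a + b),  βsne = βsor − βsim

   with *a* the shared species, *b*/*c* the species unique to the
   poorer/richer community. Applied between pooled habitat communities and
   between sampling points within a habitat, with a permutation null model
   (point labels shuffled, add-one p-value) for the habitat effect.
2. **Rarefaction–extrapolation.** Individual-based expected richness
   E[S_m] = S_obs − Σ_i C(n − x_i, m)/C(n, m) for m ≤ n, Chao1-based
   extrapolation beyond n (bounded at 2n), bootstrap percentile bands
   (default 84%, so non-overlap ≈ a test at α = 0.05).
3. **Pollen selection.** Per-taxon availability PA (occurrence share in the
   flora), harvest rate HR (share of pollen records, or of examined bees),
   and Jacobs' selection index

   D = (HR − PA) / (HR + PA − 2·HR·PA) ∈ [−1, 1],

   with bootstrap CIs (bees resampled with their whole loads, 5000
   replicates, 2.5/97.5 percentiles) and over-/under-selected/neutral
   classification by whether the CI excludes 0.
4. **Network robustness.** The study-site bipartite bee–pollen network
   (unique species-level interactions, abundant bee species only, >4
   individuals), and the percentage of interactions/species remaining after
   removing all points of one habitat, under equal-effort resampling
   (24 points per habitat drawn without replacement, 5000 replicates).

A synthetic-data generator (`simulation_config()`, `generate_dataset()`,
`emulate_study_design()`) produces datasets with known ground truth —
habitat species pools with controlled overlap, configurable foraging
preferences, realistic pollen-load marginals — so the whole pipeline is
testable without any field data.

## Worked example

```r
library(snhbees)
sim <- emulate_study_design(seed = 1)   # 30 hedgerows, 29 grasslands, 24 forest edges
ds <- sim$dataset
ds
#> <bee_dataset>
#>   sampling points: 83 (hedgerow=30, forest_edge=24, grassland=29)
#>   bees:   525 individuals, 75 species
#>   plants: 1636 occurrence rows, 295 taxa
#>   pollen: 515 records, 172 taxa

baselga_partition(pooled_habitat_community(ds, "grassland", "bees"),
                  pooled_habitat_community(ds, "hedgerow", "bees"))
#> beta partition: a=14 b=17 c=24 | bsor=0.5942 = bsim=0.5484 + bsne=0.0458
```

The grassland and hedgerow bee communities share 14 species; the
dissimilarity (0.59) is almost entirely turnover (0.55), not nestedness —
the generator's habitat pools overlap by 35%, so wooded and herbaceous
communities are genuinely different, not subsets of one another.

```r
sel <- bootstrap_selection(ds, n_boot = 5000, seed = 1)
sel
#> pollen selection: 172 taxa (0 excluded, absent from flora), 433 bees, 5000 boot
#>   classes: neutral=158, over_selected=5, under_selected=9

sub <- abundant_species_filter(ds)      # bee species with > 4 individuals
habitat_removal_robustness(sub, "grassland", n_boot = 5000,
                           subsample_size = 24, seed = 1)
#> habitat removal: grassland (5000 replicates, subsample 24)
#>   pct_remnant_interactions   mean 50.5% lost 49.5% (sd 2.13)
#>   pct_remnant_plants         mean 65.8% lost 34.2% (sd 1.19)
#>   pct_remnant_bees           mean 83.3% lost 16.7% (sd 0.09)
```

Removing the grasslands from this synthetic network costs about half of the
unique bee–pollen interactions; taxa flagged `over_selected` are those whose
bootstrap CI for Jacobs' D lies entirely above zero.

The whole chain (read/simulate → diversity → selection → network, CSV
outputs plus a JSON manifest with seeds and input checksums) runs via
`run_pipeline()` or the CLI:

```sh
Rscript -e 'snhbees::snh_cli()' simulate --out-dir sim --seed 1
Rscript -e 'snhbees::snh_cli()' run --config config.json --out-dir out
```

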