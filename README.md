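# trophicstrat

Tools for analysing how species richness is stratified across trophic
levels, and whether that stratification is uniform across the world's
community types. The package is aimed at macroecologists and food-web
researchers working with taxon-level diet descriptions (insect families,
herptile orders, bird/mammal species tables) and gridded species
assemblages.

## What it computes

**Trophic levels from diet.** Every species gets a primary-consumption
fraction *p* ∈ [0, 1] — the share of its diet derived from autotroph
(plant) material — and is classified under Lindeman's energetic
definition:

* primary consumer: *p* > 2/3
* mixed consumer (trophic omnivore): 1/3 ≤ *p* ≤ 2/3
* higher-level consumer: *p* < 1/3

Diet categories map to constants (phytophagy, nectivory, herbivory → 1;
predation, parasitism, scavenging, fungivory, carnivory → 0) or to
uncertainty intervals where the energy source is ambiguous (plant
detritivory → U[0.5, 1]; generalist saprophagy and detritivory →
U[0, 1]). Verbal predominance descriptors ("most species are X") allocate
U[0.65, 0.95] of a taxon's species to the predominant diet; insect taxa
with exclusively nectivorous adults average larval and adult diets with
the adult weighted U[0.10, 0.50]. Aquatic taxa and birds/mammals with
> 30% fish in the diet are excluded.

**Monte Carlo pyramids.** All of these stochastic rules are redrawn in
each of 1000 replicates (`build_pyramid`), yielding per-level species
percentages with 95% confidence intervals — a trophic pyramid of species
richness, per taxon group or pooled.

**Community grids and uniformity tests.** Species-by-pixel presence
tables on a one-degree grid become per-pixel proportions of
primary/mixed/higher species (`assemble_pixels`). Pixels carry one of six
community trophic structure labels (depauperate, boreal, temperate,
semi-arid, seasonal tropical, humid tropical); a linear discriminant
analysis on arcsine-√ transformed proportions (`discriminate_structures`)
measures how separable the classes are, as accuracy improvement over a
proportional-chance baseline Σpₖ². Bird/mammal diet-item tables aggregate
into a per-pixel community diet whose primary (plant-based) percentage is
compared across classes by one-way ANOVA with R² = SS_between/SS_total
(`anova_r2`).

A synthetic-data generator (`synthetic_spec`, `generate_taxon_records`,
`generate_grid`) produces every input with controllable ground truth, so
the whole pipeline is testable without any downloads.

## Worked example

```r
library(trophicstrat)

cfg <- uncertainty_config(seed = 1, n_replicates = 200)
gen <- generate_taxon_records(synthetic_spec(n_taxa = 40, seed = 1))
keep <- filter_species(gen$records, cfg)
retained <- gen$records[gen$records$taxon_id %in% names(keep)[keep], ]
build_pyramid(retained, cfg)
#> Trophic pyramid (all): 200 replicates
#>   group   level  mean  ci_lo ci_hi half_width n_replicates
#> 1   all primary 23.98 11.523 35.06     11.769          200
#> 2   all   mixed 14.84  4.234 29.01     12.388          200
#> 3   all  higher 61.18 52.465 70.83      9.182          200
```

Roughly 61% of this synthetic assemblage's species are higher-level
consumers; the wide intervals reflect the predominance and
interval-category uncertainty propagated through 200 replicates.

```r
grid <- generate_grid(synthetic_spec(seed = 3, pixels_per_class = 20,
                                     richness = 40))
comp <- assemble_pixels(grid$presence, grid$profiles, grid$pixels)
discriminate_structures(comp)
#> Discriminant analysis of trophic composition (resubstitution)
#>   accuracy: 0.3250  chance (proportional): 0.1667  improvement: 0.1583
#>   pixels: 120  predictors: t_primary, t_mixed

agg <- aggregate_community_diet(grid$presence, grid$diet)
anova_r2(agg$primary_consumption_pct[match(comp$pixel_id, agg$pixel_id)],
         comp$structure_class)
#> One-way ANOVA: R^2 = 0.0971  F(5, 114) = 2.452  p = 0.0377

pooled_level_summary(comp)
#>     level mean_pct  ci_lo ci_hi half_width n_pixels
#> 1 primary    21.02 20.158 21.88      0.863      120
#> 2   mixed    10.04  9.264 10.82      0.778      120
#> 3  higher    68.94 67.909 69.97      1.029      120
```

The default synthetic archetypes give six classes with nearly identical
trophic-level ratios (~21/10/69% pooled) but different diet-item mixes:
the discriminant sees only a modest improvement over chance and class
membership explains ~10% of the variance in community primary
consumption — trophic stratification is close to uniform across classes
even though what is eaten differs.

See `vignettes/trophic-stratification.Rmd` for the full account of the
rules, the Monte Carlo scheme and the design choices.

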