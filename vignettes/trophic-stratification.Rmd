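---
title: "Trophic stratification of species richness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trophic stratification of species richness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicstrat)
```

## The scientific question

How is species richness distributed across trophic levels — and is that
distribution uniform across the world's community types? `trophicstrat`
implements a three-level consumer scheme under Lindeman's energetic
definition: a species is a **primary consumer** when more than 2/3 of its
diet derives from autotroph (plant) material, a **higher-level consumer**
when less than 1/3 does, and a **mixed consumer** (trophic omnivore) on the
closed band in between. Any consumption of non-autotroph biomass — animals,
fungi, carrion — is higher-level consumption: fungi are themselves
consumers, and whether prey is dead or alive does not change the consumer's
trophic position.

The package has three analysis stages:

1. **Rule-based classification with uncertainty propagation**
   (`species_primary_fraction`, `build_pyramid`): taxon-level diet records
   are mapped to per-species primary-consumption fractions `p`, and every
   verbally or energetically uncertain quantity is redrawn in each of 1000
   Monte Carlo replicates to produce a trophic pyramid of species richness
   with confidence intervals.
2. **Community assembly on a one-degree grid** (`assemble_pixels`,
   `aggregate_community_diet`): per-pixel proportions of primary, mixed and
   higher-level species, plus an aggregated bird/mammal community diet split
   into plant-based and animal-based consumption.
3. **Uniformity statistics** (`discriminate_structures`, `anova_r2`,
   `pooled_level_summary`): can pixels of the six community trophic
   structures ("trophic biomes": depauperate, boreal, temperate, semi-arid,
   seasonal tropical, humid tropical) be told apart from their trophic-level
   proportions alone, and how much variance in community primary consumption
   do the classes explain?

## The classification rules

Diet vocabularies are closed per taxonomic group (`diet_categories`).
Constant-fraction categories map directly to `p`:

| fraction | categories |
|---|---|
| 1 (plant-based) | phytophagy, nectivory, herbivory, plants, seeds, fruit, nectar |
| 0 (animal/fungal) | predation, parasitism, ectoparasitism, scavenging, fungivory, carnivory, invertebrates, vertebrate endotherms/ectotherms, fish, carrion, unknown vertebrates |

Three categories are energetically ambiguous and map to uniform intervals:
plant detritivory (dead wood and leaves) to `[0.5, 1]` — an unknown share
of that energy has already passed through fungi — and generalist
saprophagy / herptile detritivory to `[0, 1]`, where the energy source is
fully unknown. Kleptoparasitism, dung and honeydew feeding are encoded as
scavenging: they rely on products of animal consumers.

Records enter as one CSV row per (taxon, stage, diet component). Three
resolution modes cover the ways natural-history descriptions report diets:

* **Within-species mixes** (component weights given): `p` is the
  weight-averaged component fraction; weights may be on a 0–100 or 0–1
  scale and must sum to 100 (or 1) within `1e-6`.
* **Across-species assignments** (no weights): the taxon's species count is
  split evenly across the listed diets. Fractional allocations are kept —
  the outputs of interest are percentages, and rounding would break exact
  conservation of species counts.
* **Predominance descriptors** ("most species are X"): the predominant diet
  receives a share drawn uniformly from 65–95% of the species, the
  remainder split evenly across the alternatives.

Taxa with complete metamorphosis carry a larva and an adult stage. Stages
weigh equally, except when the adult is exclusively nectivorous — then the
bulk of energy acquisition happens in the larval stage and the adult weight
is drawn from 10–50%. When a two-stage taxon's larval diets split the taxon
across species, the species blocks are defined by the larval allocation and
the adult stage is collapsed to its allocation-weighted mean fraction
before averaging; adult stages in such taxa are in practice single-diet
(typically nectivory), so this convention is only a tie-break for
malformed-but-parseable inputs.

**Exclusion filter.** Species with marine or aquatic habits at any life
stage are excluded, as are birds and mammals with strictly more than 30%
fish in their diet (the threshold separates opportunistic fish-eaters from
predominantly aquatic feeders; exactly 30% is retained). The fish rule is
applied to the raw reported percentage, before any renormalization. Fish
and unknown-vertebrate items in *retained* species still count as
higher-level consumption — they are animal biomass.

## Monte Carlo scheme and numerical choices

All uncertain quantities are drawn uniformly over their stated ranges —
the least-informative choice where no distribution is given. Each of the
`n_replicates` (default 1000) replicates redraws every quantity
independently per taxon and per rule. Reproducibility is by construction:
a master seed spawns one child seed per replicate, and each taxon's draws
are seeded by a hash of (child seed, taxon id). Consequently a pyramid
built per group (`pyramid_by_group`) uses draw-for-draw the same values as
the pooled run, and the weighted average of group pyramids equals the
pooled pyramid replicate by replicate — a conservation identity the test
suite checks exactly.

Boundary conventions: the mixed band is the **closed** interval
`[1/3, 2/3]` ("more than 2/3" is strict, so ties at the thresholds are
mixed). Summaries report the mean across replicates with a 95% interval,
by default the 2.5–97.5 percentile interval of replicate values (reported
symmetric "±" values in the literature do not name a method); a normal
approximation (mean ± 1.96 sd) is available via
`uncertainty_config(ci_method = "normal")`. With one replicate the CI is
reported as `NA` rather than a degenerate interval. Midpoint mode
(`draws = "midpoint"`, predominance pinned at 0.80) makes the whole
mapping deterministic and is the generator's ground-truth convention.

## Community grid and structure statistics

Per-pixel trophic-level proportions are species counts divided by
richness; zero-species pixels are dropped with a logged count. The
pipeline's default trophic level per species is a fixed classification
(the deterministic midpoint resolution, or the majority level across
replicates from `species_level_frequencies`); whether the original
analysis used one fixed classification or averaged over all 1000
randomizations is not stated in comparable workflows, so both modes are
provided — `assemble_pixels(..., propagate = TRUE)` averages each
species' replicate level frequencies into the pixel composition instead
of hard counts. Proportions
are arcsine-square-root transformed (`asin(sqrt(x))`, radians, the
standard variance-stabilizing transform for proportions) before the
discriminant analysis; values outside `[0, 1]` by more than `1e-12` are an
error, smaller excursions are clamped.

**Discriminant analysis.** Because the three proportions sum to one, only
the transformed primary and mixed proportions enter the linear
discriminant by default (`keep_all = TRUE` retains all three — the
transform is nonlinear, so they are only near-collinear). Accuracy is
reported under a named validation scheme: resubstitution by default
(matching the most common default in comparable workflows) or
leave-one-out. The chance baseline defaults to the proportional-chance
criterion `sum(p_k^2)` because biome class sizes are strongly unbalanced;
uniform (`1/K`) and majority baselines are selectable, and "improvement"
is always accuracy minus baseline in the same units. Two degenerate cases
are handled explicitly: identical predictors across all pixels fall back
to the majority-class constant classifier, and classes with zero
within-class variance (point-mass compositions) are classified by nearest
class centroid — the limiting discriminant rule — rather than erroring.

**ANOVA.** The percentage of primary consumption in the aggregated
community diet is compared across classes with a standard one-way
decomposition; `R^2 = SS_between / SS_total` is the explanatory power of
class membership, defined as 0 when the response is constant. The ANOVA
runs on raw percentages — the arcsine transform is specified for the
discriminant predictors only. The result also carries the
degrees-of-freedom-adjusted `r_squared_adj`: raw `R^2` has expectation
`(k-1)/(n-1)` even when classes explain nothing, so null-calibration
checks (and any test of "indistinguishable from zero") should use the
adjusted value, just as unbiased null checks of the discriminant use
leave-one-out rather than resubstitution accuracy.

## The synthetic-data generator

`generate_taxon_records` emits record tables exercising every rule branch
— predominance descriptors, within-species mixes, interval categories,
larva/adult splits with exclusively nectivorous adults, aquatic flags and
fish-threshold exclusions — together with the expected level percentages
under midpoint draws, computed by direct arithmetic independent of the
rule engine. Species counts are log-uniform between 2 and 500, emulating
the orders-of-magnitude spread of real taxon sizes; birds and mammals are
generated as species-level records, insects at family level and the rest
at order level.

`generate_grid` builds, per structure class, a regional species pool at
each trophic level, draws each pixel's composition from a class Dirichlet
archetype (mean + concentration), fills pixels by largest-remainder
rounding and sampling from the pools, and draws species diet-item vectors
consistent with trophic level: primary species eat the class's plant-item
mix, higher-level species its animal-item mix, mixed species a 50/50
blend. The default archetypes deliberately encode the qualitative study
outcome — six classes with very similar trophic-level ratios (all near
21% primary / 10% mixed / 69% higher-level) but clearly different
diet-item mixes (seed-dominated cold/dry classes, fruit- and
nectar-dominated tropical classes). They are synthetic defaults, not
fitted values. `concentration = Inf` gives point-mass compositions
(perfectly separable classes when the means differ); a shared archetype
across all classes gives the null. Default problem sizes — 40 pixels per
class at richness 50 for the demo grid, 12 pixels per class at richness
40 for the replicated null simulations, 100 taxa for the demo pyramid —
are chosen so that Monte Carlo standard errors are small relative to the
effects of interest.

What the generator does **not** emulate: spatial autocorrelation of
assemblages (pixels are exchangeable within a class), range cohesion
(species are sampled independently per pixel), taxonomy beyond group
labels, and the derivation of the six structure labels themselves (labels
are inputs). Passing tests therefore validate the computational pipeline
and its statistical behaviour, not the biogeographic realism of any
particular dataset.

## Worked example

```{r example, eval = FALSE}
cfg <- uncertainty_config(seed = 1, n_replicates = 1000)
gen <- generate_taxon_records(synthetic_spec(n_taxa = 100, seed = 1))
keep <- filter_species(gen$records, cfg)
retained <- gen$records[gen$records$taxon_id %in% names(keep)[keep], ]
summarize_pyramid(build_pyramid(retained, cfg))

grid <- generate_grid(synthetic_spec(seed = 3))
comp <- assemble_pixels(grid$presence, grid$profiles, grid$pixels)
discriminate_structures(comp)
agg <- aggregate_community_diet(grid$presence, grid$diet)
anova_r2(agg$primary_consumption_pct[match(comp$pixel_id, agg$pixel_id)],
         comp$structure_class)
```

## Known limitations

* The classifier consumes encoded diet records; it does not parse
  natural-history literature.
* Range maps are out of scope: the grid stage ingests precomputed
  species-by-pixel presence tables.
* Only linear discriminants are offered (no quadratic or regularized
  variants), and no post-hoc multiple comparisons follow the ANOVA.
* The predominance-residual rule (remaining species split evenly across
  alternatives) is one reading of "unless otherwise specified"
  descriptions; records with explicit sub-taxon counts should encode them
  as separate rows, which take precedence by construction.
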