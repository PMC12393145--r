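# dispersalkit

Most of what we know about microbial community assembly comes from
snapshots of who is there, not from measuring how microbes *move*.
`dispersalkit` implements a trap-based workflow for quantifying microbial
dispersal into the soil surface: **how fast** cells immigrate (an
immigration–death kinetic model fitted to cell counts on paired open and
closed glass slides) and **how far** they travel (a radius-scanned partial
Mantel analysis that finds the spatial scale at which surrounding plant
composition predicts the composition of trapped microbes). It is aimed at
microbial ecologists running field trap experiments — and at anyone who
wants seeded, first-principles implementations of PERMANOVA, PERMDISP,
PCoA and simple/partial Mantel tests that operate directly on distance
matrices.

## The models

**Immigration rate.** A sterile slide open to dispersal accumulates cells
according to

```
dN/dt = I − δN,  N(0) = 0   ⇒   N(t) = (I/δ)(1 − e^(−δt))
```

with immigration rate `I` (cells·cm⁻²·day⁻¹) and per-capita death rate `δ`
(day⁻¹). `δ` is estimated first, from closed slides inoculated with a known
community: ordinary least squares of `ln N` on time gives slope `−δ`, and
`(1 − e^(−δ))·100` is the percent of the community dying per day. With `δ`
fixed, the open-slide model is linear in `I` on the log scale
(`ln N(t) = ln I + ln[(1 − e^(−δt))/δ]`), so `ln Î` is a mean offset with a
standard error, transformed to `Î ± SE` by the delta method. An ANCOVA-style
F-test (`ln N ~ day × group`) checks whether decay slopes differ between
ecosystems.

**Dispersal scale.** Around every trap, plant community composition is
computed inside circles of increasing radius from a labelled polygon map
(exact convex polygon clipping; unmapped area is assigned the average grass
composition). At each radius the partial Mantel correlation between
microbial Bray–Curtis distances and plant-composition distances — holding
geographic distance fixed — is evaluated with a seeded permutation null.
The radius with the strongest correlation estimates the scale at which
dispersal is limited.

A synthetic-data module generates two-ecosystem landscapes, trap
communities driven by vegetation within a known influence radius, and
open/closed cell-count series with known `I` and `δ`, so every estimator
has a ground-truth recovery test.

## Worked example

```r
library(dispersalkit)

## kinetics: 96 open + 35 closed slides over a 2-month deployment
open   <- simulate_cell_counts(kinetics_sim_config(seed = 1), "open")
closed <- simulate_cell_counts(
  kinetics_sim_config(sample_days = c(3, 7, 14, 28, 56),
                      slides_per_timepoint = 7, seed = 1), "closed")
fit <- fit_immigration_death(rbind(open, closed))
summary(fit)
#> Immigration-death model summary
#>   delta      0.02288 /day  (2.26%/day; closed n = 35, R2 = 0.477)
#>   I          1085.5 +/- 51.0 cells/cm2/day (open n = 96)
#>   plateau    47453 cells/cm2 (I/delta)
immigration_fraction_of_source(coef(fit)[["immigration_I"]], 2.8e6)
#> [1] 0.04
```

The series were simulated with true `I = 1060` cells/cm²/day and
`δ = 0.02799`/day under 50% lognormal count noise; the fit recovers both
within sampling error. The last line expresses immigration as a percentage
of a litter source community holding 2.8 million cells/cm² — a fraction far
too small for dispersal to homogenize the resident community.

```r
## where do the arriving microbes come from? scan radii 0.1–4 m
land <- generate_landscape(landscape_config(seed = 1))
prof <- random_source_profiles(
  c("bare", "forb", "shrub", names(land$map$avg_grass)), seed = 1)
tab  <- simulate_trap_communities(land$map, land$locations, prof,
                                  trap_sim_config(seed = 1))   # true radius 1 m
D <- bray_curtis(relative_abundance(tab))
permanova(D, land$locations$ecosystem, n_perm = 999, seed = 1)
#> PERMANOVA: pseudo-F(1, 22) = 1.145, P = 0.267 ( 999 permutations)
#>   variance explained: 4.9%
radius_scan(land$map, land$locations, D, n_perm = 999, seed = 1)
#> Radius scan: 11 radii from 0.1 to 4 m
#>   radius_m      r p_value n_permutations degenerate p_holm
#>  0.1000000 0.6151   0.001            999      FALSE  0.011
#>  ...
#>  0.9146101 0.8707   0.001            999      FALSE  0.011
#>  1.3226410 0.7777   0.001            999      FALSE  0.011
#>  ...
#>  4.0000000 0.1628   0.097            999      FALSE  0.158
#> strongest partial Mantel correlation: r = 0.8707 at 0.915 m
```

The scan peaks at 0.915 m — the grid point nearest the 1 m influence
radius the communities were simulated with: the composition of arriving
microbes carries a meter-scale signature of its vegetation sources.

`run_pipeline(run_config(outdir, seed))` chains all stages
(simulate → fit-kinetics → permanova/permdisp → scale-scan) and writes
every artifact as TSV/GeoJSON/JSON plus a manifest recording seeds and
parameters.

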