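# sipcall

Active-community analysis for DNA stable-isotope probing (DNA-SIP)
experiments in R.

## The problem

DNA-SIP identifies *actively growing* microorganisms: soils (or other
communities) are incubated with a ¹³C-labeled substrate (CH₄, CO₂, or sodium
acetate), growing cells incorporate the heavy carbon into their DNA, and
density-gradient ultracentrifugation separates labeled ("heavy") from
unlabeled ("light") DNA before sequencing. Two complications make naive
analysis of the heavy fraction misleading:

1. **GC background.** High-GC genomes are denser, so unlabeled high-GC DNA
   drifts into the heavy fraction even without any ¹³C. A parallel ¹²C
   control incubation, with its heavy fraction sequenced, measures exactly
   this background.
2. **Catabolic turnover.** Organisms can process the substrate without
   growing; only anabolic incorporation marks growth.

`sipcall` implements the paired-control workflow that addresses both: every
¹³C sample is rarefied together with its matched ¹²C-heavy control to a
common depth *d*, and a feature (taxon or functional annotation) is called
**active** in that sample when its count is significantly higher than in the
control by a one-sided Fisher exact test on the 2×2 table

```
            feature   rest
  13C        c13     d - c13
  12C        c12     d - c12
```

at *p* < 0.05, with control-normalized abundance `max(0, c13 - c12)`
(features less abundant than their control are floored at zero). Downstream,
the package compares active communities across land uses (one-way ANOVA with
Tukey–Kramer post hoc tests and an eta-squared effect size, plus an
"active re-check" that discards features never called active in the
associated group), summarizes methanogen/methanotroph guilds, and provides
community-level permutation statistics: Bray–Curtis dissimilarity,
PERMANOVA with sequential sums of squares, and PERMDISP. A synthetic
SIP-experiment generator with known ground truth (who is active, where, at
what enrichment) makes every stage testable end to end.

Intended users: microbial ecologists analyzing paired-control SIP
experiments (amplicon or metagenome annotation tables), and method
developers who need a ground-truthed SIP simulator.

## Worked example

Simulate a pasture-enrichment scenario (three land uses — primary forest
`PF`, pasture `P`, secondary forest `SF` — three substrates, three labeled
cores plus one ¹²C control per combination, 50,000 reads per sample), call
activity, and compare methanogen richness across land uses:

```r
library(sipcall)
library(dplyr)

sim     <- simulate_sip_experiment(preset_pasture_enrichment(seed = 7))
pairing <- link_controls(sim$counts, sim$metadata)
tbl     <- sim$counts[, c("feature_id", union(pairing$sample_id, pairing$control_id))]
calls   <- call_active(tbl, pairing, alpha = 0.05)   # already at equal depth

active_summary(calls, sim$guilds) |>
  left_join(select(sim$metadata, sample_id, land_use, substrate), by = "sample_id") |>
  filter(guild == "methanogen", substrate != "CH4") |>
  group_by(land_use) |>
  summarise(mean_richness = mean(richness), mean_abundance = mean(abundance))
#> # A tibble: 3 × 3
#>   land_use mean_richness mean_abundance
#>   <chr>            <dbl>          <dbl>
#> 1 P                   20         24631.
#> 2 PF                   8          7695.
#> 3 SF                   8          7633.
```

Pasture samples carry 20 distinct active methanogens on average versus 8 in
either forest class, at roughly three-fold higher control-normalized
abundance — the simulated ground truth (20 active methanogens in pasture, 8
in the forests, six-fold guild enrichment) is recovered. The formal
comparison per (location, substrate) stratum:

```r
richness_comparison(calls, sim$metadata, sim$guilds, "methanogen") |>
  select(location, substrate, F, p_anova, eta_squared, association)
#> # A tibble: 3 × 6
#>   location substrate      F p_anova eta_squared association
#>   <chr>    <chr>      <dbl>   <dbl>       <dbl> <chr>
#> 1 SiteA    CH4         1.75   0.252       0.368 <NA>
#> 2 SiteA    CO2       Inf      0           1     P
#> 3 SiteA    NaAOc     Inf      0           1     P
```

Under the methanogenic substrates (CO₂, acetate) the land-use difference is
complete separation (every pasture core beats every forest core, so the
ANOVA F is infinite and eta-squared is 1) and pasture is the associated land
use; under CH₄ — where methanotrophs, not methanogens, are active — there is
no difference to find. `run_pipeline(run_config(preset =
"pasture-enrichment", seed = 7))` executes the same stages end to end
(linkage → rarefaction → control normalization → activity calls → guild
summaries → land-use comparisons → Bray–Curtis/PERMANOVA/PERMDISP →
methanotroph type fractions) and writes every table as TSV with a
provenance header plus a `manifest.json`.

Real data enter through `read_count_table()` (TSV; `read_count_table_biom()`
for BIOM v1), `read_sample_metadata()` and `read_guild_catalog()`; the
shell driver `exec/sipcall` exposes `simulate`, `validate`, `call-active`,
`compare`, `community` and `run` subcommands over the same functions.

## Scope

The package starts from annotation count tables; amplicon denoising,
metagenome annotation, gradient physics (buoyant densities, fraction-level
qPCR) and qSIP-style atom-fraction-excess estimation are out of scope. See
`vignettes/sip-activity-analysis.Rmd` for the statistical model, parameter
choices, and known limitations.
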