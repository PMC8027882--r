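---
title: "Identifying active methane-cycling communities from paired-control DNA-SIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying active methane-cycling communities from paired-control DNA-SIP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipcall)
library(dplyr)
```

## The statistical model

A paired-control DNA-SIP experiment produces, for every combination of
location, land use and substrate, a set of ¹³C-labeled soil cores whose
heavy gradient fraction is sequenced, plus one ¹²C control core sequenced in
both heavy and light fractions. The heavy fraction of the control exists for
one reason: high-GC unlabeled DNA is dense enough to appear there, so the
control's heavy fraction measures the GC-driven background that must be
subtracted before any claim about isotope incorporation.

`sipcall`'s activity model is deliberately minimal and matches how such data
are produced:

* Both members of a pair are rarefied (sampling without replacement) to a
  common depth $d$, so counts are comparable.
* For feature $f$ in ¹³C sample $s$ with matched control $c$, the evidence
  for enrichment is the one-sided Fisher exact test on
  $[c_{13}, d - c_{13}; c_{12}, d - c_{12}]$: the upper tail of the
  hypergeometric distribution, accumulated in log space. The test is
  one-sided because "active" is a directional claim — significantly *more*
  abundant in the labeled sample.
* A feature is **active** in $s$ iff $p < \alpha$ (strict, default
  $\alpha = 0.05$) *and* its observed proportion is strictly greater than in
  the control. Its control-normalized abundance is
  $\max(0, c_{13} - c_{12})$; features at or below their control are floored
  to zero. Features with zero counts in both members are untested and are
  excluded from richness denominators.

No multiple-testing correction is applied by default: the classification is
per (feature, sample) at raw $p < 0.05$, which is the established practice
for this design; `p_adjust = "BH"` is available and clearly marked as a
deviation. Because single samples are compared, the test assumes no
biological overdispersion between a labeled core and its control core
beyond multinomial sampling — a real limitation of the design discussed
under *Limitations*.

Downstream comparisons work on the control-normalized abundances:

* **Per-feature land-use comparison** (within one location × substrate
  stratum): one-way ANOVA across land uses, eta-squared
  ($SS_{between}/SS_{total}$) as effect size, Tukey–Kramer pairwise tests
  with the harmonic adjustment for unbalanced groups. The *land-use
  association* is the land use whose mean is highest and significantly
  higher (each pairwise $p < \alpha$) than every other land use; ties yield
  no association. Every associated feature is re-checked against the
  activity calls — a feature never called active in the associated land use
  is dropped. This re-check prevents reporting differences driven entirely
  by control-side variation.
* **Guild richness comparison**: the number of distinct active methanogens
  (or methanotrophs) per sample, compared across land uses with the same
  ANOVA + Tukey machinery.
* **Community statistics**: Bray–Curtis dissimilarities
  ($d(x,y) = \sum|x_f - y_f| / \sum(x_f + y_f)$), PERMANOVA with sequential
  (Type I) sums of squares via Gower centering and nested projections, and
  PERMDISP (distances to group centroids in principal-coordinate space with
  the imaginary-axis correction). Significance comes from free permutation
  of samples; the full permutation set is enumerated exactly when
  $n! \le 10{,}000$, otherwise `n_perm` draws are used and
  $p = (1 + \#\{F^\pi \ge F\})/(n_{perm}+1)$, so the default
  `n_perm = 999` gives a p-value floor of 0.001.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | activity and comparison threshold, compared strictly |
| rarefaction `depth` | min column sum (16S convention: 20,000) | common depth per pair |
| `n_perm` | 999 | permutations for PERMANOVA/PERMDISP |
| `alternative` | `"greater"` | test sidedness; `"two.sided"` uses the minimum-likelihood rule |
| `seed` | — | master seed; per-sample rarefaction streams derive from `(seed, sample_id)` |

Deriving each sample's rarefaction stream from `(seed, sample_id)` rather
than from column position makes every result invariant to the order in
which samples appear in a file.

## What the synthetic generator emulates

`simulate_sip_experiment()` draws a full paired design with known truth.
Its generative model:

* Baseline relative abundances from a normalized lognormal
  (`lognormal_sigma = 1.5`, a typical skew for soil communities).
* The methanogen and methanotroph guilds are pinned to fixed total community
  shares (`guild_share`, default 1.5% each). Methane-cycling guilds are
  rare-biosphere members of soils — roughly a percent of annotations — and a
  fixed share also keeps the total isotope-labeled biomass realistic, which
  matters because the relative (compositional) nature of sequencing means a
  heavily labeled community dilutes every feature's relative enrichment.
* Per-taxon GC content $g_i \sim N(0.5, 0.05)$ and a heavy-partition
  probability $h_i = \mathrm{logistic}(\kappa(g_i + \delta a_i - g_0))$ with
  $\kappa = 30$, $\delta = 0.3$, midpoint $g_0 = 0.62$. The midpoint sits
  well above the mean GC so a typical unlabeled genome sends only a few
  percent of its DNA heavy while high-GC genomes leak progressively more —
  the exact confounder the control design corrects — and full labeling
  ($a_i = 1$) shifts density by the equivalent of ~30 GC points, matching
  the relative magnitudes of labeling and GC effects on buoyant density.
  Heavy/light pooling into two classes mirrors how gradient fractions are
  pooled before sequencing; modeling 12 individual fractions would add
  physics without changing the analysis-relevant resolution.
* Activity by substrate: CH₄ feeds methanotrophs; CO₂ and acetate feed
  methanogens plus a set of ordinary heterotrophic consumers. Designated
  active sets are the *most abundant* guild members (top-K by baseline
  weight, nested across land uses): active populations grow over the
  months-long incubation, so by sequencing time the active members of a
  guild are its abundant ones. Consumers are median-abundance background
  taxa.
* Replicate cores redraw their community from a Dirichlet centered on the
  site profile (`core_concentration`); `Inf` disables core noise and yields
  the exchangeable null used for calibration. The preset uses a high
  concentration (low core-to-core noise), consistent with the
  no-overdispersion assumption of the paired exact test.
* Counts are multinomial at exactly `depth` reads per sample, with heavy
  probabilities $\propto w_i h_i$ and light $\propto w_i(1 - h_i)$.

`preset_pasture_enrichment()` encodes the scenario the pipeline must
recover: 20 of 25 methanogens active in pasture versus the top 8 in either
forest class (a strict superset), a six-fold pasture enrichment of the
methanogen guild, and 12 methanotrophs active under CH₄ everywhere.

**What passing tests do and do not show.** Recovery of this truth
demonstrates that the pipeline's logic is correct under its own model:
multinomial sampling, a clean two-class density partition, modest core
noise, and active taxa that are abundant enough to count. It does not
demonstrate robustness to the things real data add — between-core
biological overdispersion (which inflates the exact test's false-positive
rate), annotation errors and database drift, chimeric or cross-fed labeling
(partial ¹³C incorporation by secondary consumers), or compositional
effects when a very large fraction of the community is labeled.

## Numerical choices

* The exact test accumulates hypergeometric tails with `lchoose` in log
  space; an exhaustive sweep of every table with depths ≤ 60 agrees with a
  direct enumeration to better than $10^{-13}$.
* At $k = 2$ groups the studentized range is exactly $\sqrt{2}\,|t|$, so
  Tukey p-values use the closed t-form there and the studentized-range
  distribution (`ptukey`) for $k > 2$; zero within-group variance is
  reported as $p = 0$ for distinct means and as "no-test" otherwise.
* ANOVA on zero-variance data is a "no-test" result rather than a number;
  complete separation reports $F = \infty$, $p = 0$, $\eta^2 = 1$.
* PERMANOVA floors residual sums of squares at zero when they vanish to
  rounding (perfectly separated groups would otherwise produce
  noise-signed F ratios), and exact enumeration includes the identity
  permutation in its count.
* PERMDISP keeps real and imaginary principal-coordinate axes separately
  and uses $z_i = \sqrt{\max(0, d^2_{real} - d^2_{imag})}$; on Euclidean
  inputs the correction is a no-op and distances equal vegan's
  `betadisper` to $10^{-8}$.

## Design decisions that were genuinely open

* **Normalization arithmetic.** "Normalized to the control" admits several
  readings; subtraction after rarefying both members to one depth, with a
  zero floor, is the only one consistent with marking control-dominated
  features as zero counts, and it is what `control_normalize()` implements.
* **Which control fraction.** The ¹²C *heavy* fraction is the control,
  because it is sequenced precisely to capture GC-density background; the
  light fraction would measure the wrong thing.
* **Effect size.** Eta-squared, the standard multigroup effect size for
  this kind of per-feature ANOVA report.
* **Sequential sums of squares** in user-given term order for PERMANOVA,
  matching the convention of the widely used implementation; the order is
  recorded in the output.
* **Metagenome rarefaction depth** defaults to the minimum column sum of
  the compared set; amplicon data conventionally use 20,000. Each
  annotation table is rarefied independently.
* **Reporting threshold.** The per-feature report can list features up to a
  configurable `report_p` above `alpha`, but an association is only ever
  assigned at `alpha`.

## Problem sizes used in the test suite

Unit tests run the generator at 60 taxa and 4,000 reads per sample; the
recovery and calibration checks use the preset at 300 taxa and 50,000 reads,
513 null pairs, 500 exchangeable PERMANOVA simulations at $n = 12$, and a
$10^7$-draw Monte-Carlo oracle for the studentized-range quantile. These
sizes give Monte-Carlo standard errors comfortably inside the asserted
bounds while keeping the suite fast.

## Known limitations

* The paired exact test assumes the only variation between a labeled core
  and its control is multinomial sampling. Real replicate cores are
  overdispersed; with strong core-to-core variation the false-positive rate
  rises above nominal, and a replicated design with a hierarchical model
  (or qSIP-style density quantification) would be more appropriate.
* The measured false-positive rate under the null sits near the low edge of
  the nominal level (≈ 0.03 at $\alpha = 0.05$) because the exact test is
  conservative for rare features.
* Binary activity only: no atom-fraction-excess estimation, no
  quantification of *how much* label a taxon incorporated.
* Cores are treated as independent replicates; there is no spatial or
  repeated-measures structure.
* Bray–Curtis on control-normalized abundances inherits compositionality;
  PERMANOVA detects location differences in that compositional space, not
  absolute abundance shifts.
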