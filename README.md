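# cofosnet

Activation patterns and functional connectivity networks from regional
c-Fos counts.

## What this is for

Immediate-early-gene immunohistochemistry gives one activation readout per
brain region per animal: the number of c-Fos-positive cells in a fixed
counting frame. In a 2×2 factorial design — treatment (methamphetamine,
`MA`, vs saline, `SAL`) crossed with circadian phase (`light` vs `dark`)
— such a table supports two complementary analyses, and `cofosnet`
implements both as a reusable, tested pipeline:

1. **Regional activation patterns.** Each region is analysed by two-way
   factorial ANOVA with treatment and time as factors. Regions are then
   classified by which effects are significant at level α:

   | pattern | treatment | time | interaction |
   |---------|-----------|------|-------------|
   | 1 | yes | no | no |
   | 2 | no | yes | no |
   | 3 | yes | any | yes |
   | 4 | yes | yes | no |
   | 5 | no | no | no |

   Remaining combinations (an interaction without a treatment main
   effect) are labelled `other`. Where an interaction is present, the
   four simple-effect contrasts (MA vs SAL within each phase, light vs
   dark within each treatment) are tested on the pooled error term with
   Bonferroni ×4 correction.

2. **Functional connectivity.** Within one experimental group, regional
   counts are correlated across animals; the *connectivity* of region *r*
   is the node strength on the full signed correlation network,

   k_r = Σ_{s≠r} |corr(x_r, x_s)|.

   Two resampling procedures calibrate it:

   - a **permutation null** — every region column's sample order is
     shuffled independently (destroying cross-region alignment,
     preserving marginals) and connectivity recomputed; the observed k_r
     is expressed as a Z-score against this null, with Z > 2 the
     conventional significance criterion;
   - a **bootstrap group comparison** — to test whether k_r differs
     between groups, the pooled animals are repeatedly re-split at random
     into two sets of the original group sizes, the per-region difference
     Δk_r recorded each time, and the observed Δk_r scored as a Z and an
     empirical two-sided p = (1 + #{|null| ≥ |obs|}) / (n_boot + 1).

A synthetic-data module generates factorial count tables through a latent
Gaussian copula (lognormal margins with configurable mean and CV, known
latent inter-regional correlation, optional group-specific hub), so
calibration and recovery of every stage is testable without any animal
data.

## Worked example

```r
library(cofosnet)

# a 40-animal study: 10 mice/treatment/phase, 17 regions, baseline
# inter-regional correlation 0.3, plus a VMH hub (r = 0.7 to PVN, BLA,
# MEA) present only in the MA group
cfg <- cfos_sim_config(
  n_per_cell = 10, dispersion = 0.3, base_r = 0.3,
  hub = list(region = "VMH", partners = c("PVN", "BLA", "MEA"), r = 0.7),
  seed = 42)
tab <- simulate_cfos(cfg)

ap <- activation_patterns(tab)   # per-region ANOVA + classification
summary(ap)
#> $`1`
#> [1] "CEA"  "CA1"  "ILC"  "BNST" "CIN"  "NACc"
#> $`2`
#> [1] "SCN" "VMH"
#> $`3`
#> [1] "PVN" "PVT" "ARC"
#> $`4`
#> [1] "CA3"  "NACs"
#> $`5`
#> [1] "BLA" "MEA" "DG"
#> $other
#> [1] "DMH"
```

The generator's default mean structure plants one of the five patterns in
each region; at n = 10/cell a borderline region (here DMH, a weak time
effect) occasionally lands in a neighbouring category — exactly the
sampling behaviour the classifier is meant to expose.

```r
pn <- permutation_null(tab[tab$treatment == "MA", ], n_perm = 10000,
                       seed = 43)
head(as.data.frame(pn), 3)
#>   region observed null_mean   null_sd        z
#> 1    SCN 7.032036  2.956614 0.5467795 7.453502
#> 2    PVN 7.573193  2.985383 0.5429430 8.449892
#> 3    PVT 6.293940  2.979409 0.5395812 6.142785
```

Observed connectivity (~7 for SCN: the sum of 16 absolute correlations)
sits far above the permutation null (mean ≈ 2.96), giving Z ≫ 2:
coupling this strong does not arise from misaligned samples.

```r
nd <- bootstrap_compare(tab, n_boot = 10000, seed = 44)
as.data.frame(nd)[nd$region == "VMH", c("k_A", "k_B", "delta_k", "z", "p")]
#>         k_A      k_B    delta_k          z        p
#> 12 7.483773 8.005999 -0.5222266 -0.3784022 0.719928
```

With a baseline correlation of 0.3 in both groups, 20 animals per group
resolve a 3-edge hub only occasionally (see the power analysis in the
vignette): here the VMH difference is swamped by the relabelling-null
spread (sd ≈ 1.38), so Δk ≈ −0.5 is unremarkable (p ≈ 0.72).

`run_pipeline()` chains all stages and writes TSV/JSON outputs, GraphML
networks and a reproducibility manifest;
`Rscript inst/scripts/cofosnet-cli.R <simulate|anova|network|compare|all>`
exposes the same stages from a shell.

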