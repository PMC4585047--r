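---
title: "Methods: activation patterns and connectivity inference in cofosnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation patterns and connectivity inference in cofosnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofosnet)
```

# The data and the two questions

The input is a per-animal table: one row per mouse, a treatment factor
(methamphetamine `MA` vs saline `SAL`), a circadian phase factor (`light`
vs `dark`), and one nonnegative activation value per brain region — the
average number of c-Fos-immunopositive cells in a fixed counting frame
(bilateral/section averaging makes non-integer values legitimate). The
reference design is balanced: 10 animals per treatment × phase cell, 40
in total, across 17 regions.

Two questions are asked of such a table. *Within regions*: which
experimental factors drive activation? *Between regions*: which regions
co-activate across animals, and does the drug reorganise that coupling?

# Per-region factorial ANOVA and the pattern taxonomy

`two_way_anova()` fits each region against treatment, phase and their
interaction. Internally the fit uses sum-to-zero contrasts with
Type-III-style tests (`car::Anova(type = 3)`); on a balanced design this
is algebraically identical to the classical two-way decomposition (the
test suite asserts equality against a hand-coded cell-means oracle to
relative error 1e-8), while unbalanced tables — dropped animals are a
fact of life in histology — keep testing the same main-effect hypotheses
instead of silently becoming order-dependent. For the full design the
denominator df is N − 4 = 36.

Regions are then classified by the significance triple (treatment, time,
interaction) at α (default 0.05, configurable):

* pattern 1 — treatment only;
* pattern 2 — time only;
* pattern 3 — treatment effect plus interaction, with or without a time
  effect (the taxonomy's interaction category presumes the drug is doing
  something);
* pattern 4 — both main effects, additive;
* pattern 5 — nothing significant;
* `other` — the combinations the taxonomy does not name (an interaction
  without a treatment main effect). We refuse to force these into a
  neighbouring category: a label that misdescribes the fitted model is
  worse than an explicit "unclassified".

P-values between 0.05 and 0.1 are reported as trend annotations but never
enter classification — borderline regions should be visible, not
reclassified.

Where the interaction matters, `simple_effects()` tests the four
cell-mean contrasts (MA − SAL within each phase; light − dark within each
treatment) as t statistics on the pooled ANOVA error term with its full
residual df. The multiplicity family is exactly these four contrasts, so
the Bonferroni factor is 4; the source analyses report these same four
comparisons but never state a family size, and we regard per-region ×4 as
the defensible reading (correcting across regions as well would conflate
two inferential levels; across-region adjustment is provided separately
in the bootstrap stage as Benjamini–Hochberg).

# Connectivity

Within one group, `correlation_matrix()` correlates regional counts
across animals (Pearson by default; the activation magnitudes are the
quantity of interest, and a Spearman flag guards against outlying counts
when wanted). Pairwise-complete observations are used, and any region
pair with fewer than 3 complete pairs is an error naming the pair.

Connectivity is the unthresholded node strength

$$k_r = \sum_{s \ne r} \lvert \mathrm{corr}(x_r, x_s) \rvert ,$$

so $0 \le k_r \le R - 1$. Display thresholds (`edge_list()`,
GraphML export) never feed back into $k_r$: thresholding before summing
would make the statistic discontinuous in the data and sensitive to an
arbitrary cut.

**Permutation null.** "Shuffling the sample order" is only meaningful
column-wise: permuting whole rows leaves every correlation unchanged. So
each permutation replicate shuffles every region column independently,
which destroys cross-region alignment while preserving each region's
marginal distribution exactly. Z = (observed − null mean)/null sd with
the sample (n−1) sd; the conventional criterion Z > 2 flags connectivity
unlikely under misalignment. The test suite checks this null against
exhaustive enumeration of all independent column permutations on a
4-sample, 3-region instance.

**Group definition.** Light and dark animals are pooled within treatment
before correlating (the default), which doubles the effective n. The cost
is known: a shared time effect inflates correlations between any two
regions that both respond to phase. The `center_phases` flag (default
off, matching the pooled reference analysis) subtracts within-phase
region means first and removes exactly that component; the pipeline test
suite demonstrates the inflation and its removal.

# Bootstrap comparison of group networks

`bootstrap_compare()` tests per-region connectivity differences
Δk_r = k_r(A) − k_r(B) with a group-relabelling null: pool the animals,
re-split at random **without replacement** into sets of the original
group sizes (a with-replacement variant is deliberately not offered — the
procedure being emulated re-splits), rebuild both networks, record Δk_r;
repeat n_boot times. Then Z = (observed − null mean)/null sd and the
empirical two-sided p = (1 + #{|null Δk| ≥ |observed Δk|})/(n_boot + 1),
which can never return 0. Raw per-region p is primary;
Benjamini–Hochberg-adjusted values across the 17 regions are reported
alongside. On a tiny 4+4 instance the Monte-Carlo null is checked against
exhaustive enumeration of all 70 equal-size splits.

Exchangeability is what makes the null exact: under "no treatment effect
on coupling", treatment labels are independent of the data and the
observed split is one draw from the re-split distribution. The type-I
calibration test (200 null datasets, 17 regions, 20 animals/group,
n_boot = 1000) measures the pooled rejection rate at p < 0.05 and finds
it near nominal (the +1 correction and two-sidedness make it mildly
conservative).

**Power at the reference sample size is modest.** With 20 animals/group,
a hub coupled at r = 0.7 to three partners (absent in the other group)
produces an expected Δk of roughly 3 × (0.69 − 0.18) ≈ 1.5 — each hub
edge's attenuated correlation replaces the ≈ 0.18 absolute-noise
correlation a 20-sample null edge carries — against a relabelling-null
spread of ≈ 0.8, i.e. an expected bootstrap Z just under 2. The
acceptance script measures this directly (`hub_bootstrap_z_ge2_rate`,
`hub_max_deltak_rate`, `hub_recovery_rate`): the bootstrap detects such a
hub in a minority of simulated studies, while the *permutation* Z of the
hub within its own group (the Z > 2 criterion) succeeds far more often
(`hub_perm_z_ge2_rate`). This is a property of the procedure at this
sample size, not an implementation artifact: power scales up as expected
when group sizes grow, and the null machinery is validated exhaustively.
Single-study hub conclusions at n = 20/group should therefore lean on the
within-group permutation Z; the bootstrap comparison quantifies, rather
than guarantees, between-group evidence.

# The synthetic-data generator

`simulate_cfos()` exists so that every stage above can be tested for
calibration (nulls behave like nulls) and recovery (planted structure is
found). It emulates:

* the 2×2 factorial mean structure — `pattern_cell_means()` ships one
  preset per activation pattern, with magnitudes (tens of cells per
  frame) typical of immediate-early-gene counts, and
  `default_pattern_map()` assigns each of the 17 regions the pattern it
  exhibits in the reference study;
* overdispersed, right-skewed, nonnegative counts — each animal draws a
  latent multivariate normal vector under its treatment group's latent
  correlation matrix, each coordinate is mapped to a lognormal with mean
  equal to the animal's cell mean and coefficient of variation
  `dispersion`, then rounded. No distributional information about the
  real counts exists, so `dispersion` is an exposed parameter, never a
  constant; the default CV of 0.3 is a typical between-animal spread for
  regional c-Fos counts;
* a latent inter-regional network per group — default baseline
  correlation 0.3 in both groups (most regions in the reference analysis
  are significantly connected, so an uncoupled default would be
  unrealistic);
* an optional treated-group hub (`hub =`), mimicking a drug-specific
  increase in one region's coupling.

The lognormal transform attenuates correlations:
`attenuated_correlation()` gives the closed form
$(e^{\rho s_1 s_2} - 1)/\sqrt{(e^{s_1^2}-1)(e^{s_2^2}-1)}$ with
$s_i^2 = \log(1 + \mathrm{CV}_i^2)$, and the fidelity tests hold realized
correlations to ±0.05 of it at n = 2000 (rounding adds only negligible
further perturbation at realistic means) and realized cell means to 2% at
n = 10^4 per cell.

**Feasibility of hub stars.** A hub correlated at r with p mutually
near-independent partners requires $p\,r^2 \le 1$; r = 0.7 with three
partners violates this, so "hub edges at 0.7, everything else at
baseline" is not a correlation matrix. `latent_correlation()` therefore
keeps partner–partner entries at the baseline when the star is feasible
and otherwise raises them — by bisection — to the smallest value that
restores positive semidefiniteness with a 10⁻³ spectral margin (0.236
for the 0.7/3-partner case; never above r², the value implied by partners
loading fully on the hub's component). Hub–partner edges are always
exact. As a safety net, any remaining non-PSD matrix is repaired by
eigenvalue clipping with diagonal renormalisation, and the repair aborts
if any entry moves by more than 0.05 — a larger repair would silently
simulate a different truth than configured.

**Seeding.** A master seed deterministically derives substreams per
treatment group and per animal, so tables are byte-reproducible and
individual animals are reproducible independently of table size.
Permutation and bootstrap replicates likewise derive one substream per
replicate from their own seed, independent of the generator stream.

**What the generator does not emulate:** image-level data, ROI geometry,
bilateral/section averaging (counts are drawn directly at the
per-animal level), litter or cohort effects, heavier-than-lognormal
tails, and count-specific mean–variance laws (a Poisson component is
negligible at tens of cells but real at very low counts). Passing tests
therefore certify the statistical machinery under a plausible data model,
not the biology of any particular dataset.

# Numerical and interface choices

* Degenerate inputs fail loudly and specifically: empty or
  single-observation design cells name the cell; zero residual variance,
  zero-variance regions, and region pairs with <3 complete pairs name the
  region(s).
* `n_perm`/`n_boot` have a floor of 100 in analysis entry points,
  overridable only via an explicit `unsafe` flag intended for tests.
* The grouping factor's first level is network A throughout, so
  Δk = k(MA) − k(SAL) for the default treatment grouping; swapping labels
  negates Δk and leaves p invariant (tested).
* With `collapse_phases = FALSE` the pipeline builds the four
  treatment × phase networks and runs the bootstrap comparison MA vs SAL
  within each phase — the coherent extension once phases are kept apart.
* The run manifest records inputs, parameters, seeds and package version
  but no wall-clock timestamps, so identical configurations produce
  byte-identical outputs.

# Problem sizes used by the test suite

The suite exercises the full 40-animal, 17-region reference design for
all pipeline-level checks; exactness checks run on deliberately tiny
instances where enumeration is exhaustive (4 samples × 3 regions for the
permutation null — 24³ column permutations; 4+4 animals for the bootstrap
null — 70 splits); calibration and power use 200 and 100 simulated
studies at n_boot = 1000; fidelity uses n = 2000 (correlations) and
n = 10⁴ per cell (means). These sizes were chosen to make Monte-Carlo
error a small fraction of each tolerance while keeping the default test
run fast.

# Known limitations

* Connectivity treats positive and negative coupling identically (|r|);
  a region flipping the sign of all its correlations has Δk = 0.
* Pairwise-complete correlation matrices can be non-PSD under heavy,
  structured missingness; with the near-complete tables this package
  targets the effect is immaterial, and connectivity (a sum of absolute
  entries) does not require PSD.
* The permutation and bootstrap nulls share no variance-reduction tricks
  (no balanced or antithetic designs); at n_perm = n_boot = 10⁴ the
  Monte-Carlo error on Z is already well below interpretive resolution.
* The bootstrap comparison is underpowered for subtle network changes at
  20 animals/group (see the power discussion above); it answers "is the
  difference larger than relabelling noise", not "is the network the
  same".
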