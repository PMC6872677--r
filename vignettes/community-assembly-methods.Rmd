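---
title: "Methods: diversity, distance-decay, and null-model partitioning of community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, distance-decay, and null-model partitioning of community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`intertidr` implements the statistical layer of a coastal microeukaryote
community survey: a site-by-OTU count table, a rooted OTU phylogeny and
per-sample metadata go in; alpha diversity, ordination, matrix-correlation
tests, distance-decay and a per-pair partition of community assembly
processes come out. This vignette records the models, the defaults, and the
design decisions, in that order of importance.

## The two-step null model

The core inference classifies every pair of communities into one of five
assembly processes by comparing observed turnover against two null
distributions.

**Step 1 — phylogenetic turnover.** For samples $x$ and $y$, the
abundance-weighted between-community mean nearest taxon distance is

$$\beta\mathrm{MNTD}(x,y) = \tfrac{1}{2}\Big[
  \sum_{i \in x} f_i^{(x)} \min_{j \in y} d_{ij} +
  \sum_{j \in y} f_j^{(y)} \min_{i \in x} d_{ij} \Big],$$

where $d_{ij}$ is the patristic distance between OTUs $i$ and $j$ and
$f_i^{(x)}$ is OTU $i$'s relative abundance in $x$ (or $1/S$ for the
unweighted variant). A taxon present in both samples contributes zero. The
null model shuffles OTU labels across the tips of the phylogeny — one
shuffle per iteration for the whole table, equivalently a joint
row/column permutation of the patristic matrix — and recomputes
$\beta$MNTD for every pair. The standardised effect size is

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{obs} -
  \overline{\beta\mathrm{MNTD}}_{null}}{\mathrm{sd}(\beta\mathrm{MNTD}_{null})}.$$

$\beta$NTI $> 2$ is read as heterogeneous selection (more phylogenetic
turnover than chance), $\beta$NTI $< -2$ as homogeneous selection. Pairs
with a degenerate null (zero standard deviation, which happens when two
samples have identical membership) are reported `NA` with a warning rather
than silently classified.

**Step 2 — compositional turnover.** Pairs with $|\beta\mathrm{NTI}| \le
2$ are referred to a Bray-Curtis Raup-Crick null. Each null iteration
re-assembles every sample independently from the regional pool: the
sample's observed richness is drawn as taxa sampled with probability
proportional to regional occupancy frequency (each receiving one read),
then filled to the sample's observed read total with probability
proportional to pooled regional relative abundance. The observed
Bray-Curtis value is located in the null distribution:

$$RC_{bray} = 2\left(\frac{\#\{null < obs\} + \tfrac{1}{2}\#\{null =
obs\}}{n_{null}} - \tfrac{1}{2}\right) \in [-1, 1].$$

$RC_{bray} > 0.95$ is dispersal limitation, $RC_{bray} < -0.95$
homogenizing dispersal, and the remainder ecological drift. The $\pm 2$
and $\pm 0.95$ cutoffs are the framework's conventional values and are
exposed as arguments (`bnti_threshold`, `rc_threshold`).

Both null models consume the *rarefied, untransformed* count table: the
Raup-Crick null resamples integer reads, so it must see counts. The
log(x+1) transform applies only to the Bray-Curtis matrices used for
ordination, ANOSIM, Mantel tests and distance-decay.

Choices the framework leaves open, and what this package does:

* $\beta$MNTD is abundance-weighted by default (`weighted = FALSE`
  available). The survey analyses abundance data throughout, so presence
  weighting would discard most of the signal.
* The $\beta$NTI null pool is the whole OTU table passed in (a regional
  null), not per-group subpools.
* The RC null preserves both observed richness and observed read totals;
  a richness-only variant (`fill = "richness_only"`) is available.
* Process fractions are summarised over within-group pairs by default
  (`scope = "all_pairs"` available), matching the per-subgroup
  presentation that motivated the design.

## Surrounding statistics

* **Rarefaction** is a single draw without replacement to a common depth
  (default 13,595 reads, the survey's minimum library size); the seed is
  recorded in the run summary, and rarefied column sums are exact.
* **Shannon** is reported in nats (log base is an argument); **Faith's
  PD** is root-inclusive (the minimal spanning subtree includes the path
  to the root; `include_root = FALSE` switches the convention).
* **Group comparisons** use classic one-way ANOVA for alpha metrics
  (Welch's variant by flag) and Welch t-tests for environmental
  variables. Alpha-environment screens use Spearman's rank correlation
  with Holm correction applied within each metric's family of
  environmental variables; missing values are dropped pairwise and the
  effective n is reported.
* **Ordination** is NMDS (Kruskal stress-1, monotone regression) on
  log-transformed Bray-Curtis, best of 20 random starts, k = 2.
* **ANOSIM, Mantel, partial Mantel** are rank-based with 9,999
  permutations by default; every permutation p-value carries the +1
  correction and can never be exactly zero. The Mantel inner correlation
  defaults to Spearman (Pearson by flag): the surrounding analyses are
  consistently rank-based, and the source framework does not state the
  choice.
* **Geographic distance** defaults to a local equirectangular
  ("Cartesian") projection with Euclidean distances, mirroring the
  field's usage; haversine great-circle distance (R = 6371 km) is the
  alternative. At sub-100 km spans the two agree to well under 1%.
* **Distance-decay** correlates community similarity (1 − Bray-Curtis)
  with geographic distance; its permutation test is one-sided for the
  directional decay hypothesis (negative r). A direction-adaptive test
  would double the type-I rate under the null.
* **Environmental transforms**: square root for every variable except pH
  (already log-scaled by definition); community counts are log(x+1)
  transformed before ordination-layer analyses.

## The synthetic-data generator

The generator emulates the *processed* data layer of an intertidal survey
so that every downstream statistic can be validated by parameter recovery:
13 sites along a 66 km shoreline near 24.5°N 118.1°E, 36 samples (21
planktonic in two size fractions, 15 benthic in two seasons), an OTU pool
of ~500 taxa, and multinomial read sampling at a depth of 13,595.

Each sample's OTU weights combine, per the active regime: regional
log-normal abundances; a Gaussian trait-matching kernel
$\exp(-(t_i - e_s)^2 / 2\sigma_f^2)$ between phylogenetically conserved
niche traits and the site environment; mass-effect mixing between
site-specific drifted pools with weight $e^{-d/\lambda}$; and per-sample
log-normal noise. One synthetic environmental driver controls selection;
the other metadata columns are correlated nuisance variables (AR-1 chain,
correlation 0.3) so Mantel/partial-Mantel discrimination is testable.
Sediment-only variables are missing for water samples, as in real surveys
where different variable sets are measured per habitat.

Design decisions that required iteration, and why they ended where they
did:

* **Tree shape.** `simulate_tree()` produces a two-timescale
  clustered-radiation tree: a Yule backbone with long exponential
  branches carrying ~3-tip radiations with short branches. On a plain
  Yule tree with iid branch lengths, a random subset of 50-100 of a few
  hundred tips is nearly as phylogenetically tight as a clade, which caps
  attainable $|\beta\mathrm{NTI}|$ near 1-2 at this problem size and
  makes homogeneous selection undetectable in principle. The clustered
  shape is also the realistic model of OTU phylogenies — shallow
  radiations of sequence variants separated by deep divergences between
  higher taxa. Nearest-taxon statistics are informative exactly when
  community membership is sparse at the clade level.
* **Selection kernel.** The kernel is truncated at 2.5 widths (hard
  physiological limits), so a lucky abundance draw cannot override a
  strong niche mismatch. Under a spatially uniform environment the
  optimum sits at the densest trait neighbourhood rather than the trait
  median, which can fall in a gap between clades.
* **Drift preset.** Pure drift assembles each sample as a uniform random
  draw from the regional pool (membership at a target occupancy of 0.6,
  abundances refilled multinomially). Uniform membership propensity is
  the fixed point of the Raup-Crick occupancy null: propensities tied to
  abundance saturate for dominant taxa, which the occupancy-frequency
  null cannot reproduce, and the preset would read as homogenizing
  dispersal rather than drift.
* **Homogenizing dispersal preset.** Mass effects maintain a common
  regional abundance ranking while local capacity varies, so communities
  are nested subsets of a shared ranking (per-sample capacity 0.35-0.8 of
  the pool). With exchangeable multinomial sampling alone the RC null
  essentially reproduces the generative process and no pair can fall
  below it; nestedness is the realistic mechanism that makes communities
  *more* similar than random assembly at the same occupancy frequencies.
* **Preset strengths.** Selection presets use kernel width 0.10 trait-SD,
  per-sample noise 2.0-2.5 (species turnover within the favoured clades)
  and a relatively even pool (log-normal sd 0.5); dispersal presets use
  site-level drift sd 2.5 with mixing scales of 6 km (limited) versus
  10^4 km (homogenizing); `mixed` sits between.

What the generator does **not** emulate: sequencing error, chimeras, PCR
bias, taxon-specific copy-number variation, temporal autocorrelation
between seasons, or genuinely two-dimensional coastal geometry. Passing
recovery tests therefore shows the statistics respond correctly to the
ecological forces the generator encodes — not that real intertidal data
are free of these other complications.

## Numerical choices

* Ranks use average ties (the Spearman/ANOSIM standard).
* All permutation p-values use the $(\#\{extreme\} + 1)/(n_{perm} + 1)$
  estimator.
* NMDS: tolerance 1e-7 on stress ratio, max 300 iterations, 20 restarts;
  non-convergence returns the best solution with a warning flag.
* Every random step takes an explicit integer seed; the pipeline derives
  per-stage seeds deterministically from the master seed so stages can be
  re-run independently, and two runs of the same configuration produce
  byte-identical output files.
* Degenerate inputs error early and by name: all-zero samples,
  constant distance matrices, perfectly collinear partial-Mantel
  controls, sub-minimum group sizes.

## Validation scale

The test suite and the acceptance script validate at 36 samples, 300-500
OTUs, read depth 2,000 and 199 null-model iterations (999 permutations for
the type-I calibrations, 500 simulations each). These sizes keep the full
validation battery — five regime-recovery experiments of ten seeds each,
three permutation-test calibrations, and twenty distance-decay recovery
seeds — fast enough to run routinely while leaving every recovered effect
far from its decision threshold. Package defaults remain at the survey
scale (depth 13,595, 9,999 permutations, 999 null iterations).

## Known limitations

* $\beta$NTI loses power when communities share most of their abundance
  (shared taxa contribute zero to $\beta$MNTD in both the observed and
  the null value); near-identical communities are reported `NA`.
* The RC null conditions on observed richness and occupancy, so processes
  that act through richness itself are partially absorbed by the null.
* The drift category is a residual: any process the two nulls cannot
  detect lands there.
* Classification treats pairs independently; no multiple-comparison
  control is applied to the per-pair labels, matching standard practice
  for this framework.
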