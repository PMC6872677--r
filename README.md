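# intertidr

Statistical pipeline for community surveys of intertidal microeukaryotes
(and, generally, any site-by-OTU dataset with a phylogeny and spatial
metadata). It answers the field's standard questions — how diverse are
these communities, how do they differ between habitats, sizes and seasons,
does similarity decay with distance — and its central one: **which
ecological processes assemble these communities?**

That last question is answered with a two-step phylogenetic null model.
For every pair of communities:

1. **βMNTD / βNTI.** The abundance-weighted between-community mean nearest
   taxon distance,
   βMNTD = ½ [ Σᵢ fᵢ(x) minⱼ∈y d(i,j) + Σⱼ fⱼ(y) minᵢ∈x d(j,i) ],
   is compared against a null that shuffles OTU labels across the tips of
   the phylogeny. The standardised deviation βNTI = (obs − mean_null) /
   sd_null flags selection: βNTI > 2 heterogeneous selection, βNTI < −2
   homogeneous selection.
2. **RC_bray.** Remaining pairs are located within a null distribution of
   Bray-Curtis values from communities randomly re-assembled from the
   regional pool (observed richness drawn by occupancy frequency, reads
   refilled by regional abundance). RC_bray > 0.95 indicates dispersal
   limitation, RC_bray < −0.95 homogenizing dispersal, and the remainder
   ecological drift.

Per-group fractions of these five processes are the pipeline's headline
output. Around it the package provides rarefaction, richness / Shannon /
Faith's PD with ANOVA group tests and Holm-corrected Spearman
environmental screens, log(x+1)-transformed Bray-Curtis matrices, NMDS,
ANOSIM, Mantel and partial Mantel tests, geographic distance matrices,
distance-decay tests, environmental PCA and per-variable Welch t-tests —
plus a synthetic-data generator with five assembly-regime presets so each
statistic can be validated by parameter recovery.

## Worked example

Simulate a dispersal-limited survey (13 sites along 66 km of shoreline,
36 samples, 300 OTUs), then run the analysis:

```r
library(intertidr)

cfg    <- scenario_config(regime = "dispersal_limitation",
                          n_taxa = 300, depth = 2000, seed = 42)
bundle <- generate_bundle(cfg)
bundle
#> <synthetic_bundle> 36 samples x 300 OTUs, regime: dispersal_limitation

rare  <- rarefy_counts(bundle$counts, depth = 2000, seed = 1)
alpha <- alpha_table(rare, bundle$tree)
head(alpha, 3)
#> # A tibble: 3 × 4
#>   sample_id  richness shannon faith_pd
#>   <chr>         <int>   <dbl>    <dbl>
#> 1 WMI_S01_01      113    2.00     871.
#> 2 WMI_S02_02      148    3.57    1008.
#> 3 WMI_S04_03      173    4.13    1023.

comm <- bray_curtis(transform_community(rare))
anosim_test(comm, bundle$meta$habitat, n_perm = 999, seed = 1)
#> ANOSIM: statistic = -0.0386, p = 0.819 (999 permutations, n = 36)

geo <- geo_distance_matrix(bundle$meta)
distance_decay(comm, geo, n_perm = 999, seed = 1)
#> distance-decay (Spearman): statistic = -0.9138, p = 0.001 (999 permutations, n = 36)

res <- run_assembly(rare, bundle$tree, bundle$meta, n_null = 199, seed = 1)
res
#> <assembly_result> 630 pairs, 199 null iterations; 0 NA pair(s)
#>   heterogeneous_selection     33  (5.2%)
#>   homogeneous_selection        0  (0.0%)
#>   dispersal_limitation       496  (78.7%)
#>   homogenizing_dispersal      15  (2.4%)
#>   drift                       86  (13.7%)
```

Reading the output: habitats do not differ (ANOSIM R ≈ 0 — this regime
applies no selection), community similarity declines steeply with
distance (Spearman r = −0.91, p = 0.001), and the classifier attributes
most pairwise turnover to dispersal limitation — the process that
generated the data. `autoplot(res)` draws the stacked process-fraction
bars; `tidy(res)` returns the per-pair table.

The same analysis runs end-to-end from files
(`run_pipeline(list(otu_table = ..., tree = ..., metadata = ...,
out_dir = ...))`), writing every result table as TSV plus a JSON run
summary, and is also exposed as a thin command line at
`inst/cli/intertidr.R` with `generate` and `run` subcommands.

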