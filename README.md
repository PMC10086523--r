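# chromarch

Two-condition comparison of hierarchical chromatin architecture from
binned Hi-C contact maps and single-cell multiome data, with a
synthetic-data generator that makes every stage testable at desk scale.

Chromatin is organized hierarchically: megabase-scale A/B compartments,
sub-megabase topologically associated domains (TADs), focal loops between
anchor pairs, and — at single-cell resolution — networks of co-accessible
regulatory sites wired to the genes they regulate. Studies of aging and
differentiation repeatedly find that the global levels are static while
the local levels rewire; quantifying that claim requires a consistent
statistical toolkit across all levels and two conditions (e.g. young
versus aged stem cells). `chromarch` provides that toolkit in R:

- **Balancing and expectation** — Knight–Ruiz matrix scaling
  (`kr_balance`), per-diagonal expected profiles and observed/expected
  maps.
- **Compartments** — A/B calls from the leading eigenvector of the O/E
  Pearson correlation matrix, sign-oriented by GC content
  (`call_compartments`); switch fractions between conditions
  (`compartment_switches`); saddle plots and compartment strength
  (mean within-compartment over between-compartment O/E in the
  eigenvector-quantile corners, `saddle`).
- **TADs** — multi-window diamond separation scores with rank-sum boundary
  significance (`tad_separation_score`, `find_boundaries`,
  `assemble_domains`); boundary stability (stable / lost / gained,
  `match_boundaries`); rearrangement classes (stable / shift / split /
  merge / indeterminate, `classify_rearrangements`); intra-TAD
  connectivity (`intra_tad_connectivity`); degree of disorder — the mean
  k-nearest-neighbor distance among a TAD's top O/E pixels
  (`degree_of_disorder`).
- **Loops** — donut-filter focal peak calling with Poisson tails and
  global BH across tested pixels (`call_loops`), aggregate peak analysis
  with the center-over-lower-left-corner score (`apa`), loop/TAD
  containment (`classify_loops_vs_tads`) and cross-condition matching
  (`match_loops`).
- **Co-accessibility networks** — CCAN detection by Louvain communities
  over thresholded site pairs (`detect_ccans`, `select_ccan_cutoff`),
  maximum-weight bipartite matching of CCANs across conditions
  (`match_ccans`), containment in loops/TADs (`ccan_containment`), and
  distance-binned within-TAD fold enrichment against a 500-shuffle
  distance-preserving null (`tad_enrichment_by_distance`).
- **Peak-to-gene linkages** — condition-pure low-overlap cell aggregates
  (`make_aggregates`, k = 40 cells, median shared cells 0, mean shared
  fraction ≤ 0.10), aggregate-level co-accessibility scores
  (`coaccessibility_scores`), pooled-aggregate Pearson linkage tests
  retained at correlation > 0.45 and BH FDR < 1e-4 (`peak_to_gene`),
  k-means clustering of linkage profiles (`cluster_linkages`), and the
  mean fraction of co-accessible peak pairs per linked gene
  (`linkage_coaccess_fraction`).
- **Synthetic data** — `simulate_contact_map` (Poisson counts around a
  power-law decay with planted compartments/TADs/loops),
  `simulate_multiome` (latent-factor two-condition cell-by-peak /
  cell-by-gene matrices with planted linkages and communities),
  `simulate_site_pairs` / `simulate_random_pairs` /
  `simulate_coaccess_pairs` — each emitting its ground truth.

The methods vignette (`vignettes/chromatin-architecture.Rmd`) documents
the model behind each statistic, every tunable parameter with its default
and rationale, and the design choices made where conventions diverge.

## Worked example

Simulate a young map under the default study conditions and an aged map in
which one TAD boundary is lost (two TADs merge), then run the comparison:

```r
library(chromarch)

## global architecture: identical planted compartments in both conditions
young <- simulate_contact_map(hic_sim_params(depth = 4e6, seed = 1))
aged  <- simulate_contact_map(hic_sim_params(depth = 4e6, seed = 2))
ym <- kr_balance(young$map)
am <- kr_balance(aged$map)
ycomp <- call_compartments(ym, young$gc)
acomp <- call_compartments(am, aged$gc)
sw <- compartment_switches(ycomp, acomp)
round(sw$fractions, 3)
#>  A->A  A->B  B->A  B->B
#> 0.494 0.006 0.008 0.492
sw$switch_fraction
#> [1] 0.014
oe <- observed_over_expected(ym, expected_by_distance(ym))
round(saddle(oe, ycomp)$strength, 2)
#> [1] 1.64
```

Under identical planted compartments, only 1.4% of bins apparently switch
(estimation noise at block edges) — global architecture reads as static,
with a compartment strength of 1.64 at `c_comp = 1.5`.

```r
## local architecture: the aged condition merges two TADs
ty <- simulate_contact_map(hic_sim_params(c_comp = 1, depth = 4e6, seed = 3))
ta <- simulate_contact_map(hic_sim_params(
  c_comp = 1, depth = 4e6, seed = 4,
  tad_boundaries = c(45, 85, 140, 250, 290, 340, 395, 440)))
tym <- kr_balance(ty$map); tam <- kr_balance(ta$map)
ytad <- assemble_domains(find_boundaries(tad_separation_score(tym)), tym$grid)
atad <- assemble_domains(find_boundaries(tad_separation_score(tam)), tam$grid)
classify_rearrangements(ytad, atad)$summary
#>       stable shift split merge indeterminate
#> cond1      8     0     0     2             0
#> cond2      8     0     0     1             0
```

The two young TADs flanking the removed boundary are classified as a
merge into one aged TAD; all other domains are stable.

```r
## loops: calling, aggregate enrichment, TAD containment
cfg <- loop_config(resolutions = 40000, loop_fdr = 0.1, peak_widths = 2,
                   windows = 5, min_dists = 80000, merge_dists = 40000)
yloop <- call_loops(tym, cfg)
yloop
#> <loop_call> 23 merged loops (40000 bp: 23)
apa(tym, yloop$loops, W = 10)
#> <apa_result> 18 loops, APA score 7.081
round(attr(classify_loops_vs_tads(yloop$loops, ytad), "fractions"), 2)
#>        within-TAD         cross-TAD boundary-anchored
#>              0.91              0.04              0.04
```

The 20 planted loops are recovered (plus jitter duplicates at cluster
edges), the aggregate peak analysis shows a 7-fold central enrichment,
and 91% of called loops are constrained within single TADs.

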