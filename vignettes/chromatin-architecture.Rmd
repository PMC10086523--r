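---
title: "Comparing hierarchical chromatin architecture between two conditions"
author: "chromarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing hierarchical chromatin architecture between two conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromarch)
```

## Scope and data model

`chromarch` compares the hierarchy of chromatin organization — A/B
compartments, topologically associated domains (TADs), focal loops, and
single-cell co-accessibility structure — between two biological conditions,
the archetype being young versus aged stem cells. Inputs are binned
intra-chromosomal Hi-C contact matrices (COO triplet text), per-bin signal
tracks (bedGraph), interval sets (BED/BEDPE), scored co-accessible site
pairs (TSV), and sparse cell-by-peak / cell-by-gene matrices (MatrixMarket)
with a two-condition label file. All coordinates are 0-based and half-open
(BED convention); bin `i` covers `[i * resolution, (i + 1) * resolution)`
and positions map to bins by `floor(pos / resolution)`. Only cis
(intra-chromosomal) contacts are modeled: every statistic in scope is
cis-only, so inter-chromosomal input is out of the data model entirely.

Because real two-condition Hi-C / multiome datasets are far beyond desk
scale, the package ships a first-class synthetic-data module that plants
known structure and emits the corresponding truth, so every stage has a
recovery or calibration test. The design intent is that all claims made by
the test suite are claims about this generative model, not about any
particular tissue.

## The synthetic generators

**Contact maps.** The expected count at pixel $(i, j)$ is multiplicative
over features:

$$\lambda(i,j) \;=\; Z\,(1 + |i-j|)^{-\alpha}\;
c_\text{comp}^{[\ell_i = \ell_j]}\;
c_\text{tad}^{[\text{same TAD}]}\;
c_\text{loop}^{[\text{loop peak}]},$$

with $Z$ chosen so the expected upper-triangle total equals the requested
depth, and observed counts drawn Poisson. This is the simplest generative
form that reproduces the checkerboard (compartment), block (TAD) and focal
(loop) patterns that the downstream statistics assume. The fixed default
conditions are one 20 Mb chromosome at 40 kb (500 bins), decay exponent
$\alpha = 1$ (the classic fractal-globule regime), ten alternating
compartment blocks with $c_\text{comp} = 1.5$, ten TADs with
$c_\text{tad} = 3$ whose interior boundaries (bins 45, 85, 140, 190, 250,
290, 340, 395, 440) deliberately avoid compartment block edges so the two
structures remain statistically separable, twenty single-pixel loops with
$c_\text{loop} = 6$ placed inside TADs at 10–30 bin separations, and a
read depth of $10^6$ — a realistic per-chromosome cis depth for a pooled
in situ Hi-C library. A GC track is emitted with A bins centered at 0.46
and B bins at 0.40 so the compartment sign-orientation rule is testable.

**Multiome.** Each cell carries a latent state $z \sim U(-2, 2)$, a smooth
continuum shared by both conditions. A planted peak–gene linkage with
latent correlation $\rho$ gives the peak logit
$u = \sqrt{\rho}\,z + \sqrt{1-\rho}\,\varepsilon_1$ and the gene log-rate
$v = \sqrt{\rho}\,z + \sqrt{1-\rho}\,\varepsilon_2$, so
$\mathrm{cor}(u, v) = \rho$ exactly; accessibility is Bernoulli in
`plogis(-0.5 + 1.5 u)` and expression Poisson in `exp(0.3 + 0.8 v)`,
matching the binary sparsity of scATAC and the count nature of scRNA.
Condition-specific links load on $z$ only in their condition. Planted
co-accessibility communities share a per-community factor. Defaults: 500
cells per condition, 200 peaks at 8 kb spacing, 100 genes, 25 shared links
at $\rho = 0.8$, 5 young- and 5 aged-specific links, 10 null links
($\rho = 0$), and 5 distance-negative links whose TSS sits beyond the
500 kb search window.

One consequence worth stating plainly: because all planted links load on a
*single* latent program, peaks and genes from *different* links are also
genuinely correlated (at $\rho$), so the linkage stage legitimately retains
cross-pairs beyond the planted list. Recovery is therefore measured as
recall of planted links together with the behavior of the $\rho = 0$,
all-null and distance-negative controls — not as precision against the
planted list, which would be the wrong oracle under this model.

What the generators do **not** emulate: mappability and duplication
artifacts, restriction-fragment geometry, batch effects, doublets, trans
contacts, copy-number variation, or nested/hierarchical TADs. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to these real-data complications.

## Matrix balancing and the expected model

`kr_balance()` computes weights $w$ with
$b(i,j) = w_i\, c(i,j)\, w_j$ and every unmasked row of $b$ summing to 1.
Rows with fewer than 10% non-zero pixels are masked first (a standard
sparsity filter; balancing diverges on near-empty rows). The solver is a
Newton-type inner–outer iteration with conjugate-gradient inner solves —
the algorithm Hi-C pipelines describe as Knight–Ruiz scaling — with a
damped symmetric Sinkhorn fixed point
($x \leftarrow \sqrt{x / (Ax)}$) as fallback. Tolerance is $10^{-8}$ on
the row-sum residual and the default iteration cap is 1000; at the 500-bin
scale the Newton iteration converges in a handful of outer steps and the
result is bit-stable. The test oracle is an independent alternating
row/column Sinkhorn–Knopp iteration: for symmetric input both must reach
the same doubly-stochastic scaling.

`expected_by_distance()` averages balanced values per diagonal over
unmasked pixels (zeros included); `observed_over_expected()` divides by
that profile, returning missing (never infinite) values where the
expectation is zero or missing. By construction every non-empty O/E
diagonal has mean 1, which the suite verifies numerically.

## Compartments

Per chromosome, the Pearson correlation matrix of the O/E rows is formed
and its eigenvector of largest algebraic eigenvalue taken (not a PCA of
the O/E matrix — the two differ by centering). The sign is oriented so
that positive-eigenvector bins have mean GC at least that of negative
bins, the standard A-compartment convention; the mean is unweighted
(bin counts are constant on a fixed grid, so weighting would only matter
for truncated terminal bins). Bins are labeled A where the eigenvector is
positive, B where negative; chromosomes with fewer than 10 informative
bins are skipped. Rows with zero variance (no compartment signal) are
treated as masked.

`compartment_switches()` reports the four transition fractions over bins
labeled in both conditions; masked bins are excluded from the denominator.
`saddle()` ranks labeled bins into `n_quantiles` (default 50)
equal-occupancy groups by eigenvector value and averages O/E over pixel
pairs per group pair. Compartment strength is
$(\overline{AA} + \overline{BB}) / (\overline{AB} + \overline{BA})$ over
the extreme 20% corner blocks. The corner fraction is a convention fixed
here for reproducibility — there is no universally agreed numeric
definition of "strength" — and on an analytic block O/E of 2.0 within /
0.5 between it gives exactly 4, which the suite asserts.

## TADs

The **separation score** at bin $i$ is the multi-window z-score of diamond
means: for window $w$, the mean balanced value over
$\{(a,b): i-w \le a < i \le b < i+w\}$, z-scored along the chromosome and
averaged over windows $\{4, 6, 8, 10\}$ bins at 40 kb. The window set is
fixed (the multi-scale idea behind insulation-based TAD callers) so the
score is reproducible. Each bin's boundary p-value is a one-sided
rank-sum test of its pooled diamond pixels against the pooled diamonds at
$i \pm w$; boundaries are local score minima with BH-adjusted p-value
(adjusted over candidate minima genome-wide) below the FDR threshold
(default 0.01) and a score drop of at least 0.01 versus both flanking
maxima. Domains tile between consecutive boundaries; spans under 3 bins
are dropped.

Cross-condition **boundary matching** is greedy mutual-nearest within a
1-bin tolerance, ties resolved toward the leftmost boundary so the result
is deterministic; unmatched boundaries are lost (young-only) or gained
(aged-only). **Rearrangement classification** builds the overlap graph
between the two domain tilings and labels each connected component:
1↔1 within tolerance → stable, 1↔1 beyond → shift, 1↔many → split,
many↔1 → merge, anything else → indeterminate. The taxonomy is symmetric:
splits become merges when the conditions are exchanged, which is tested on
random tilings.

**Intra-TAD connectivity** is the mean raw count per intra-TAD pixel
divided by the total raw count of interactions with the immediately
flanking TADs. The denominator wording ("as a fraction of reads") is
genuinely ambiguous between a summed and a per-pixel-mean normalization;
the sum is the default and the mean is available via
`inter_mode = "mean"`. Both are invariant to uniform count scaling.

**Degree of disorder** selects, within each TAD, the pixels whose O/E is
at or above the `top` (default 0.7) empirical quantile and averages each
significant pixel's mean Euclidean distance (bin units) to its `k = 3`
nearest significant peers. The reference implementation of this statistic
has additional internal parameters (`ww`, `pw`, `ratio`, `gap`); they are
accepted for interface compatibility and reported as unused, because
their semantics are not defined by the statistic itself. Fewer than
`k + 1` significant pixels yields a missing value, never an error.

## Loops

`call_loops()` is a donut-filter caller. For each resolution, candidate
pixels (upper triangle, beyond the minimum diagonal distance, observed
above the distance-decay expectation) are tested against the maximum of
four local background estimators — donut annulus between the peak radius
`p` and window `i`, horizontal and vertical stripes, and the lower-left
quadrant — each computed by scaling the pixel's decay expectation by the
neighborhood's observed/expected ratio, via integral-image rectangle sums.
P-values are Poisson upper tails; multiplicity is controlled by global
Benjamini–Hochberg over all tested pixels rather than by
lambda-chunking, which is an implementation detail of the GPU caller this
emulates — global BH is conservative and easy to verify against the
Poisson null. Significant pixels are clustered by 8-connectivity, each
cluster reporting its centroid pixel and the statistics of its strongest
pixel. Post-hoc filters mirror the conventional threshold quadruple
(default `0.02, 1.5, 1.75, 2`): q-value at most 0.02 and
observed/expected at least 1.5 (both stripes), 1.75 (donut) and 2
(lower-left). Calls are merged across resolutions preferring the finest
call within the per-resolution merge radius. Restricting candidates to
O/E > 1 bounds the test count without affecting recoverable peaks (a
called loop must exceed its local background several-fold anyway).

`apa()` averages mean-1-normalized O/E submatrices
($21 \times 21$ by default) centered on loop pixels and scores the center
over the mean of the $6 \times 6$ lower-left corner block — the corner
closer to the diagonal, whose background is highest, making the score
conservative. The corner size follows the aggregate-analysis convention;
the defining sentence of the score does not pin it down numerically.
Loops closer than the window allows are skipped; zero eligible loops is
an error.

`classify_loops_vs_tads()` calls a loop within-TAD when both anchor
midpoints fall in one TAD, else boundary-anchored when an anchor midpoint
lies within one bin of a boundary, else cross-TAD. `match_loops()` pairs
loops whose two anchors agree within tolerance, greedy mutual-nearest and
one-to-one, labeling stable / lost / gained.

## Co-accessibility networks

`detect_ccans()` thresholds site pairs at the co-accessibility cutoff
(default 0.1), builds the site graph, and runs Louvain community detection
(resolution 1.0) under a fixed seed; vertices are name-sorted first so
the result is invariant to input row order. Communities of at least 3
sites become CCANs. `select_ccan_cutoff()` scans candidate cutoffs and
returns the one maximizing the summed CCAN count over both conditions,
ties to the smallest — the same joint-maximization rule used to justify
the 0.1 default. `match_ccans()` weights young–aged CCAN pairs by shared
site count and computes a maximum-weight bipartite matching; the shared
fraction is Jaccard ($|\cap| / |\cup|$) by default because it is
symmetric and condition-order invariant (a per-side mean is available).
Matching optimality is verified against exhaustive enumeration on
hundreds of small random instances.

The upstream co-accessibility *estimation* on real data (a graphical-lasso
model in the established single-cell tool) is intentionally not
reproduced; scores arrive from file or from the simplified
aggregate-correlation estimator in the linkages module. The network,
matching and enrichment layers are the contribution here.

**Within-TAD enrichment.** Pairs are binned by inter-site distance in
25 kb bins; per bin the fold enrichment is (pairs within one TAD) /
(pairs spanning TADs), with a zero denominator flagged infinite rather
than erroring, and bins under 5 pairs flagged low-n. The null re-assigns
links among sites within each (bin, chromosome) stratum by permuting the
signed pair offsets across the stratum's upstream anchors: every null
link still starts at a real site and the bin's distance distribution is
retained exactly. The design alternative — re-pairing arbitrary site
endpoints — destroys the distance structure that defines the bin, which
makes the observed value incomparable to its null (its calibration fails
even under TAD-indifferent placement); the offset-permutation scheme is
calibrated, which the suite checks by requiring the observed FE to fall
inside the central 95% of its own 500-shuffle null in at least 90% of
TAD-indifferent replicates.

## Aggregation and peak-to-gene linkages

`make_aggregates()` embeds one condition's cells in the top 10 principal
directions of the log-scaled accessibility matrix and grows aggregates as
the `k = 40` nearest neighbors of randomly ordered seed cells, accepting
greedily while the running constraints hold: median pairwise shared-cell
count 0 and mean pairwise shared fraction at most 0.10. These are
exactly the constraints under which `k` was chosen in the motivating
analysis; condition purity is structural (cells are drawn from one
condition's pool only) and asserted in the tests by exhaustive pairwise
intersection. Any smooth embedding suffices for the neighbor search — the
constraint checks are representation-independent — so plain PCA replaces
the LSI embedding a full single-cell pipeline would provide.

`peak_to_gene()` pools both conditions' aggregates (the pooled test is
what lets age-specific loading express itself as correlation while using
every aggregate; a per-condition analysis can be run by passing the same
condition twice), total-count normalizes and log1p-transforms expression,
and computes the Pearson correlation between peak accessibility and gene
expression for every pair within 500 kb of the TSS. P-values come from
the correlation t statistic; BH adjustment is genome-wide over all tested
pairs; a linkage is retained when correlation > 0.45 and FDR < 1e-4.
Accessibility enters as raw member sums, so results are exactly invariant
to a global scaling of counts and to aggregate order. `cluster_linkages()`
k-means the concatenated, separately row-standardized accessibility and
expression aggregate profiles into 5 clusters (fixed seed, 10 restarts).
`linkage_coaccess_fraction()` reports, per gene with at least two linked
peaks, the fraction of its linked-peak pairs present in the co-accessible
set, averaged over genes — one defensible reading of "sites within the
average linkage that are co-accessible with each other"; the denominator
of that statistic is not otherwise defined.

## Problem sizes, determinism, and limitations

The test and acceptance runs use the generator defaults (500 bins; 500
cells per condition) for recovery checks, 250-bin maps for the 20-replicate
loop null, and 200-cell / 20-cell-aggregate datasets for the 20-replicate
all-null linkage calibration — sizes chosen so the whole suite exercises
every stage end-to-end in minutes on one core while leaving each statistic
comfortably powered. All stochastic stages (simulation, Louvain, k-means,
aggregation, permutation nulls) take explicit seeds and restore the
caller's RNG state (`withr::with_seed`), and the suite asserts
byte-identical reruns.

Known limitations: single-resolution analysis per stage (no multi-scale
TAD nesting); dense per-chromosome matrices internally, appropriate to
desk-scale chromosomes (hundreds to a few thousand bins) rather than
whole mammalian genomes at 5 kb; the boundary rank-sum test treats diamond
pixels as exchangeable, which is approximate under strong distance decay
(the z-score minimum, not the p-value, carries most of the localization
signal); Louvain modularity has a resolution limit, so very small or very
weakly connected communities below the cutoff graph's density may merge;
and the aggregate-overlap constraints can be unsatisfiable for small cell
numbers with large `k`, in which case the error reports the achieved
overlap rather than silently relaxing the constraint.
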