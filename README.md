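# nucleoscape

Quantifying chromatin accessibility and the nucleosome landscape at
CpG-island (CGI) promoters from ATAC-style fragment coordinates, with a
focus on promoters bound by Polycomb repressive complexes.

ATAC-seq fragments carry two signals at once: how often the transposase
cut (accessibility) and what it cut around (fragment size reflects
nucleosomal structure). `nucleoscape` separates these readouts for a set
of CGI promoters classified by Polycomb occupancy, so that questions like
*"does losing PRC1 change nucleosome occupancy without changing
accessibility?"* can be answered quantitatively. It is aimed at
epigenomics analysts who already have aligned fragment coordinates
(BED-like `chrom start end`) and promoter/peak annotations, and at method
developers who want a fully seeded synthetic benchmark with recorded
ground truth.

## What it computes

**Promoter classification.** TSS windows (TSS ± 500 bp by default) are
labelled `PcG` when they overlap at least one peak from each of a PRC1
subunit (RNF2) and a PRC2 subunit (SUZ12) ChIP peak set *and* a CGI,
`nonPcG` when they overlap a CGI only, `excluded` otherwise. All
coordinates are 0-based half-open throughout.

**Fragment processing.** Coordinate-duplicate removal, blacklist
filtering by fragment midpoint, seeded downsampling, and a size split
into nucleosome-free (< 120 bp) and mononucleosomal (150–250 bp) classes.

**Nucleosome model.** For mononucleosomal fragments the midpoint
estimates the nucleosome dyad. A truncated-Gaussian kernel density of
midpoints (sd σ = 20 bp, unit mass per fragment) gives the dyad density
*d*<sub>mono</sub>(x); occupancy is its share of the all-fragment
density,

    occ(x) = d_mono(x) / (d_all(x) + ε),  ε = 10⁻³,  occ ∈ [0, 1].

Dyads are called at strict local maxima of `occ` (score ≥ 0.1), accepted
greedily in descending score order with ≥ 120 bp separation. Per
promoter the package reports: median fragment size, fragments-per-kb-per
million (RPKM), summed occupancy per kb over the CGI, the median
nearest-neighbour inter-dyad distance (the spacing statistic, tracking
the nucleosome repeat length, NRL), and median fuzziness (the standard
deviation of mono midpoints within ± 73 bp of a called dyad).

**Condition deltas and statistics.** Per-promoter `cond2 − cond1` deltas
(log2 fold change with pseudocount for occupancy), two-sided rank-sum
tests between promoter classes (exact enumeration for n ≤ 12, normal
approximation with tie/continuity correction otherwise),
Benjamini–Hochberg FDR, and FDR < 0.05 plus fold-change > 1.5 significance
calls.

**Synthetic data.** `simulate_experiment()` generates a two-class
promoter cohort on a synthetic chromosome: phased nucleosome arrays
around a TSS nucleosome-free region, with per-class NRL, occupancy
probability, positional jitter, and nucleosome-free fragment content,
plus peak/CGI files constructed so classification recovers the classes
exactly, and a ground-truth table. `simulate_knockout()` derives a
perturbed condition (occupancy × factor, NRL + Δ) for the bound class
only, emulating a PRC1-null experiment.

## Worked example

```r
library(nucleoscape)

sim <- simulate_experiment(n_per_class = 20, seed = 42)
windows   <- make_tss_windows(sim$tss_table, flank = 500)
promoters <- classify_promoters(windows, sim$rnf2_peaks,
                                sim$suz12_peaks, sim$cgi_intervals)
table(promoters$label)
#> nonPcG    PcG
#>     20     20

land <- landscape_from_fragments(sim$fragments, promoters)
aggregate(cbind(median_fragment_size, occupancy_per_kb,
                median_inter_dyad, median_fuzziness) ~ label, land, median)
#>    label median_fragment_size occupancy_per_kb median_inter_dyad median_fuzziness
#> 1 nonPcG                  169         524.5842               193         11.35197
#> 2    PcG                  181         864.5976               170         23.85054
```

The class medians recover the generator's contrasts: the PcG-like class
(true NRL 175 bp, occupancy 0.9, jitter 25 bp) shows larger fragment
sizes, higher occupancy, closer spacing and fuzzier positioning than the
active-like class (NRL 195 bp, occupancy 0.6, jitter 12 bp).

A PRC1-null-like second condition (occupancy × 0.5, NRL + 20 bp, bound
class only):

```r
ko    <- simulate_knockout(params_pcg_like(), 0.5, 20)
sim2  <- simulate_experiment(ko, params_active_like(),
                             n_per_class = 20, seed = 43)
land2 <- landscape_from_fragments(sim2$fragments, promoters)
d     <- condition_delta(land, land2)
aggregate(cbind(log2fc_occupancy, delta_inter_dyad,
                delta_median_fragment_size) ~ label, d, median)
#>    label log2fc_occupancy delta_inter_dyad delta_median_fragment_size
#> 1 nonPcG     -0.009630242            -0.50                       -0.5
#> 2    PcG     -0.262262865            17.25                       -1.0
```

Only the perturbed class moves: occupancy falls, inter-dyad spacing
widens by ~17 bp, fragment sizes shift toward the nucleosome-free range,
while the untouched class stays at zero. `run_pipeline()` wraps this
whole flow and writes all tables plus a JSON manifest.

Stable output column orders: landscape tables are
`promoter_id, label, n_fragments, median_fragment_size, rpkm,
occupancy_per_kb, n_calls, median_inter_dyad, median_fuzziness`; delta
tables are `promoter_id, label, delta_median_fragment_size,
log2fc_occupancy, delta_inter_dyad, delta_fuzziness, log2fc_rpkm`.

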