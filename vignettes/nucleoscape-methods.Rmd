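---
title: "Methods: nucleosome landscape quantification from ATAC fragments"
author: "nucleoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome landscape quantification from ATAC fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoscape)
```

## Scope and rationale

ATAC-seq tags accessible DNA with a transposase and reads out fragment
coordinates. Beyond the raw cut frequency (accessibility), the fragment
*size distribution* is structured: sub-nucleosomal fragments (here
< 120 bp) come from protein-free DNA, while fragments spanning one
nucleosome (150–250 bp) are protected at their centre by the histone
octamer, so their midpoints cluster at nucleosome dyads. `nucleoscape`
exploits this to quantify, per CpG-island (CGI) promoter, both
accessibility and three nucleosome-landscape features — occupancy,
spacing, and positional fuzziness — and their changes between
conditions. The motivating application is Polycomb biology: promoters
bound by both PRC1 and PRC2 in stem cells are less accessible and more
nucleosome-dense than active promoters, and loss of PRC1 perturbs the
nucleosome features while leaving accessibility essentially unchanged.
The package's statistics are designed to resolve exactly that
dissociation.

## Coordinate and assignment conventions

All intervals are 0-based half-open (BED convention), including TSS
positions in TSV input; a single convention end to end avoids
off-by-one drift across BED/bedGraph I/O. "Overlap" always means at
least one shared base pair. A fragment belongs to an interval when its
midpoint, `floor((start + end) / 2)`, lies inside it — each fragment
then counts toward at most one of a set of disjoint promoters, so
counts never double across adjacent CGIs. Whether a study uses
any-overlap or midpoint assignment is rarely material at CGI scale, but
midpoint assignment is the only choice that makes per-promoter counts
additive; we use it everywhere, including RPKM. A window overlapping
several CGIs is assigned the CGI with the largest intersection,
leftmost on ties, deterministically.

## Promoter classification

A TSS window (default flank 500 bp each side, symmetric regardless of
strand) is `PcG` when it overlaps at least one peak in *each* of two
repressive-complex subunit peak sets — requiring both a PRC1 and a PRC2
mark avoids single-complex or spurious peaks — and overlaps a CGI;
`nonPcG` with a CGI but without dual peaks; `excluded` without a CGI.
The three labels always partition the TSS set. The CGI restriction can
be disabled (`require_cgi = FALSE`) to measure how often dual-bound
promoters co-occur with CGIs before restricting (`cgi_fraction()`); in
real stem-cell annotations this fraction is close to 100%, which is why
subsequent promoter analyses are CGI-based. We treat "TSS within a CGI"
as window–CGI overlap rather than strict containment of the TSS point;
the two differ only for TSSs a few hundred bp outside a CGI edge, and
overlap is the more permissive, annotation-robust reading.

## The kernel occupancy model

NucleoATAC-style tools infer occupancy from a model of the fragment
size/position distribution. `nucleoscape` instead uses a transparent
kernel surrogate whose contract is directional and ordinal, not
numerical equivalence with any external tool:

1. **Dyad density.** Each mononucleosomal fragment contributes a
   Gaussian kernel (sd `bandwidth_sd` = 20 bp) centred at its midpoint,
   truncated at ±3σ and renormalised to unit mass, evaluated per bp.
   Mass conservation (integral = fragment count for interior fragments,
   to 1e-6 per fragment) is a tested invariant. 20 bp matches the
   positional uncertainty of a single mono-fragment midpoint around the
   true dyad and smooths without merging neighbouring nucleosomes at
   typical repeat lengths (≥ 147 bp).
2. **Occupancy.** `occ = d_mono / (d_all + ε)` with ε = 1e-3 per-bp
   density units, clipped to [0, 1]. The denominator uses *all*
   fragments, so occupancy is the local probability that tagmented DNA
   was nucleosomal — it is deliberately normalised for total coverage,
   i.e. independent of accessibility, which is what lets occupancy and
   accessibility dissociate. ε only stabilises empty positions (a
   single fragment's peak density is ≈ 0.02, 20 × ε).
3. **Dyad calls.** Strict local maxima of `occ` with score ≥ 0.1
   (plateaus take the leftmost bp), accepted greedily in descending
   score order subject to ≥ 120 bp pairwise separation — just under the
   147 bp footprint, so overlapping nucleosomes are never called while
   closely spaced genuine dyads survive. Greedy descending acceptance
   with leftmost tie-break makes calling fully deterministic.
4. **Fuzziness.** Population sd of mono midpoints within ±73 bp (half
   the nucleosome footprint) of a call; at least two midpoints are
   required, otherwise missing.
5. **Spacing.** Within each CGI, every called dyad's distance to its
   nearest neighbouring dyad *in the same CGI* (no cross-CGI
   neighbours), summarised by the median. Nearest-neighbour is the
   default because it is what "distance to the closest dyad" means; a
   consecutive-pair mode is available (`mode = "consecutive"`) and
   gives the same answer on regular arrays.

Per promoter, occupancy is additionally summarised as the summed
per-bp occupancy over the CGI divided by its length in kb
(`occupancy_per_kb`). The analysis region is padded by 200 bp beyond
the CGI so edge dyads have full kernel support; statistics are then
taken over the CGI proper.

## Group statistics

Per-promoter metrics are medians of skewed quantities, so class and
condition comparisons use a two-sided rank-sum (Mann–Whitney) test.
For pooled sizes ≤ 12 the p-value is computed by exact enumeration of
all label arrangements on midranks (`2·min(P(W ≤ w), P(W ≥ w))`, capped
at 1), which handles ties exactly; larger samples use the normal
approximation with continuity correction and the standard tie
correction (verified against `wilcox.test` and full permutation
enumeration in the test suite, and calibrated: type-I error at α = 0.05
lies in [0.03, 0.07] over 1,000 null replicates). FDR control is
Benjamini–Hochberg step-up, applied per metric per contrast over the
promoters with non-missing values. A change is "significant" at
FDR < 0.05 with linear fold change > 1.5 (the ATAC convention; 2.0 is
the usual expression-analysis choice and is a parameter). Condition
comparisons are unpaired by default; the per-promoter delta tables
support paired-style sign summaries.

Occupancy deltas use `log2((occ2 + c)/(occ1 + c))` with pseudocount
c = 1 occupancy-per-kb unit, small against typical values of several
hundred, so it only guards promoters with near-zero occupancy.

## The synthetic generator

`simulate_experiment()` emulates the statistical structure of a
two-class promoter cohort, not sequence-level detail. Each promoter is
a symmetric phased array: true dyads at
`tss ± (nfr_width/2 + 73 + k·NRL)`, k = 0…4 per side (10 nucleosomes).
Per dyad, `Poisson(depth = 20)` candidate draws are thinned by the
occupancy probability; kept draws emit mono fragments with
`Normal(0, fuzziness_sd)` midpoint jitter and sizes
`Normal(180, 20)` truncated to [150, 250]. `Poisson(nfr_rate)`
nucleosome-free fragments fall uniformly over the NFR plus internal
linkers with sizes `Normal(60, 25)` truncated to [20, 119]. Defaults:

| parameter | PcG-like | active-like | why |
|---|---|---|---|
| NRL (bp) | 175 | 195 | compact vs relaxed arrays |
| occupancy | 0.9 | 0.6 | nucleosome-dense repressed promoters |
| jitter sd (bp) | 25 | 12 | poorly vs well positioned |
| NFR width (bp) | 60 | 300 | open TSS only at active promoters |
| NFR fragments | 10 | 60 | short-fragment content |

These produce ~200 candidate fragments per promoter, a realistic
per-promoter depth for a deeply sequenced merged library, and were
fixed from the qualitative contrasts the assay literature reports
(repressed CGI promoters: higher occupancy, shorter spacing, fuzzier
positions, fewer short fragments). Promoters sit 5 kb apart on one
synthetic chromosome; class-A intervals are emitted into both synthetic
ChIP peak files and the CGI file, class-B intervals into the CGI file
only, so `classify_promoters()` reconstructs the design exactly — by
construction, which is the point: annotation recovery is then a tested
invariant, not an estimate. Every locus draws from its own RNG stream
seeded by `hash(global_seed, promoter_index)`, making the experiment
reproducible fragment-for-fragment and safe to parallelise.
`simulate_knockout()` scales class-A occupancy (× 0.5 by default) and
widens its NRL (+ 20 bp), leaving class B untouched.

What the generator does **not** emulate: Tn5 sequence/GC insertion
bias, replicate overdispersion beyond Poisson, chromatin-state
heterogeneity within a class, genome-scale annotation noise (every
simulated promoter is cleanly labelled), or the reduced *total*
accessibility of Polycomb promoters — simulated class-A promoters
actually yield more fragments than class B because of their higher
nucleosome emission. Passing recovery tests on this generator therefore
demonstrates the estimators' correctness and directional sensitivity,
not their behaviour under real-data artefacts.

## Validation scales and numerical choices

The test suite validates at deliberately modest problem sizes chosen as
the smallest scales at which every contrast is resolvable: oracle
equivalence on up to 10⁴ points (nearest-neighbour distances vs an
O(n²) scan), exact rank-sum enumeration up to pooled n = 12, parameter
recovery on 50 promoters per class across 5 seeds (~20,000 fragments
per condition per seed), and a 1,000-replicate null calibration.
Recovery tolerances: class-median inter-dyad distance within ±8 bp of
the true NRL; all orderings (occupancy, fragment size, fuzziness,
spacing) must hold in every seed. Degenerate inputs are handled
explicitly and tested: empty fragment sets give all-zero densities;
promoters with < 2 dyads give missing (never zero) spacing; missing
metrics propagate through deltas; empty CGI sets classify everything
`excluded` with a warning.

## Known limitations

- **Ratio-normalised occupancy compresses depth changes.** Because
  `occ = d_mono/(d_all + ε)` is a share, halving the per-nucleosome
  fragment emission halves both numerator and (mono-dominated)
  denominator wherever mono fragments dominate; the occupancy value
  falls mainly in linkers and NFRs, where the fixed nucleosome-free
  density gains weight. The acceptance script quantifies this: under
  the default knockout (occupancy × 0.5) the class-A median
  `log2fc_occupancy` is ≈ −0.25 — clearly negative and class-specific,
  but far from the −1 a count-proportional statistic would give. This
  mirrors the "subtle" occupancy shifts ratio-based occupancy methods
  report for PRC1 loss, and is intrinsic to any accessibility-
  independent occupancy definition: users needing a depth-sensitive
  readout should look at `delta_median_fragment_size` or mono-fragment
  counts alongside.
- Inter-dyad medians sit 3–5 bp below the true NRL at default jitter
  (kernel-mode noise makes the nearest neighbour slightly closer than
  the repeat on average); this bias is well inside the ±8 bp recovery
  tolerance but is visible in the acceptance output.
- The occupancy surrogate is not NucleoATAC: no V-plot/EM fragment
  model, no cross-correlation positioning. Agreement with such tools is
  expected to be ordinal (rankings, signs), not numeric.
- `read_bedgraph()` handles single-chromosome tracks only, matching the
  per-region way the package writes them.

```{r example, eval = FALSE}
# end-to-end run with all defaults (writes TSVs + manifest)
res <- run_pipeline(list(seed = 1L), outdir = "nucleoscape_run")
str(res$deltas)
```
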