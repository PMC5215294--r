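# epipoise

Epigenomic poising analysis for naive and memory CD4 T cells: does the
gain or loss of activating histone-modification islands (H3K4me3 and
friends) around a gene explain why that gene is rapidly inducible in one
cell subset and not another?

Memory T cells produce lineage cytokines within minutes to hours of
re-stimulation while naive cells need days. One mechanistic account is
*poising*: the promoters and enhancers of rapid-recall genes stay marked by
activating histone modifications in resting memory cells even though the
genes themselves are silent, so transcription factors can bind immediately
on activation. `epipoise` implements a complete, testable pipeline for that
question, from aligned ChIP-Seq tags (BED6) and FPKM tables to per-gene
poising calls — together with a seeded synthetic-data generator that plants
ground-truth poised genes and islands, so every stage can be validated
without any external download.

## What it computes

For tag libraries of a reference (naive) and target (memory) cell type:

1. **Coverage** — tags extended to fragment length `L`; each fragment adds
   `10^6 / total_mapped` to every bp it covers (FPM units).
2. **TSS metaprofiles** — each tag's 5' end shifted by `L/2` toward the
   fragment center contributes at one position in `TSS ± 2000` bp; counts
   are normalized per million mapped tags and per gene (X/Y tags weighted
   twice) and smoothed with a 100 bp centered moving average.
3. **Expression classes** — with resting FPKM `r` and activated FPKM `a`:
   *expressed* (`r > 5`), *silent* (`r < 2`, `a < 5`), *inducible*
   (`r < 2`, `a > 5`); values on or between the thresholds are ambiguous.
   Inducible genes are grouped by the relative induction ratio
   `(|ΔFPKM_TEM| + 0.1) / (|ΔFPKM_Naive| + 0.1)` at 150 min: ratio ≥ 3 is
   TEM-specific, ≤ 1/3 naive-specific, otherwise shared.
4. **Islands** — a scanning-window Poisson caller: non-overlapping 200 bp
   windows, genome-wide expectation `λ = n_tags / n_windows`, windows with
   upper-tail `P(X ≥ k) < 10^-5` merged across gaps ≤ 400 bp.
5. **Differential islands** — MAnorm-style normalization: on islands common
   to both samples, fit `M = log2(tgt/ref)` against
   `A = ½·log2(tgt·ref)` by least squares and subtract the fit everywhere;
   an island is differential when the exact conditional binomial test gives
   `p < 0.01`, `|M_adjusted| > 1` (2-fold), and ≥ 15 raw reads in at least
   one condition.
6. **Association** — a gene has *gained*/*lost* chromatin if a passing
   island overlaps `[TSS − 20 kb, TSS + 1 kb]` (transcription-oriented),
   consistently in both replicate comparisons; the poising summary reports
   the fraction of each induction group with gains/losses. Promoter-level
   calls use `TSS ± 1 kb` and classify the expression consequence
   (increased expression / increased inducibility / no change / losses).

## Worked example

```r
library(epipoise)
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
```

```
Poising pipeline report (seed 1): 200 genes, 100 inducible
          group n_genes fraction_gained fraction_lost
 naive_specific      40       0.0000000             1
   tem_specific      41       0.9756098             0
         shared      19       0.0000000             0
Promoters: 40 gained, 40 lost (replicate-consistent)
Recovery: 100.0% of marked poised_TEM genes; 0.0% spurious gains
```

Reading this: the default simulation plants 200 genes (20% poised-in-TEM,
20% poised-in-naive, 10% poised in both, plus constitutive and silent
genes) and simulates two ChIP replicates per cell type at a 3:1 depth
imbalance. Of the 100 genes inducible at 150 min, the 41 TEM-specific ones
almost all carry a TEM-gained island within `[TSS − 20 kb, TSS + 1 kb]`
(fraction_gained ≈ 0.98) while the naive-specific ones instead show a loss
relative to naive (fraction_lost = 1) — exactly the planted poising
structure. All 40 marked poised_TEM genes are recovered as
TEM-specific-with-gain, with no spurious gains among constitutive or
silent genes.

Individual stages are plain functions: `simulate_genome()`,
`simulate_chip_tags()`, `build_coverage()`, `tss_profile()`,
`classify_expression()`, `induction_groups()`, `call_islands()`,
`differential_islands()`, `link_islands_to_genes()`,
`promoter_differential()`, `consequence_matrix()`. A thin command-line
wrapper lives at `inst/scripts/run_pipeline.R`. See the vignette
(`vignettes/poised-chromatin.Rmd`) for the model and its assumptions.

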