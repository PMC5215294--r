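---
title: "Detecting epigenomic poising from ChIP-Seq islands and expression"
author: "epipoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epigenomic poising from ChIP-Seq islands and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipoise)
```

## The question and the model

Memory CD4 T cells induce lineage cytokine genes within minutes to hours of
re-stimulation; naive cells receiving the same activation signal cannot.
The poising hypothesis holds that this difference is written in chromatin:
in resting memory cells the promoters and enhancers of rapid-recall genes
remain covered by activating histone modifications (H3K4me3 in particular)
even while the genes are silent, so that the same transcription-factor
signal finds accessible targets only in the memory subset.

`epipoise` operationalizes that hypothesis as a measurable pipeline:

1. identify islands of ChIP enrichment per sample;
2. test islands for differential strength between naive and memory samples
   after M-A normalization;
3. classify genes as expressed / silent / inducible from FPKM tables and
   group the inducible genes by their relative induction between cell
   types;
4. ask whether differentially induced genes preferentially carry
   differential islands near their TSS.

The package also ships a synthetic-data generator that *plants* this
structure with known labels. That makes every stage falsifiable: the
pipeline's job is to recover the planted truth, and the test suite measures
exactly that.

## Coverage and metaprofiles

Aligned tags (BED6, 0-based half-open everywhere in this package) are
extended to the fragment length `L` (default 150 bp, configurable; a fixed
value is used rather than a per-library estimator so that results are
deterministic). Each extended fragment adds `1e6 / total_mapped` to every
bp it covers, giving fragments-per-million (FPM) tracks; the per-bp sum
therefore equals `L × n_tags / (total_mapped / 1e6)` exactly, up to
clipping at chromosome ends — a conservation law the tests check literally.

Metaprofiles around TSSs use a different convention, chosen to match
standard average-density plots: each tag within ±2000 bp of a TSS
contributes at *one* position, its 5' end shifted by `L/2` toward the
fragment center. Counts are normalized by millions of mapped tags and by
the number of genes, with X/Y-chromosome tags counted twice (one copy per
male genome ⇒ half the expected yield); the weighting is applied to raw
counts, before any normalization. The profile is smoothed with a centered
100 bp moving average whose window truncates at the array edges. Profiles
are transcription-oriented by default (minus-strand genes flipped so
positive positions are downstream); a genome-oriented mode exists for
comparison with browser views.

## Expression classes and induction groups

With resting FPKM `r` and activated FPKM `a` (150 min by default — the
timepoint the induction-ratio analysis is defined at; an any-timepoint mode
exists):

* expressed: `r > 5`
* silent: `r < 2` and `a < 5`
* inducible: `r < 2` and `a > 5`
* ambiguous: anything else, including values exactly on a threshold.

The 2/5 FPKM bracket reflects the rule of thumb that ~5–8 FPKM corresponds
to roughly one transcript copy per cell, so "silent" means below one copy
per cell with a guard band. Isoform tables are first collapsed by summing
FPKM over isoforms sharing a TSS (transcript mass from one start site is
additive); isoforms with distinct TSSs stay separate entries.

Inducible genes (silent at rest in both cell types, induced above 5 in at
least one) are ranked by the relative induction ratio

$$\rho = \frac{|FPKM_{TEM,150} - FPKM_{TEM,R}| + 0.1}
             {|FPKM_{Naive,150} - FPKM_{Naive,R}| + 0.1}$$

with `ρ ≥ 3` TEM-specific, `ρ ≤ 1/3` naive-specific, otherwise shared
(ties at exactly 3-fold go to the specific group). The absolute values and
the 0.1 offsets are implemented verbatim; a signed-delta variant would
distinguish decreases from increases on activation, but it is not the
default because the eligibility filter (silent at rest, induced after)
already restricts the universe to increases.

## Island calling

The caller is a fixed-width scanning-window Poisson model: non-overlapping
200 bp windows, a single genome-wide expectation `λ = n_tags / n_windows`,
window eligibility at upper-tail `P(X ≥ k) < 1e-5`, eligible windows merged
across gaps ≤ 400 bp, islands trimmed to their outermost eligible windows.
Tag membership uses the extended-fragment midpoint (strand-symmetric; 5'
end and overlap modes are available). This is a deliberately transparent
model — every decision is an explicit Poisson tail that the test suite
re-derives from pmf partial sums — rather than a local-background caller of
the MACS2 family; at the simulator's conditions (≥ 50 expected background
tags per kb, ≥ 5-fold enrichment) it recovers planted islands essentially
completely, and the expected number of false windows genome-wide is
`n_windows × 1e-5`.

## Differential islands: M-A normalization and the exact test

Two samples' island sets are merged into union regions; a region is
*common* when islands from both samples overlap it. With raw counts
`(a, b)` per region (pseudocount 0.5 replaces zeros so M stays finite):

$$M = \log_2(b/a), \qquad A = \tfrac12 \log_2(ab)$$

A least-squares line `M ~ A` is fitted over the common regions only — they
are presumed non-differential, so the fitted trend captures depth imbalance
and intensity-dependent bias — and subtracted from every region's M,
including sample-unique regions, to give `M_adjusted`.

One numerical guard matters: the slope of that line is only identifiable
when the common islands span a real intensity range. When their A values
are nearly constant (sd below 0.5 log2 units) an OLS slope is noise, and
extrapolating it to sample-unique islands at lower intensity corrupts
`M_adjusted` by several log2 units; in that regime the fit reduces to the
intercept (the pure depth offset). The default simulation is exactly this
regime — all constitutive promoter islands share one expected strength —
and real datasets with few, homogeneous common peaks would hit it too.

Significance uses an exact conditional test: given the total `a + b`, under
the no-difference null `b` is binomial with success probability
`2^f / (1 + 2^f)` where `f` is the fitted M — equivalent to comparing two
Poisson rates after normalization, but closed-form and oracle-checkable. An
island is differential when `p < 0.01`, `|M_adjusted| > 1` (adjusted fold
change > 2), and the *raw* count reaches 15 in at least one condition
(the plain reading of the read filter: pre-normalization, per comparison).
Direction is `gained` (stronger in the target/memory sample) for positive
`M_adjusted`.

## Association with genes

A gene's association window spans 20 kb upstream to 1 kb downstream of its
TSS in transcription orientation (the upstream/downstream reading of the
window; a genomic-orientation mode is provided since either convention is
defensible). A gene is *gained* when at least one passing gained island
overlaps the window by ≥ 1 bp — presence/absence, no per-gene p-value
combination — and, when two replicate comparisons are available, only when
both agree and neither shows the opposite direction. Promoter-level calls
use the symmetric `TSS ± 1 kb` window with the same both-replicates rule.

The poising summary then reports, per induction group, the fraction of
genes with gained or lost chromatin; the expression-consequence step
compares each promoter-changed gene's class between naive and memory cells
(silent→inducible = increased inducibility, silent→expressed = increased
expression, and so on; transitions involving ambiguous classes are treated
as no change). The heatmap matrix uses `log2(max(FPKM, 1))` — flooring
avoids huge fold changes among barely-expressed genes — with rows ordered
by average-linkage hierarchical clustering on correlation distance, a
purely cosmetic choice.

## The synthetic-data generator

`sim_config()` defaults define the conditions the package is validated
under:

* 200 genes on two 4 Mb autosomes plus an X-like chromosome, TSSs on a
  50 kb grid so association windows never collide (class fractions:
  25% constitutive, 20% poised_TEM, 20% poised_naive, 10% poised_both,
  25% silent — deterministic proportional allocation so expected counts
  are exact; a multinomial mode exists);
* background 0.05 tags/bp (50 expected tags per kb — enough that a 1 kb
  island is statistically unmissable), planted 1 kb promoter islands at
  10× background, 150 bp fragments read as 36 bp tags;
* constitutive genes carry their island in every cell type (active
  promoters — these become the common islands that anchor normalization);
  poised genes only in the cell type(s) where they are inducible;
* FPKM templates of 20 (induced/expressed) and 0.5 (silent) with
  multiplicative lognormal noise of σ = 0.3 — wide enough to be visible,
  far enough from the 2/5 thresholds that noiseless classification is
  exact and noisy misclassification stays in the low percent;
* the two replicates per cell type are drawn at a 3:1 depth imbalance in
  the pipeline, so normalization always has real work to do.

Two knobs decouple chromatin from expression where the biology does: a
`poised_marked_fraction` below 1 leaves some TEM-induced genes unmarked
(induction that chromatin does not explain — at 0.35 the recovered gained
fraction among TEM-specific genes should track 35%), and
`marked_silent_fraction` plants islands on silent genes (promoter gains
with no expression consequence, mirroring the observation that only about
half of promoter-gain genes change expression state).

What the simulator does *not* model — and what passing tests therefore do
not show about real data: sequence-level effects (mappability, GC bias,
duplicates), input/IgG background structure, broad domains or
variable-width islands, enhancer–promoter looping, and population
heterogeneity (a memory population in which only a fraction of cells carry
a mark is represented implicitly by the single enrichment fold, not by an
explicit mixture fraction). Island strength is homogeneous by design, which
is the hard case for the normalization fit (see the guard above) but easier
than real data for the caller.

## Determinism, problem sizes, degenerate inputs

All randomness flows from one master seed through labelled derived streams
(`derive_seed`), so adding a sample never perturbs another sample's draws,
and identical configurations give byte-identical outputs including the JSON
report. The validation suite runs the full pipeline over ten seeds at the
default 200-gene, ~12 Mb scale (a scale chosen so island statistics are
comfortably in the detectable regime while a complete ten-seed sweep stays
in minutes), plus exact-oracle checks of coverage, metaprofiles and island
calling on small random toys against brute-force reimplementations.

Degenerate inputs are defined behaviour: zero genes simulate to empty
tables; zero tags call zero islands; an empty induction group reports NA
fractions; fewer than 10 common islands is an error advising deeper
simulation rather than a silent bad fit; boundary FPKM values are
ambiguous by construction; interval membership at window edges follows the
half-open convention everywhere, so a fragment midpoint exactly at an
interval's end is outside it.

## Known limitations

The island caller's single genome-wide λ assumes background homogeneity;
chromatin input controls and copy-number variation are out of scope. The
binomial differential test inherits the Poisson assumption — biological
replicate overdispersion is handled only through the both-replicates
consistency rule, not through a dispersion model. The 15-read filter is
applied per replicate comparison (a pooled mode is available). Only
positive marks are modelled: loss of repressive marks, DNA methylation and
chromatin accessibility are different assays with different statistics.
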