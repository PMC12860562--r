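---
title: "Seasonal multi-omics integration: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal multi-omics integration: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasomics)
```

`seasomics` reconstructs, over synthetic data with planted ground truth,
the inference chain that prioritizes a transcription-factor regulator of a
red–green–red seasonal anthocyanin cycle from four omics layers. This
vignette documents the models, their assumptions, the tunable parameters,
and the choices made where the design was genuinely open.

## Coordinates and formats

Internally every interval is 0-based half-open (`0 <= start < end`);
GFF3-like annotation and methylation position columns are 1-based on disk
and converted only at the file boundary, so no off-by-one can propagate
between layers. Interval arithmetic (promoter windows, overlaps, merges)
is delegated to GenomicRanges/IRanges; the brute-force all-pairs oracles
in the test suite check every overlap operation against an independent
O(n·m) implementation.

## The synthetic generator as the study design

The generator (`simulation_config()`, `simulate_dataset()`) emulates a
three-stage seasonal design — spring (SPS), summer (SUS), autumn (AUS) —
with 3 biological replicates for RNA-seq, ATAC-seq, WGBS and 2 for Hi-C
(six matrices in total). Its defaults are the package's "study
conditions"; they were fixed once, on power-analysis grounds, and the
tests then measure recovery under them.

* **Counts (RNA/ATAC).** Negative binomial (Poisson–gamma) with per-gene
  lognormal baselines; variance µ + φµ². Defaults φ = 0.02 (RNA) and
  0.01 (ATAC) encode highly reproducible biological replicates, the
  regime in which a 3-vs-3 Welch test on log2-CPM has adequate power for
  the planted effect sizes: the planted regulator and structural genes
  are 8× summer-repressed in expression (and 6× less accessible at their
  promoter peaks) against baselines of several hundred counts. With
  φ ≈ 0.05 and n = 3, Welch's 4-df variance estimate makes recovery of
  even an 8-fold effect unreliable — an instructive limitation of
  unmoderated per-feature tests at minimal replication, and the reason
  moderated models (DESeq2, limma) exist. The package deliberately
  implements the plain Welch screen and chooses generator noise the
  screen can support.
* **Background genes have no season effect.** Seasonal structure beyond
  the planted genes comes from 54 "seasonal" genes spanning the six
  archetype patterns (the 3! orderings of high/mid/low at 4-fold), which
  also provide the truth labels for pattern classification and
  clustering tests.
* **Epigenome coupling.** For seasonal and structural genes, promoter
  accessibility scales as 2^(0.6·Δlog₂ expression) and promoter
  methylation drops by 20 % per log₂ unit of expression — this plants the
  genome-wide positive expression–accessibility and negative
  expression–methylation fold-change correlations. TF genes other than
  the master regulator are *excluded* from this coupling: otherwise every
  seasonally expressed TF would inherit a promoter accessibility
  contrast, and the master regulator would not be the unique TF passing
  all four evidence layers — uniqueness is precisely what the planted
  design is meant to exhibit. The control TFs therefore carry expression
  signatures only (WRKY-like: same high-low-high trend; ERF-like:
  opposite), exercising the sign-symmetric |r| edge criterion and the
  expression filter's direction.
* **Methylation.** Per-site beta-binomial: context baselines CG 0.60 >
  CHG 0.35 > CHH 0.08, a mild upward seasonal drift (×0.95, ×1.00,
  ×1.05 for SPS/SUS/AUS), beta precision 50, ~10 reads per site per
  replicate (~30× pooled per season). CG/CHG/CHH sites are dense near
  promoters (15/21/9 bp spacing) and sparser genome-wide. A graded dip
  (down to 30 % of baseline) within ±600 bp of every ATAC summit plants
  the canonical hypomethylation of open chromatin. The master regulator
  and the structural genes additionally carry a 600 bp promoter region at
  level 0.30 that jumps to 0.85 in summer (CG and CHG) — the planted
  summer-hypermethylation signature.
* **Hi-C.** Two-block checkerboard per chromosome: within-block mean 120,
  between-block 12, times 1/(1+d) distance decay, Poisson counts. The
  gene placement puts ~70 % of genes in the A half, which is what the
  eigenvector orientation rule keys on. Two switch bins per chromosome
  (one A2A2B, one B2A2B — the two patterns reported to dominate) flip
  block membership by season. Depth was set so that distal bins retain
  enough counts for a stable eigenvector sign; at half this depth a
  switch bin's entry occasionally lands at ≈0 and flips its label.
* **Metabolome.** 87 compounds in the eight anthocyanin-related classes
  (24/23/11/8/7/6/6/2). Fifteen planted contrasting metabolites
  (7 cyanidins, 5 delphinidins, 2 pelargonidins, 1 peonidin) follow the
  pigment trend at 8-fold; the first cyanidin is the C3G-like pigment at
  300-fold, matching a "several-hundred-times" summer depletion.
  Replicate CV 10 %. Calibration standards span 0.01–5000 ng/ml in 14
  log-spaced levels with homoscedastic noise in concentration units —
  the model under which the prescribed *unweighted* OLS is correct. (With
  noise proportional to response, high-concentration standards corrupt
  the intercept and low-level inversions; a practitioner would switch to
  1/x-weighted regression, which is out of scope here.)

What the generator does **not** emulate: read-level artefacts (mapping,
duplication, bisulfite conversion), gene-length or GC biases,
overdispersed outlier replicates, trans-chromosomal Hi-C structure, and
correlated biological covariation among background genes. Passing tests
therefore demonstrate correct recovery of planted effects under a clean
generative model, not robustness to the full messiness of real data.

## Differential screens

All three screens share one machinery: a vectorized Welch t-test on a
log-like scale with closed-form Satterthwaite degrees of freedom, then
Benjamini–Hochberg. Degenerate features (zero pooled variance) get p = 1
when the means agree, so identical inputs yield zero calls rather than an
error. Thresholds follow the printed inequalities *exactly*:

| screen | effect scale | call rule |
|---|---|---|
| DEG | mean log2-CPM difference (pseudocount 0.5) | FDR < 0.05 **and** \|log₂FC\| > 1 (both strict) |
| DAR | library-normalized log2 counts over consensus peaks | \|log₂FC\| ≥ 0.58 (inclusive) **and** raw P ≤ .01 (inclusive) |
| DAM | log2 of content means (pseudocount 0.01) | BH q < 0.05 and \|log₂FC\| ≥ 1 |

DE testing excludes genes with fewer than 10 summed counts across the
tested samples. The DAR rule uses a raw-p threshold (not FDR), matching
the quoted differential-binding setting; consensus peaks are the ≥1 bp
merge of all per-sample peaks.

## The DMR caller

A transparent stand-in for window-based DMR callers: 100 bp windows every
50 bp; a window is tested when it holds ≥5 cytosines of the context
covered ≥4× in both pooled samples; the test is a Yates-corrected Pearson
χ² on the pooled 2×2 counts (`dmr_method = "fisher"` switches to an exact
test); calls require BH q < 0.05 and |level difference| ≥ 0.1 (CG/CHG) or
0.05 (CHH); overlapping same-direction windows merge, and a merged DMR
must span at least `dmr_min_run = 3` called windows (≈200 bp, ≥2×
min_sites cytosines). The minimum-run rule is the analogue of the
minimum-CpG requirement in production callers: without it, single-window
flukes at the BH boundary are reported and precision on planted-region
benchmarks degrades to roughly 1 − FDR of the window test rather than
reflecting region recovery. The continuity correction matters for the
same reason — BH operates in the far tail, where the uncorrected χ² is
anti-conservative.

## Compartments

Balancing is plain iterative proportional fitting to equal marginals
(tolerance 10⁻⁵ on relative deviation), after masking bins with zero
marginal or a marginal strictly below the type-1 empirical 2nd-percentile
of the nonzero marginals (the inverted-ECDF quantile; an interpolating
quantile would always mask the minimum bin even in clean data). O/E
divides by per-|i−j| diagonal means over unmasked entries. The
compartment call is the leading eigenvector of the Pearson correlation
matrix of O/E, sign-oriented to correlate positively with gene density
(A = gene-dense); A ⇔ value > 0, masked bins are `NaN`, and per-bin
season labels concatenate into switch strings (`A2A2B`). Genes inherit
the label of their TSS bin. Labels are invariant to positive scaling of
the contact matrix; degenerate (uniform) matrices raise an error rather
than returning an arbitrary split.

## The integrative screen

The network correlates each TF with each structural gene on log2-CPM over
all 9 replicate samples (`corr_over = "samples"`; season-mean mode is
available — with only three seasons, three-point correlations are nearly
always |r| ≈ 1, so the replicate-level default is the informative one).
Edges need |r| > 0.8 (strict); a TF qualifies via any one structural gene.
The four filters are each recomputable from one layer:

* `expr_contrast`: DEG down in SPS→SUS **and** DEG up in SUS→AUS;
* `atac_contrast`: promoter overlaps a loss-DAR in SPS→SUS and a
  gain-DAR in SUS→AUS;
* `meth_contrast`: promoter overlaps a hyper-DMR in SPS→SUS and a
  hypo-DMR in SUS→AUS (summer-peaked methylation; any context;
  `meth_contrast_mode = "gene_body"` switches the region);
* `compartment_A_stable`: label A in all three seasons; `NaN` counts as
  failure but is annotated as missing rather than silently false.

Candidates are ranked by layers passed (0–4), then maximal |r|, then
tf_id — a deterministic total order. Missing layers produce `NA` flags,
not `FALSE`. The trend-matching of structural genes conditions on the
seasonal pattern (high-low-high, with a 0.5-log₂ deadband) plus at least
one epigenomic evidence — deliberately *not* on DEG status, since a gene
can track the pigment trend while narrowly missing a DEG threshold in one
comparison.

Global layer summaries are Spearman correlations of per-gene
season-to-season fold changes (both transitions pooled), with Fisher-z
confidence intervals.

## Numerical and degenerate-input conventions

Pattern labels use sign(ΔSUS−SPS, ΔAUS−SUS) with a 0.5-log₂ deadband;
cluster centroids are labelled with a 0.25 deadband in Z units. Tree
cutting processes genes in sorted id order, so clustering output does not
depend on input order. The log2-CPM pseudocount (0.5) means exact
count-scaling invariance of pattern labels holds only away from the
deadband boundary at very low counts. Empty peak files parse to empty
sets; empty DEG sets, empty consensus sets, all-zero Hi-C rows, unknown
methylation contexts, and methylated > total all raise immediate,
specific errors.

## Problem sizes

The default dataset is desk-scale by design: 2 chromosomes × 400 kb,
200 genes (30 TFs), ~210 peaks, ~63k cytosines × 9 samples, 20 Hi-C bins
per chromosome; a full pipeline run takes a few seconds, and the 20-seed
stability analysis about two minutes. The DMR benchmark plants 40 regions
of 300 bp at 30× coverage on a 60 kb background, sized so the planted
truth dominates the BH-expected false discoveries of the window test.

## Known limitations

Welch-on-log2 screens at n = 3 are underpowered relative to moderated
count models; the DMR caller's pooled test ignores replicate-level
biological variability (pooling is standard for window testers but
overstates certainty under overdispersion — the minimum-run rule
compensates pragmatically, not inferentially); compartment calls assume
intra-chromosomal two-block structure and a gene-density orientation
signal; and the |r| > 0.8 network over 9 samples carries no multiplicity
control, exactly as specified for the screen it reproduces.
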