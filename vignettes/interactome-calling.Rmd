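---
title: "Calling bait interactors from AP-MS spectral counts and prioritizing NDD candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling bait interactors from AP-MS spectral counts and prioritizing NDD candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurointeract)
```

## The analysis this package implements

An endogenous bait protein — here the neurodevelopmental kinase DYRK1A in
human neural stem cells — is immunoprecipitated with two antibodies
recognizing its C-terminal and N-terminal regions, alongside three mock
controls (free beads and two irrelevant antibodies, MAR and RAM), each
injected in triplicate. Protein-level peptide-spectrum-match (PSM) counts
from the search engine are the input. The package then answers four
questions: which co-purified proteins are credible interactors; which of
them track the bait's expression across brain development; which are
promising new candidate genes for neurodevelopmental disorders (NDDs);
and, after knocking the bait down, how transcription responds at the
gene and gene-set level.

Counts live in a `SpectralCountExperiment`, a `SummarizedExperiment`
whose `psm` assay holds one column per (condition, replicate) run, with
protein lengths in `rowData` and the condition/replicate/role design in
`colData`. One naming note: the control-IP antibodies are mouse
anti-rabbit (MAR) and rabbit anti-mouse (RAM); an occasional "GAR" label
seen for the latter in write-ups of this design is treated as a synonym
of RAM, and the package uses `{Beads, MAR, RAM}` throughout.

## The interactor filter

A protein is called an interactor for a given antibody when all three
criteria hold:

1. **Clean controls** — for *every* control condition, the sum of its
   replicate PSM counts is strictly below 5. A control sum of exactly 5
   fails. The bound is applied per control condition by default; a
   grand-sum variant is selectable (`controlScope = "total"`).
2. **Reproducible detection** — the antibody's replicate counts sum to
   at least 5 *and* every replicate is positive. (5, 0, 0) fails;
   (2, 2, 1) passes.
3. **NSAF enrichment** — the normalized spectral abundance factor,
   $\mathrm{NSAF}_i = \frac{\mathrm{SpC}_i / L_i}{\sum_j \mathrm{SpC}_j / L_j}$
   with $L_i$ the protein length in amino acids, computed on
   replicate-summed condition counts, must be at least 1.5-fold higher
   in the bait IP than in the controls. The ratio is inclusive
   (exactly 1.5 passes).

Three numerical choices in criterion 3 were genuinely open and are fixed
as follows, all selectable by argument. The control reference is the
*maximum* NSAF across control conditions — the most conservative
denominator (`mean` and `sum` are available). When the control reference
is zero and the test NSAF positive, the ratio is $+\infty$ and the
criterion passes: absence from nine control runs is evidence, not
missing data. When both sides are zero the criterion fails — no
evidence is never enrichment. NSAF is computed per condition aggregate
because the filter reasons at condition level; per-run NSAF
(`scope = "run"`) exists for diagnostics. A run or condition with no
counts at all yields all-zero NSAF with a warning rather than an error,
since empty mock IPs are a legitimate outcome.

Support is classified per protein as `both`, `Cter-only`, `Nter-only`
or `none`. On the packaged published partner table — which carries only
per-antibody PSM *sums*, replicate splits being unpublished — replicate
rules cannot be evaluated; `callInteractors()` refuses such tables, and
`countSummary()` instead uses "both per-antibody sums ≥ 5" as the
dual-detection proxy. That proxy reproduces the published 7
dual-antibody partners exactly and is documented as a sum-table-only
rule; we deliberately never fabricate replicate splits for printed sums.

```{r}
summary <- countSummary(dyrk1aPartners(),
                        geneSet = list(APC = c("CDC27", "ANAPC4", "CDC23",
                                               "CDC16", "ANAPC7")))
unlist(summary)
```

## Co-expression with the bait

Each partner's developmental brain-expression profile is correlated with
the bait's (Pearson, across whatever sample columns the matrix
provides). The binning threshold for "moderate-to-high positive"
co-expression is 0.58, inclusive: the source analysis never printed its
cutoff, and 0.58 is the conventional-looking value that reproduces the
published 11-of-35 co-expressed partners on the packaged table; it is an
argument everywhere it is used. The 35-partner denominator includes the
one partner with no expression data (AGO1): missingness is reported as
`unknown`, never as low correlation, and never converted to 0. Profiles
with fewer than 3 overlapping samples or zero variance yield `NA` with a
warning.

## Phenotype overlap and NDD-candidate flagging

A bait syndrome is a set of clinical-sign identifiers (HPO-style);
each partner-linked disease is another. `phenotypeOverlap()` reports the
fraction of bait terms covered by the union of partner-disease sets and
per disease. Overlap is exact identifier intersection — no propagation
to ontology ancestors — because the question asked is "is this clinical
sign also described there", not semantic similarity.

A partner is flagged as an NDD candidate iff it has **no** known disease
involvement, pLI **strictly above** 0.9, and bait co-expression **at or
above** 0.58. Missing pLI or correlation disqualifies, conservatively.
On the packaged table this flags DCAF7, GSPT1 and PRRC2B — the first two
are the canonical examples; PRRC2B satisfies the same rule and is
reported rather than suppressed.

## DEG tiers and gene-set directionality

Differential-expression results are consumed as produced upstream
(DESeq-style `log2FoldChange`/`pvalue`/`padj`); adjusted p-values are
never recomputed. A gene is a DEG iff padj < 0.1, tiered `strong`
(padj < 0.05) or `moderate`. A log2FC of exactly 0 counts as neither up
nor down and is reported separately (`n_zero`), because directionality
is defined by strict inequalities. Gene-set directionality (the
fraction of a signature's genes with positive log2FC) uses *all* set
members present in the table with no significance filter: a signature
statement like "91% of 200 targets overexpressed" is about the whole
signature, not its significant sliver.

## What the synthetic generators emulate — and what they do not

Every pipeline input has a generator with ground-truth labels, all
requiring an explicit seed and restoring the caller's RNG state.

`simulateApms()` emulates the five-condition triplicate design. Its
count model is a gamma–negative-binomial hierarchy chosen on two
grounds. First, contaminant *stickiness is a protein property*: each
background protein draws one abundance from a gamma spread (shape 1,
mean 0.5 PSMs per replicate by default) and keeps that same mean in
every condition, bait and control alike — a background protein seen in
the bait IP is, on average, equally visible to the controls, which is
the premise the control filter rests on. Second, run-level repeatability
is modestly overdispersed (negative binomial, size 4): an abundant
protein does not vanish from a third of injections, but counts are
noisier than Poisson. Planted true interactors draw bait counts at 30
PSMs per replicate and near-zero control counts (mean 0.02); the bait
protein itself is included at twice that. Protein lengths are uniform on
100–2000 aa. These defaults are documented choices about a plausible
instrument, not a claim to match any particular one.

What this generator does *not* emulate is informative about the filter
itself. At a background mean of 0.5 PSMs per replicate over 200
proteins and two antibodies, a rare protein occasionally lands ≥ 5 PSMs
spread over all three replicates of one bait IP while missing from all
nine control runs. Such a protein passes all three criteria — as it
must: this is exactly the count profile of several published weak
single-antibody partners (e.g. 5/0 PSM sums). In Monte-Carlo runs at the
default regime all planted interactors are recovered in every seed, but
roughly one run in three acquires one such background call, so
*perfect* (zero-false-positive) recovery holds in only ~60–75% of
seeds depending on the count model. This is an irreducible property of
threshold-based spectral-count filtering at low background abundance,
not a defect of the implementation; probabilistic scoring models exist
precisely to address it and are out of scope here. The acceptance
metrics therefore report sensitivity, the perfect-recovery rate and the
false-positive rate separately.

`simulateExpression()` builds partner profiles as
$\rho\, z_{\text{bait}} + \sqrt{1-\rho^2}\,\varepsilon$ against a
standardized bait profile, so planted correlations are realized in
expectation at the default unit noise; stage/structure labels mimic a
developmental atlas's design but carry no signal. It does not emulate
stage-autocorrelation or region effects, so passing recovery tests
says nothing about those structures in real atlases.
`simulateDeTable()` plants signature-sign probabilities and a
configured significant fraction; it does not model count-level
variance–mean coupling, only the result-table layer this package
consumes. `simulateOntology()` allocates bait terms to diseases in
maximally disjoint consecutive slices so that stated overlap fractions
are exact by construction.

## Problem sizes and determinism

The bundled tests run the filter-oracle comparison on 50 random tables
of up to 20 proteins, the interactor Monte-Carlo on 100 seeds of the
205-protein default regime (a few seconds), correlation recovery at 500
samples, and signature recovery on a 200-gene set in a 2000-gene table
— sizes at which every stochastic bound used (±0.05 at n = 500;
3 binomial standard deviations for sign fractions) has comfortable
margin. Reports embed the exact thresholds used; rerunning an identical
configuration reproduces the report byte for byte.

## Known limitations

Numbers that depend on external snapshots are not reproduced here: live
phenotype-ontology coverage figures, and any DEG or signature statistic
of the original knockdown experiment, which require the deposited
RNA-seq data and a DESeq re-run. The package reproduces the published
partner-table summaries exactly and tests everything else against
synthetic ground truth. Protein inference, FDR control, contaminant
repositories and probabilistic interaction scoring are upstream or
out of scope.
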