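---
title: "Measuring translational selection across expression patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring translational selection across expression patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(codonsel)
```

# The question

Synonymous codons are not used equally. One driver is *translational
selection*: codons decoded by abundant tRNAs are translated faster and more
accurately, so selection should favour them — most strongly in genes that are
expressed highly and at a stable level in every tissue, and weakly or not at
all in genes whose expression is tissue-specific or fluctuates. `codonsel`
implements the full chain of measurements needed to test this prediction:

1. a per-gene codon usage bias (CUB) statistic with a significance test;
2. an expression-pattern classification of genes from a multi-tissue RPKM
   matrix;
3. identification of each amino acid's translationally *optimal* codon from
   tRNA gene copy numbers;
4. the association statistics that connect 1–3;
5. a synthetic-data generator with known ground truth, so every stage is
   verifiable end to end.

# Codon usage bias: the codon deviation coefficient

## Model

For a gene with sense-codon counts $x = (x_1, \dots, x_{61})$, we need a null
expectation for what its codon usage would look like *without* any codon
preference, given the gene's own background nucleotide composition. The
expectation assumes independence of the three codon positions and, within a
position, is parameterised by the GC content $g_k$ and purine content $r_k$
of position $k$ (computed from the gene's observed codons, stops excluded):

$$P_k(\mathrm{G}) = g_k r_k,\quad P_k(\mathrm{C}) = g_k (1 - r_k),\quad
  P_k(\mathrm{A}) = (1 - g_k) r_k,\quad P_k(\mathrm{T}) = (1-g_k)(1-r_k).$$

A codon's expected probability is the product over its three positions; stop
codons are removed and the remainder renormalised over the 61 sense codons,
giving $e$. The codon deviation coefficient is the cosine dissimilarity

$$\mathrm{CDC} = 1 - \frac{x \cdot e}{\lVert x \rVert\, \lVert e \rVert}
  \in [0, 1],$$

which is 0 when usage is exactly proportional to the expectation. Because the
expectation is built from the gene's own composition, CDC is insensitive to
mutational GC pressure, unlike ENC-style statistics.

Two properties are verified by the test suite: under the null (counts drawn
from $e$ itself) CDC decreases toward 0 as gene length grows, and a
point-mass on one codon gives the closed-form maximum
$1 - 1/\sqrt{61} \approx 0.872$.

Note the purine parameterisation: at a position where every codon carries G,
the purine content is 1, not 0 — G counts as a purine wherever it appears.

## Significance

Finite-length genes have CDC > 0 by chance, so significance uses a parametric
bootstrap: draw `n_boot` multinomial samples of the same size from $e$,
recompute CDC for each, and report the add-one estimate

$$P = \frac{1 + \#\{\mathrm{CDC}_{sim} \ge \mathrm{CDC}_{obs}\}}{n_{boot}+1}.$$

The add-one form keeps $P > 0$ and is the standard conservative Monte-Carlo
estimator. Default `n_boot = 1000` gives a P-value resolution of ~0.001 at
roughly 1 second per 1,000 genes; the pipeline filters at `p_cut = 0.05`
**once**, before any downstream analysis. The suite verifies calibration:
bootstrap P-values of null genes pass a Kolmogorov–Smirnov test of
uniformity.

## Ranks

CDC is binned into five ranks with left-closed, right-open intervals:
`low` < 0.10, `medium-low` [0.10, 0.13), `medium` [0.13, 0.16),
`medium-high` [0.16, 0.19), `high` ≥ 0.19. These cut points sit in the range
CDC actually occupies for real and simulated coding sequences (medians
~0.08–0.20 from no bias to strong bias) and give informative occupancy of all
five bins at the default generator settings.

# Expression-pattern classification

*Breadth* is the number of tissues with RPKM above `expressed_threshold`
(default 0, i.e. any detectable expression). Genes with breadth exactly 1 are
**TS** (tissue-specific), recorded with their expressing tissue. Genes
expressed in all tissues are *ubiquitous* and are split into:

- **EIG** — expression-invariant genes: high, *stable* expression everywhere
  (the housekeeping core);
- **EVG** — expression-variable genes: ubiquitous but fluctuating.

The split clusters a per-gene dispersion statistic by hierarchical clustering
(Euclidean distance, average linkage), cuts at `k = 10` clusters, and labels
a cluster EIG when its median dispersion is below `cv_cut = 0.25`. Using
k = 10 rather than 2 lets several tight low-dispersion clusters be EIG while
diffuse clusters of any size fall to EVG; the cut at 0.25 separates the two
dispersion regimes the generator (and typical RNA-seq data) produce.

**Choice of dispersion statistic.** The default is the standard deviation of
log10 RPKM across tissues (`dispersion = "log_sd"`). An alternative based on
the coefficient of variation of quantile ranks (each tissue's expression
mapped to `n_bins = 1001` quantile bins, `dispersion = "rank_cv"`) is kept as
an option, but it misclassifies ubiquitous genes whose mean expression is
extreme: at the top or bottom of the rank scale the rank CV saturates near
zero regardless of true variability, so highly expressed *variable* genes
leak into EIG. On simulated data with known labels, log-sd recovers 98–100%
of EIG/EVG labels across seeds, versus ~92% for rank CV; the package default
follows the measurement that is faithful to the intended definition
("invariant expression *level*"), not the one that is merely rank-based.

# Optimal codons from tRNA gene copy numbers

A codon's decoding weight is the genomic copy number of the tRNA whose
anticodon is its Watson–Crick reverse complement. One modification is
applied: for the eight amino acids (Ala, Arg, Ile, Leu, Pro, Ser, Thr, Val)
whose A34 anticodons are deaminated to inosine by ADAT, inosine pairs with C
better than with U, so the A34 copies are credited to the **C-ending** codon
of the family *instead of* its T-ending Watson–Crick cognate. Crediting
*instead of* (reassignment), rather than *in addition to*, is deliberate:
inosine-decoded families have no dedicated G34 tRNA, so without the
reassignment the C-ending codon would have weight 0 and the T-ending codon
would carry the whole A34 pool — the opposite of observed wobble efficiency —
and additive crediting would manufacture spurious T/C ties.

The optimal codon is the within-family weight argmax. Methionine and
tryptophan (single-codon families) are excluded a priori; families whose top
weight is tied are excluded as undecidable. With the packaged tRNA table
(`trna_fixture()`, a synthetic table patterned on human genomic tRNA copy
numbers), glutamate is tied and 17 amino acids receive an optimal codon — all
17 of them G- or C-ending, the classic signature of translational optimality
in GC-rich mammalian genomes.

# RSCU and association statistics

Relative synonymous codon usage for codon $j$ of an $n_i$-fold family, on
counts pooled over a gene group:

$$\mathrm{RSCU}_j = \frac{x_j\, n_i}{\sum_{j' \in i} x_{j'}},$$

so a family's RSCU values sum to the family size and 1 means "no preference".
Unobserved families are NA (not 0). Group comparisons report, per group, how
many optimal codons have strictly larger RSCU than in every other group
(*exceedance*) and how many exceed 1 (*preferential use*).

Associations between CUB and expression:

- Pearson (or Spearman) correlation of CDC against log10 RPKM, per class and
  tissue; TS genes are correlated only within their own expressing tissue.
- Breadth-stratified correlations (one per breadth × tissue stratum).
- Expression trend across the five CUB ranks with a two-sided rank-sum test
  between adjacent ranks: exact enumeration over all
  $\binom{n_a+n_b}{n_a}$ assignments (mid-ranks for ties) when both groups
  have ≤ 8 members, the tie-corrected normal approximation otherwise.
- GC content by codon position (GC1/GC2/GC3) versus CDC, plus a high-vs-low
  rank contrast per position.

P-values are annotated `*` < 0.05, `**` < 10⁻³, `***` < 10⁻¹⁰, with no
multiple-testing correction — the tables report per-test evidence and leave
family-wise control to the reader, since which tests form a family depends on
the question asked.

# The synthetic generator

`generator_config()` + `generate_dataset()` produce coding sequences, an RPKM
matrix and the tRNA table, with a ground-truth table of class labels, mean
levels and per-gene bias strength $\beta$.

**Sequences.** Amino acids are drawn i.i.d. from a fixed human-average
composition; each amino acid's codon is its optimal codon with probability
$\beta$ and otherwise uniform within the family. $\beta = 0$ therefore gives
RSCU ≈ 1 everywhere and $\beta = 1$ gives only optimal codons; median CDC is
strictly increasing in $\beta$ (verified on a grid). Lengths are lognormal
(median 400 codons, floor 100).

**Expression.** Three lognormal regimes: EIG median 145 RPKM with small
between-tissue spread (σ = 0.2 on the log scale), EVG median 20 with large
spread (σ = 1.2), TS/other median 10. TS genes are expressed in exactly one
tissue.

**Coupling.** The default β rule couples bias to expression *only in EIGs*
($\beta = 0.10 + 0.25(\log_{10} \text{level} - 1)$, clamped to [0, 1]);
non-EIG genes get β uniform on [0.05, 0.55], independent of expression. This
builds in the effect under study — a positive CUB–expression correlation in
EIGs, none in EVGs — so recovery of the pattern is a genuine end-to-end test
with known truth, and the expression-independent scatter in the other classes
populates all five CUB ranks.

**Realism and limits.** The generator is deliberately minimal: i.i.d. amino
acids (no protein structure), a single global optimal-codon set, no isochore
or GC-gradient structure along the sequence, no noise model on RPKM beyond
lognormality, and bias that acts only through the optimal codon. It is a
calibration instrument, not a genome simulator; conclusions about real
genomes require real data through the same pipeline.

**Determinism.** Every stochastic entry point takes a seed; per-unit seeds
are derived from the master seed via `derive_seeds()` (all below $2^{31}$),
and seeded helpers save and restore the caller's RNG state so they never
perturb the surrounding session.

# Pipeline

`run_pipeline(pipeline_config(...))` runs everything on the id intersection
of the FASTA and the matrix, applies the CUB significance filter exactly
once, and writes `cub.tsv`, `classes.tsv`, `optimal_codons.tsv`, `rscu.tsv`,
`correlations.tsv`, `breadth_correlations.tsv`, `contrasts.tsv`,
`preferential.tsv` and `summary.txt`. `validate_config()` checks a
configuration without side effects. The numbered scripts under `analysis/`
run the same stages as a readable, stepwise study.

# Default problem sizes

Defaults (1,500 genes × 10 tissues, 1,000 bootstrap replicates) run the full
pipeline in well under a minute on one core; these sizes are the package's
own choice of a comfortable desk-scale benchmark, large enough for the
statistics to stabilise and small enough to iterate on.

# Limitations

- CDC's independence null absorbs composition but not dinucleotide or
  context effects; genes with strong CpG avoidance can show inflated CDC.
- The EIG/EVG split is a clustering heuristic; near the dispersion boundary
  labels are sensitive to `cv_cut` and to the tissue panel.
- Optimal-codon identification uses tRNA gene copy number as a proxy for
  tRNA abundance, ignores tissue-specific tRNA expression, and resolves
  wobble only through the ADAT rule.
- The expressed/not-expressed call at RPKM > 0 is permissive; noisy
  low-coverage data may need a higher `expressed_threshold`.
- No multiple-testing correction is applied to the association tables.
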