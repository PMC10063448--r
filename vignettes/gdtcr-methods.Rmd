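---
title: "Methods and design of the gdtcr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the gdtcr pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdtcr)
```

This vignette describes the models and procedures `gdtcr` implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design choices made where more than one reasonable
convention exists.

## The analysis problem

Tumor-infiltrating γδ T cells are characterized on two coupled axes: the
TCR axis (which Vδ gene a cell uses, whether its clonotype is expanded, how
diverse the repertoire is, and how cells cluster by CDR3 similarity) and the
expression axis (transcriptional subpopulations, exhaustion programs, and a
Vδ2⁻-specific gene signature whose enrichment in bulk pretreatment tumors
can be associated with survival and checkpoint-inhibitor response). The
package implements both axes plus the bridge between them: the gene
signature derived from single cells is scored in bulk cohorts.

## Contig processing

A *productive* contig must encode a functional chain. The six conditions are
implemented as independent toggles in `productive_rules()`: full-length
span, an `ATG` initiator at the start of the assembled sequence, a detected
CDR3, a junction length divisible by three, no internal stop codon in the
CDR3 translation, and V/J calls from one locus (hybrid TRAV/DV segments
count as consistent with both TRA and TRD J genes). When the annotation
already carries a definite productive flag, the flag is trusted by default;
records with an unknown flag (`"None"` in 10x outputs) are evaluated against
the rules. This two-tier behavior keeps the filter reproducible across
annotation dialects whose flag conventions differ.

Hybrid TRAV/DV contigs are delta chains only when their D, J *and* C genes
are all TRD-locus calls; matching tolerates case and the `TRAV14/DV4`
spelling. All three genes must be present and delta — a missing call leaves
the chain untouched, and such contigs simply never enter γδ pairing.

Annotation tools do not specify how a cell with two productive contigs at
one locus should be resolved. The package keeps the highest-UMI contig,
breaking ties by read count and then lexicographically smallest contig id,
which makes the choice deterministic under any input ordering. Orphan cells
(one chain only) are excluded from pairing and reported separately; they
enter no downstream statistic.

## Clonotypes, expansion and diversity

The clonotype key is the concatenation of the gamma and delta full
nucleotide sequences, scoped per sample: the same sequence pair observed in
two patients is two clonotypes. Expansion is a cell-level label (≥ 2 cells
sharing a key). Where summaries could count either cells or clones, the
per-cell convention is primary and `clonotype_sizes()` provides the
clone-level view.

The Gini coefficient uses the pairwise mean-absolute-difference definition
without small-sample correction — the common default, and the form that is
exactly testable against a brute-force oracle. It is scale-invariant and
strictly below 1. Group comparisons of Gini values use the Wilcoxon
signed-rank test, exact when at most 25 non-zero differences with untied
magnitudes exist, and the normal approximation with continuity correction
otherwise.

The chain-usage table derives within-Vδ2⁻ percentages from counts, so the
identity `within % = overall % / Vδ2⁻ fraction` holds exactly up to
rounding — a worked-arithmetic property the acceptance checks exercise.

## CDR3 similarity networks

Networks are cell-level graphs per patient over delta-chain CDR3 amino-acid
sequences; cells without a phenotype cluster label are excluded before
construction, and no cross-patient edges are ever formed. The default edge
threshold is Levenshtein distance 0 (identical sequences), where connected
components coincide with a group-by on the CDR3 string — that equivalence is
used as an independent test oracle. Larger thresholds are supported for
exploration but are not part of the default outputs. Component counts and
maximum component sizes are normalized by the patient's cell count and
log₁₀-transformed; the convention here is clusters ÷ cells (values ≤ 0).
Edit distances are computed with `utils::adist`, validated exhaustively
against a dynamic-programming oracle in the test suite.

## Expression pipeline

Quality control runs in a fixed order: cells below the 200-gene floor,
genes detected in fewer than 3 cells, then cells failing the strict upper
bounds (< 4,000 genes, < 20,000 counts, < 10% mitochondrial, the `MT-`
prefix identifying mitochondrial genes, configurable). The strictness of
the comparisons is deliberate: a cell with exactly 4,000 genes is removed.
Counts are then scaled to 10,000 per cell and log1p-transformed (natural
log).

Batch adjustment equalizes per-gene batch means on the log layer (with an
optional scale step); it removes additive shifts while preserving
within-batch contrasts, which the tests verify on simulations with planted
batch shifts plus planted biology.

Clustering selects highly variable genes by dispersion (variance/mean; the
defaults are 1,000 HVGs, 30 principal components, 15 neighbors), builds a
kNN graph in PC space and runs Leiden community detection with the
modularity objective at resolution 0.6. These defaults are exposed because
no single choice is canonical; the resolution default reflects a typical
setting for immune-cell subpopulation structure. Clustering is
deterministic under a fixed seed.

Vδ2 labels use the argmax over Vδ gene expression (TRDV1/2/3 plus the five
hybrid genes by default). Cells with no Vδ expression, or an argmax tie,
are left unassigned rather than arbitrarily classified; on zero-noise
simulations the expression-based labels agree fully with contig-derived
labels among assigned cells.

Gene-set scores subtract a control mean from the set mean, with controls
sampled per expression-magnitude bin (25 bins, 50 controls per set gene) to
match the set's expression profile — so a random gene set scores ≈ 0 and a
shifted set scores positive regardless of overall expression level.

Differential expression is the two-sided Wilcoxon rank-sum test per gene
with tie-corrected normal approximation and Benjamini–Hochberg adjustment
(BH chosen as the field default). The log fold change is
`log(mean(expm1(target)) + ε) − log(mean(expm1(reference)) + ε)` with
ε = 1e-9, natural log; values are clipped to ±7 for display only, never for
ranking. The signature is the top 20 upregulated genes by raw p, ties
broken by larger log fold change then gene name, making the selection
deterministic under input permutation. Where the contrast pools several
reference populations (e.g. Vδ2⁺ γδ plus αβ CD4 and CD8 cells), they are
treated as one reference group.

## Cohort scoring and outcome association

Because the original single-sample enrichment method is an external tool,
the package uses a self-contained rank-percentile score: within each sample
genes are ranked, and the score is the mean rank percentile of the
signature genes. The score depends only on within-sample ranks, hence is
invariant to any strictly increasing per-sample transform — the property
the tests assert. Scores feed a median split (strictly above the median is
"high"; ties and the odd middle sample are "low"), Kaplan–Meier curves and
a log-rank test after administrative censoring at 60 months (a five-year
analysis window), and a rank-sum comparison by clinical response. Results
are therefore method-qualified: they preserve the analysis logic, not the
numerical output of the external scorer.

## Synthetic data: what it does and does not emulate

`simulate_repertoire()` plants clone sizes (explicit or power-law with
exponent 2.5 on sizes 1–30), copies one gamma and one delta nucleotide
sequence per clone to all member cells, draws delta V genes from a usage
mixture whose defaults reflect a Vδ1-dominated tumor repertoire with a
substantial Vδ2 and hybrid component (Vδ1 36%, Vδ2 28%, Vδ4 13%, Vδ5 7%,
Vδ6 7%, Vδ3 6%, Vδ7 3%), and injects noise as unproductive contigs (a stop
codon planted in the CDR3) and orphan-chain cells. CDR3 amino acids are the
standard-table translation of the junction, keeping nucleotide and protein
views consistent for network tests.

`simulate_expression()` draws negative-binomial counts around cluster-level
log means; Vδ marker genes are near-silent off-cluster, and signature genes
carry exactly the configured log shift in the signature-bearing
subpopulation (and no extra cluster wiggle, so the zero-effect null is
exactly flat). Batches, when requested, add per-gene log shifts and are
assigned randomly to avoid confounding with clusters.

`simulate_cohort()` gives each sample a planted signature fraction
(uniform), shifts signature-gene expression proportionally, and draws
exponential survival with log-hazard linear in the standardized fraction
(median 24 months at the mean — a realistic advanced-cancer figure),
independent exponential censoring calibrated to the configured rate, and
Bernoulli response with logit linear in the same covariate around a 30%
baseline response rate.

None of the generators simulate sequencing reads, doublets, ambient RNA,
or batch effects beyond additive shifts; passing recovery tests therefore
demonstrates correctness of the analysis logic under the stated generative
model, not robustness to every artifact of real single-cell data.

## Numerical choices and degenerate inputs

Empty contig files return empty tables with a warning; missing mandatory
columns fail naming the column. An all-zero-score cohort median-splits to
all-low with a warning. Networks for patients with no eligible cells warn
and are omitted. Gini of an empty or non-positive vector is an error, as is
a Kaplan–Meier fit on empty input or a log-rank test with an empty group.
All simulators take a single integer seed; the pipeline fans one global
seed out to per-stage seeds by fixed offsets so stages are individually
reproducible.

## Problem sizes

The test suite and acceptance script run on scales chosen to make each
property measurable quickly: repertoires of 50–500 cells, expression
matrices of 300–500 cells by 400–600 genes, cohorts of 100–300 samples,
1,000 replicates for null calibration of the median-split log-rank test,
and a 400-cell demo pipeline for determinism checks. The pipeline itself
has no scale assumptions beyond memory; the demo default is 2,000 cells.

## Known limitations

The Leiden implementation clusters a plain kNN graph (unweighted, union of
directed neighborhoods); shared-nearest-neighbor weighting is not
implemented. The rank-sum DE uses the normal approximation throughout, which
is standard for single-cell group sizes but approximate below ~10 cells per
group. The cohort score is a rank-based substitute for external enrichment
tools and will not numerically match them. Gamma-chain networks are not
built (delta only), and no Shannon/Simpson diversity suite is included
beyond the Gini coefficient.
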