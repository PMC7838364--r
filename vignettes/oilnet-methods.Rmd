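---
title: "Methods: cross-species co-expression analysis of seed-oil biosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species co-expression analysis of seed-oil biosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oilnet)
```

`oilnet` links interspecific variation in seed-oil unsaturation to
expression shifts of pathway genes — in particular the duplicated FAD2
and FAD3 desaturases of the 18:1 → 18:2 → 18:3 cascade — through a chain
of statistics whose every step is defined here: the model, its
assumptions, the defaults, and what the synthetic tests do and do not
demonstrate.

## Fatty-acid statistics

Compositions are **mass fractions** of total fatty acids (GC-MS percent
composition against an internal standard is the expected upstream
measurement; molar handling is out of scope and the mass-fraction
assumption is stated here once). Desaturation efficiencies quantify the
proportion of available substrate converted to downstream products:

- omega-6: DE₆ = (18:2 + 18:3) / (18:1 + 18:2 + 18:3)
- omega-3: DE₃ = 18:3 / (18:2 + 18:3)

Both are part-of-whole ratios, hence in [0, 1] whenever defined. A zero
denominator makes the quantity *undefined*; `oilnet` reports `NA`, never
0 or ∞, so downstream means and comparisons cannot silently absorb a
degenerate sample. The same convention covers MUFA:PUFA with no PUFA and
per-stage stoichiometry r² under zero variance.

qPCR relative expression is the textbook 2^−ΔΔCt with
ΔCt = Ct(target) − Ct(reference); the implementation is invariant to a
shared shift of sample and calibrator ΔCt, which the tests assert.

Oil-accumulation summaries flag the stage of maximal oil content and the
onset of rapid accumulation: the first stage whose increment exceeds
`onset_frac` (default 0.1) of the range of the stage-mean series. A flat
series has no onset; a single replicate reports `NA` standard errors
rather than zero.

## Expression processing

**FPKM.** `fpkm = count · 10⁹ / (length_nt · total_count)`. The package
starts from count or FPKM matrices; read alignment and quantification
are upstream of its interface.

**Transcript collapsing.** Assemblies of non-model species carry
near-identical transcripts. Pairs at identity ≥ 0.90 and coverage ≥ 0.80
(both configurable) are linked; connected components (single linkage —
deterministic, unlike order-dependent greedy incremental clustering)
become clusters, each contributing the element-wise sum of its members'
expression under the longest member's id. Column sums are preserved
exactly.

**Differential-expression screen.** A deliberately assumption-light
stand-in for parametric count models: the statistic is the difference of
group means of log2(x + 1) (pseudocount 1 FPKM stabilises fold-changes at
zero), and significance comes from shuffling group labels. Two design
choices matter:

1. *The null pool is shared across genes.* With three replicates per
   group a per-gene label shuffle has at most 20 distinct values, so no
   single gene could ever reach q < 0.05. Pooling the permutation
   statistics of all genes yields fine-grained p-values and is calibrated
   under a homogeneous null — the suite verifies a 3–7 % type-I rate at
   α = 0.05 over 5,000 null genes and KS-level uniformity.
2. *Shuffles that reproduce the observed grouping (or its complement)
   are rejected.* Such shuffles re-create every true effect inside the
   null pool; with n = 3 vs 3 they would impose an artificial floor of
   about 0.1 on the adjusted q of any genuine signal. Excluding them does
   not change the null distribution under the null hypothesis (no split
   is special when there is no effect), so calibration is unaffected.

Benjamini–Hochberg adjustment with a configurable threshold (default
q < 0.05) yields the `is_de` flag. The upstream study screened with a
count-noise model whose cut-offs are unpublished; these defaults are the
package's own and are recorded in every run manifest.

**Profile clustering.** Per-gene stage means are z-scored — shape, not
level, should drive cluster identity — and clustered agglomeratively with
average linkage on 1 − Pearson distance, cut to exactly *k* groups
(default use case: ten dynamics clusters of stage DEGs).

**CV stability.** Reference-gene candidates are ranked by coefficient of
variation (sample sd / mean) across all samples, ascending, ties broken
by gene id, undefined (zero-mean) CVs last.

## Weighted co-expression networks

Built from scratch on log2(x + 1) expression (the scale on which FPKM
correlations are conventionally computed; the pipeline applies the
transform before `correlation_matrix()`):

- **Adjacency**: a_ij = ((1 + r_ij)/2)^β. This mapping is inherently
  *signed* — perfect anti-correlation maps to 0, not 1 — and is adopted
  as printed; no unsigned/hybrid variants.
- **TOM**: TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 −
  a_ij), k_i = Σ_{u≠i} a_iu, diagonal forced to 1. The implementation is
  one matrix product; the test suite pins it to a brute-force triple-loop
  oracle at 10⁻¹⁰ on random 40-gene instances.
- **Modules**: average linkage (the conventional companion of TOM
  dissimilarity) on 1 − TOM, cut *statically* at `cut_height` with
  branches below `min_module_size` (default 30) left unassigned. This is
  a documented simplification of dynamic tree cutting: deterministic and
  sufficient for planted-module recovery.
- **Eigengenes**: the leading right-singular vector over samples of the
  gene-standardised module submatrix, unit norm, sign-anchored to the
  module mean profile (largest-magnitude entry positive in the exactly
  symmetric case). Modules whose eigengenes correlate ≥
  `merge_correlation` (default 0.75) merge transitively.

**Choice of β and cut height.** Two defaults here are the package's own,
decided after examining the behaviour of the estimator on the synthetic
design (15 samples, 500 unstructured genes, three planted modules at
within-correlation 0.8):

- With so few samples the scale-free fit curve is nearly flat (maximum
  r² ≈ 0.65–0.78 across β = 2…20, never reaching the conventional 0.8
  target), so automatic selection degenerates to an unstable argmax that
  oscillates between low and high powers; low powers let chance
  correlations (sd ≈ 1/√14 ≈ 0.27 per pair) corrupt module detection.
  The pipeline therefore defaults to the field's standard fixed power
  for signed networks below 20 samples, **β = 18**. `pick_beta()` —
  smallest β whose scale-free fit (r² of the log-frequency vs
  log-connectivity regression over 10 binned connectivities) reaches
  `r2_target`, argmax with a fallback flag otherwise — remains available
  via `run_config(beta = NULL)`.
- The static cut defaults to dissimilarity **0.93**: unstructured genes
  agglomerate at 1 − TOM ≳ 0.95 in sparse high-power networks, while a
  cut tied to the top of the dendrogram (e.g. 0.99 of the maximum merge
  height) sits inside that zone and attaches chance-correlated
  background to module branches, degrading recovery below the package's
  own acceptance bar.

Both values are configuration, printed in the manifest, and the
sensitivity is easy to re-examine (`cut_modules(tom, cut_height = …)`).

## Oil-module selection and validation

Modules containing pathway seed genes (core fatty-acid-synthesis
enzymes) whose eigengene correlates ≥ `pattern_correlation` with the
seed-richest module's eigengene are united into the oil-biosynthesis
module. Validation is two-fold:

- **Permutation robustness** (default 5,000 draws, judged at p < 10⁻³):
  observed mean off-diagonal TOM within the module against the same
  statistic on random equal-size gene sets. The permuted unit is the
  *gene set*, not the expression values — module cohesion is the
  quantity under test. The add-one rule p = (1 + #{null ≥ obs})/(B + 1)
  keeps p ≥ 1/(B + 1). A median variant of the statistic is available.
- **Hypergeometric validation** (judged at p < 10⁻⁶): upper tail of the
  overlap between module and annotated set against a background of N
  genes. The same engine, applied over a caller-supplied term → genes
  map with BH correction, doubles as the enrichment analysis; ontology
  retrieval and term propagation are out of scope.

## Orthology

Reciprocal best hits: (a, b) is a pair iff each is the other's unique
top-scoring cross-species hit; identity breaks score ties, and genes
still tied after that are disqualified — ambiguous orthology should not
seed one-to-one cross-species claims. Orthogroups are connected
components of the hit graph after per-query score normalisation, with a
floor at 0.5 of each query's own best score; singletons are emitted, so
the output partitions every gene the table mentions. This is a
documented stand-in for phylogeny-aware orthogroup clustering, whose
parameters are not reproducible here; the package consumes hit tables
and never runs an aligner.

## Cross-species conservation

A focal-species oil-module gene is *conservatively co-expressed* when
its orthogroup contains oil-module members of **every** other species —
any-module membership of the ortholog suffices (the weaker reading;
same-module identity is not required). The intersection with
interspecific DEGs gives the candidate genes explaining the oil
phenotype difference. The containment chain
conserved-and-DE ⊆ conserved ⊆ focal module is asserted on every report.
Desaturase anchor neighbourhoods (`fad_neighbors()`) default to a TOM
floor at the network's 99th percentile, with a top-k alternative;
cross-species consensus is computed at orthogroup resolution.

## Expression stoichiometry

Per species and stage, each pathway gene's fraction of the summed
fatty-acid-synthesis + TAG-assembly transcripts, replicates averaged
before fractions (a per-replicate mode exists); multiple transcripts per
enzyme are summed to the enzyme symbol first when a mapping is supplied.
Inter-species CV per gene **pools** the fractions of both species across
stages (sd/mean of the pooled vector; the alternative — averaging
per-stage CVs — is not used, and the choice is stated here). Per-stage
cross-species r² is the squared Pearson correlation of the two fraction
vectors, symmetric in species order and invariant to global rescaling of
either expression matrix.

## The synthetic-data generator

The generator emulates the study design the analysis assumes: by default
**3 species × 5 stages (0, 40, 50, 60, 100 days after flowering) × 3
replicates**, 500 background genes, three planted modules (bell 60,
rising 40, falling 30 genes; the bell-shaped module is the oil module,
matching oil-accumulation dynamics), 25 four-fold interspecific DE genes,
two paralog duplications (one subfunctionalised child with a
stage-shifted profile, mimicking seed-specific vs vegetative desaturase
copies), and per-species desaturation targets contrasting an ALA-rich
focal species (DE₆ = 0.80, DE₃ = 0.60) with an oleic-rich species
(DE₆ = 0.40, DE₃ = 0.55).

Expression is generated on the log2 scale and exponentiated (positivity
and right skew of FPKM data). Module members share a latent per-sample
profile (stage shape + Gaussian wiggle); per-gene noise is calibrated as
sd² = Var(latent) · (1 − ρ)/ρ so the expected pairwise log-scale Pearson
correlation equals the module's target ρ — the Monte-Carlo tests confirm
0.75–0.85 at ρ = 0.8. Baselines are uniform on log2 [2, 8], lengths
uniform on [500, 3000] nt, replicate noise i.i.d. with no batch
structure. Noise level and dynamic range are calibration choices of the
generator, not inferences about any particular dataset.

Fatty-acid trajectories are built by **constructive inversion**: at the
final stage, 18:3 = T·DE₆·DE₃, 18:2 = T·DE₆·(1 − DE₃),
18:1 = T·(1 − DE₆) for a C18 pool T (default 0.90), the saturated
remainder split in fixed proportions; earlier stages interpolate
linearly from a uniform composition. The round trip through
`desaturation_efficiency()` is therefore exact to machine precision at
the final stage — a property, not an empirical finding.

Similarity tables give every true ortholog pair a top reciprocal score
(150–200) and decoys strictly lower scores (20–70, the clearly
sub-orthologous range of spurious local alignments), with identity and
coverage fields populated.

**What passing synthetic tests shows — and what it does not.** Recovery
at ARI ≥ 0.8, conserved-gene precision/recall ≥ 0.9 and calibrated error
rates demonstrate the machinery is correct and self-consistent under the
generative model. Real data differ: correlated background structure,
batch effects, heavy-tailed counts, incomplete orthology and assembly
artefacts are all absent from the generator, so synthetic performance is
an upper bound, not a forecast. Headline gene counts from any real study
depend on its sequencing data and are not reproduction targets.

## Numerical choices and degenerate inputs

- Permutation p-values use the add-one rule and are never 0.
- Equal CVs rank by gene id; equal best-hit scores fall to identity,
  then disqualify.
- Zero-variance genes abort correlation with the offending gene named;
  zero pathway sums, all-zero fatty-acid profiles, unordered stages and
  missing anchors are errors, not silent zeros.
- Average-linkage merge heights are sorted to remove floating-point
  inversions between tied merges before `cutree()`.
- Eigengene signs anchor to the module mean profile; in the exactly
  symmetric case (mean identically zero) the largest-magnitude entry is
  made positive.
- All stage seeds derive from the single run seed; rerunning a config
  writes byte-identical artifacts, and the manifest records every
  threshold plus md5 digests of every file.

## Problem sizes

The default study (632 genes/species × 15 samples × 3 species) runs the
full pipeline in ~2 s on one core; the test suite uses 150–632-gene
networks, 5,000-gene null calibrations and 20-seed Monte-Carlo loops,
chosen so properties are measured with comfortable margins at
interactive runtimes.

## Known limitations

- Static cut + minimum size is cruder than dynamic tree cutting on
  dendrograms with nested modules of very different tightness.
- The DEG screen's pooled null assumes roughly exchangeable gene-level
  noise; strong per-gene variance heterogeneity would mis-calibrate it
  (a variance-moderated statistic would be the next step).
- Orthogroup components merge aggressively through promiscuous hubs; an
  MCL-style inflation loop is a possible extension, off by default.
- No block-wise network approximation: matrices are dense, so the
  practical ceiling is tens of thousands of genes, not hundreds of
  thousands.
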