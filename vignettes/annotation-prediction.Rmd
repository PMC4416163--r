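---
title: "Predicting gene function annotations with latent semantic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene function annotations with latent semantic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golsa)
library(Matrix)
```

## The problem

Gene Ontology (GO) annotation databases are incomplete: curation is slow
and expensive, while the underlying biology keeps being discovered. Given
a snapshot of known gene–term annotations, **golsa** ranks the *absent*
gene–term pairs by how strongly they are implied by the co-occurrence
structure of the known ones, producing a prioritized list of candidate
annotations for curators and experimentalists.

The package treats the annotation set like a document–term corpus: genes
are "documents", GO terms are "words", and latent-semantic machinery
(truncated SVD, a cluster-refined variant, and a probabilistic topic
model) fills in plausible missing entries.

## From a corpus to the annotation matrix

Direct annotations are made to the most specific applicable term, but the
ontology's true-path semantics imply every ancestor term too. The pipeline
therefore **unfolds** the corpus — each annotation (g, f) is propagated to
all ancestors of f — before building the binary matrix `A` (rows = genes,
columns = terms). Propagation follows both `is_a` and `part_of` edges;
those are the two relation types that carry the sub-typing/partition
semantics of the GO DAGs, and other relationship types (e.g. `regulates`)
are ignored at parse time.

After unfolding, columns annotated to fewer than `L` distinct genes are
**pruned** (default `L = 3`, the value used throughout the reported
experiments): terms this rare cannot contribute co-occurrence signal and
only inflate the computation. Pruning is a single pass applied before the
final sweep that removes genes left without annotations; iterating it
could not change any count, because pruning removes columns while the
zero-row sweep happens last. The strict reading `< L` of the pruning rule
is implemented; callers preferring the inclusive variant can pass `L + 1`.

All three namespaces are processed jointly by default (matching how the
benchmark datasets combine BP+CC+MF); a `namespace` argument restricts to
one sub-ontology.

## TF–IGF weighting

The binary matrix can be replaced by a weighted one before model fitting.
The two statistics mirror TF–IDF, adapted to the annotation domain:

* **TF(g, f)** = 1 + the number of descendants of *f* (among the matrix
  columns) annotated to *g*. A general term supported by many annotated
  descendants is more relevant for that gene than a term carried by a
  single direct annotation. Descendants are counted among post-pruning
  columns only, since TF is defined on `A`.
* **IGF(f)** = ln(|G| / n_f), with n_f the number of genes annotated to
  *f*. Ubiquitous terms (near the root) get weight 0; a term annotated to
  a single gene gets the maximum ln |G|.

A schema is a three-letter code: local (`N` = TF, `A` = augmented,
0.5 + 0.5·TF/maxTF over the gene's annotations), global (`T` = IGF,
`N` = none), normalization (`N` = none, `M` = divide each row by its
maximum). The combinations reported as useful are `NTN`, `NTM` and `ATN`;
`none` keeps the binary matrix. Terms annotated to every gene have
IGF = 0 and produce all-zero columns under `NTN`/`ATN`; they are kept
(the formulas say so), and every predictor tolerates zero columns.
Row-max normalization uses true division, so the maximum of each nonzero
row is exactly 1, not 1 up to rounding.

## The three predictors

**tSVD / LSI.** With `W = U S Vᵀ`, the reconstruction
`Ŵ = W V_k V_kᵀ` projects each gene profile onto the span of the top-k
right singular vectors — the directions of dominant term co-occurrence.
Singular-vector sign indeterminacy is resolved by forcing the
largest-magnitude entry of each right singular vector positive, so
results are reproducible across LAPACK backends.

**SIM.** tSVD is linear, so sparsely annotated genes receive
systematically smaller reconstructed scores than heavily annotated ones.
SIM counteracts this bias with a soft clustering step: each of the first
`C` left singular vectors u_c defines cluster memberships; per cluster, a
reweighted term-correlation matrix `T_c = Wᵀ diag(u_c) W` is
eigendecomposed and truncated to k columns, and each gene is scored by
whichever model (including the global c = 0 one) reconstructs its profile
with the smallest L2 error, ties going to the global model. The c = 0
correlation matrix is `T = WᵀW` — whose eigenvectors are exactly the
right singular vectors of `W`. Eigenvectors are ordered by *signed*
eigenvalue, non-increasing (the `T_c` for c ≥ 1 can be indefinite);
ordering by magnitude is available via `sort_by_magnitude = TRUE`. The
per-cluster truncation uses the same k as the global model. With `C = 0`,
SIM is *exactly* tSVD, and its output is labeled accordingly.

**pLSAnorm.** The aspect model posits latent topics t with
`P(f|g) = Σ_t P(f|t) P(t|g)`, fitted by EM on the log-likelihood
`ℓ = Σ W(g,f) log Σ_t P(f|t)P(t|g)` from a seeded random
initialization (the standard EM updates for this likelihood are used).
Since each `P(·|g)` sums to 1, genes with many plausible terms dilute
their scores; the *norm* step divides each gene row by its maximum so
every gene's top candidate scores exactly 1, restoring comparability in a
global ranking. EM stops when the relative likelihood improvement falls
below `tol` (default 1e-6) or after `max_iter` (default 200) iterations;
both are exposed, as is the seed (same seed, bitwise-identical fit). EM
reaches a local optimum only — different seeds can give different models.

Latent dimensions default to `k = 500` components/topics and `C = 3`
clusters, the settings under which the methods were benchmarked; both are
clamped to the matrix dimensions with a warning, so toy inputs work.

## Evaluation

**Windowed ROC.** Thresholding `Ŵ` at τ against the input `A` yields
four classes: AC (A=1, score > τ), AP (A=0, score > τ), AR (A=1,
score ≤ τ), NAC (A=0, score ≤ τ); prediction uses strict `>`, so ties at
τ count as negatives. The curve plots ACrate = AC/(AC+AR) against
APrate = AP/(AP+NAC) over all τ. Only the window APrate ∈ [0, 0.010]
is scored — the region of the few best-scoring candidates, which are the
ones a curator would look at. The reported `auc_percent` is the
trapezoidal area over the window divided by the window width, times 100:
under this normalization a reconstruction identical to the input scores
exactly 100, and an anti-correlated one scores 0. The τ sweep includes
sentinels beyond the score range so the curve always starts at (0, 0) and
ends at (1, 1); the area is integrated along the τ-ordered path, so
vertical jumps contribute nothing. A high windowed AUC means the output
closely mirrors the input; it is a dissimilarity diagnostic, not a proof
of prediction quality, which is why the version comparison below exists.

**Version comparison.** A model is trained on the curated part (evidence
∉ {IEA, ND}) of an older corpus; its top-500 candidates are then looked
up in (a) the same corpus's computational-only annotations (`cmp`), (b) a
newer corpus version with any evidence (`Uany`), and (c) the newer
version with curated evidence (`Ucur` ⊆ `Uany`, the most reliable
confirmation). A pair counts toward `cmp` only when *all* its old
evidence codes are computational — otherwise it would have been in the
training set and could not be a candidate. Matching is done on unfolded
corpora, so predicting a general term is credited when the update
annotates any of its descendants (`unfold_updated = FALSE` disables
this). These percentages are lower bounds: a candidate absent from the
update may simply not have been discovered yet.

**Dataset statistics.** `dataset_stats()`/`annotation_delta()` report the
annotation growth Δ = a_new − a_old and Δ% = Δ/a_old·100 between corpus
versions. Δ% is truncated toward zero at two decimals; that is the
convention under which the published GPDW snapshot tables (shipped in
`inst/extdata/gpdw_annotation_counts.tsv`) are reproduced exactly.

## Synthetic data: what it emulates and what it does not

`make_ontology()` grows a rooted random DAG level by level (each term has
1–2 parents in the previous level, the second with probability 0.2, which
creates diamond motifs); `make_corpus()` plants `n_blocks` gene modules,
each owning the leaf terms of a distinct depth-1 subtree. Module genes
carry each owned leaf with probability `block_density` (curated evidence
IDA/IMP/ISS), plus uniform off-module noise at `noise_rate` (evidence
IEA). A `holdout_fraction` of curated annotations exists only in the
"updated" corpus, emulating database growth between releases; these
masked pairs are the recoverable ground truth. Defaults — 200 genes, 60
terms, 5 blocks, density 0.8, noise 0.02, holdout 10% — are sized so that
a full multi-seed evaluation runs in seconds while the planted rank
structure (≈ one latent direction per block) is clearly recoverable at
`k = 5`.

The generator writes real OBO and GAF files, so synthetic runs exercise
the actual parsers. It does *not* reproduce GO's topology statistics,
organism-specific annotation depth distributions, or correlated
(non-uniform) annotation noise; a predictor passing the recovery tests
here is validated for mechanics and ranking behavior, not for its
absolute precision on real corpora. `mask_holdout()` performs the
matrix-level analogue: it removes only "leaf-most" entries (those with
TF = 1, i.e. no annotated descendant), so the masked matrix remains a
valid unfolded matrix.

## Numerical choices and edge cases

* SVD/eigen sign fixing as above; candidate rankings break score ties
  lexicographically by gene then term (C-locale radix order), making
  output files byte-reproducible.
* SIM's argmin over cluster models allows a tiny absolute slack (1e-18 on
  squared distances) so that exact ties — e.g. every model reconstructing
  perfectly at full rank — resolve to the global model rather than to
  floating-point noise.
* pLSA requires a strictly positive row sum per gene (a gene with no
  weight mass has no likelihood contribution and is reported by name);
  log-likelihood of a zero-probability positive-weight entry returns
  -Inf with a warning rather than an error.
* Degenerate inputs fail fast with classed errors: all-zero matrices for
  tSVD, all-ones/all-zeros matrices for the ROC, empty corpora for matrix
  building; the command-line wrapper maps these classes to exit codes
  (2 configuration, 3 input/parse, 4 numerical).

## Worked example

```{r example}
spec <- synthetic_spec(seed = 42)
graph <- make_ontology(spec)
corpora <- make_corpus(graph, spec)

run <- predict_annotations(graph, corpora$old, method = "sim",
                           schema = "NTN", k = 5, clusters = 3, L = 3)
head(run$result$ranking)

roc <- roc_curve(run$A, run$result$scores)
roc$auc_percent

version_compare(run$result$ranking, corpora$old, corpora$updated, graph,
                n_top = min(500, nrow(run$result$ranking)))
```

## Known limitations

* Only `is_a`/`part_of` propagation; `regulates`-type relations and
  cross-namespace links are out of scope.
* Gene identifiers are taken verbatim from the GAF; no cross-database ID
  mapping is attempted.
* The SVD is computed densely; matrices in the tens of thousands of rows
  work but are not the design point, and no sparse/randomized SVD backend
  is provided.
* Windowed-AUC normalization (area / window) is this package's documented
  convention; other tools may normalize ROC areas differently, so compare
  AUC values across tools with care.
* EM for pLSA finds local optima; rankings can vary across seeds, and no
  multi-start heuristic is built in.
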