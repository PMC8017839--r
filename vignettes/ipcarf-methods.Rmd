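---
title: "Methods and design notes for ipcarf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ipcarf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipcarf)
```

This vignette documents the model behind `ipcarf`, the assumptions it
makes, the tunable parameters and their defaults, the numerical choices,
and what the synthetic benchmark can and cannot demonstrate.

## The prediction problem

Given a binary association matrix $A \in \{0,1\}^{n \times m}$ over $n$
lncRNAs and $m$ diseases, the task is link prediction: score every zero
cell by the probability that the association exists but has not yet been
observed. The working premise is guilt by association — similar diseases
tend to involve similar lncRNAs — so the pipeline is built entirely from
similarity structure.

## Disease semantic similarity

Two models are computed on the disease ontology DAG.

**Contribution-decay model.** A disease $D$ collects credit from every
term $t$ in its ancestor closure $\mathrm{DAG}(D)$:

$$C_D(D) = 1, \qquad
C_D(t) = \Delta \cdot \max\{\, C_D(t') : t' \text{ child of } t \text{ in } \mathrm{DAG}(D) \,\},$$

so with a uniform attenuation factor $\Delta$ a term's credit is
$\Delta^h$ with $h$ the least number of generations separating it from
$D$. With semantic value $G(D) = \sum_t C_D(t)$, similarity is the shared
credit normalised by the total:

$$\mathrm{sim}(D_1, D_2) =
\frac{\sum_{t \in \mathrm{DAG}(D_1) \cap \mathrm{DAG}(D_2)} C_{D_1}(t) + C_{D_2}(t)}
     {G(D_1) + G(D_2)}.$$

This is symmetric, bounded by 1, and equals 1 exactly on the diagonal.
Two useful closed forms, both covered by tests: siblings under a common
parent score $\Delta/(1+\Delta)$, and diseases in disjoint ontology
components score 0. The recursion restricts "children" to the closure:
children outside $\mathrm{DAG}(D)$ never lie on a path back to $D$ and
carry no credit. `delta` defaults to 0.5, the conventional value in this
method family; larger values flatten the decay and raise all
similarities.

**Information-content model.** The second model is specified only by
reference in the method lineage; we implement the standard
information-content variant and flag it as an interpretation. A term's
credit is $-\log(n_t/N)$, where $n_t$ of the $N$ diseases under study
contain $t$ in their closure, plugged into the same ratio form. Terms
shared by every disease (e.g. the root) have zero information content and
contribute nothing; the diagonal is set to 1 exactly, and a pair whose
only shared terms carry zero information scores 0. By default the two
model matrices are averaged element-wise (`combine_similarity`); both
single-model options are exposed because the choice is genuinely open.

## Gaussian interaction profile kernels

Disease profiles are columns of $A$, lncRNA profiles rows — the
orientation is a convention, fixed here and used consistently. The
bandwidth is the reciprocal mean squared profile norm
($k_{dis} = m / \sum_i \lVert A_{\cdot i} \rVert^2$, analogously
$k_{lnc}$), so the kernel scale adapts to catalogue density; the kernel
is $\exp(-k\,\lVert x - y \rVert^2)$. The bandwidth is positive by
construction; an all-zero matrix has no defined bandwidth and is
rejected rather than patched, because an empty profile also carries no
usable label information. Integration with the semantic matrix is the
element-wise mean where both diseases have ontology coverage and the
kernel value alone elsewhere — the dominant convention in this family,
chosen because it degrades gracefully when the ontology misses diseases.
An lncRNA functional-similarity matrix, when supplied, is averaged in the
same way; none is computed internally because no standard definition
exists without external annotation data.

## Pair features and negative sampling

The feature vector of a pair $(l, d)$ concatenates $l$'s row of the
integrated lncRNA similarity matrix and $d$'s row of the integrated
disease similarity matrix (width $n + m$). This is the minimal encoding
in which both the lncRNA's and the disease's neighbourhood structure are
visible to the classifier.

Training uses all known positives and `neg_ratio` (default 1, i.e.
balanced) times as many negatives sampled uniformly without replacement
from the zero cells. Balance is the usual choice under an AUC protocol;
no reliable-negative heuristic is applied, so some sampled negatives are
necessarily unobserved positives.

A caveat stated once and prominently: similarity matrices are computed
from the full association matrix, including any cell later scored or held
out in cross-validation. The kernel profiles therefore carry a faint
transductive imprint of test labels. Recomputing GIP per fold with masked
cells would remove it at substantial cost; we follow the method's design
and document the optimistic bias instead.

## The IPCA reduction

The reduction operates on the feature covariance
$C = X_c^\top X_c/(r-1)$ of the centred sample matrix $X_c$ (rows =
samples; centring subtracts column means):

1. compute each covariance column's $\ell_2$ norm and keep the largest
   $k$ columns (ties broken towards the smaller index, making selection
   deterministic);
2. QR-orthonormalise the selected columns into a basis $Q$ of the
   dominant subspace;
3. take the SVD of the compressed covariance $Q^\top C Q$ and retain the
   top `n_components` directions, mapped back through $Q$.

Taking the orthonormal factor $Q$ as the subspace and decomposing
$Q^\top C Q$ is the reading under which the final step preserves the
covariance spectrum, consistent with the randomized-SVD family this
construction paraphrases; at $k = p$ the result provably coincides with
exact PCA, and the test suite checks the recovered eigenspaces to
principal angles below $10^{-8}$ (measured with the sine-based
Björck–Golub formulation, since the arccosine form cannot resolve angles
below $\sqrt{\varepsilon} \approx 10^{-8}$).

Numerical choices: the compressed covariance is explicitly symmetrised
before the SVD; each basis column's largest-magnitude entry is made
positive so repeated fits are bit-identical; if the data's numerical rank
(singular values above $10^{-12}$ of the largest) is below the requested
`n_components`, the fit falls back to the available rank — silently for
the automatic default, with a warning when the caller asked for more.
Constant input yields zero variance and zero projections. Defaults,
chosen because the method's source gives none: `n_components`
$= \min(64, p)$ and $k = \min(2\,\text{n\_components}, p)$ — 64
components retain essentially all practically relevant variance of
similarity-row features at these matrix sizes, and doubling $k$ leaves
headroom for the column-selection step to matter.

## Classifier and evaluation

The classifier is a probability random forest (`ranger` back-end) behind
`train_rf()`; a single integer seed fixes bootstrap sampling and tree
construction, so fits are reproducible. Bit-level identity across forest
implementations is not promised — only statistical agreement — which is
why all performance claims are cross-validated rather than tied to one
fit. The forest size `num_trees` (default 1500) is the one hyperparameter
that matters empirically; `grid_search_trees()` evaluates a grid (default
$\{100, 500, 1000, 1500, 2000, 2500\}$) by shared-fold mean AUC with ties
going to the smallest forest.

Cross-validation is stratified at the pair level (the common reading;
lncRNA-level folds would test a different, harder generalisation), 10
folds by default. Within each fold the centring, the IPCA basis and the
forest are all fitted on the training portion only. Metrics follow the
standard confusion-matrix formulas; undefined ratios (zero denominators)
return `NaN` and are skipped in aggregates rather than raising, so a
degenerate fold cannot abort a run. The default F1 is the harmonic mean
of precision and recall; `f1 = "printed"` substitutes accuracy for
precision, replicating a formula variant that circulates in the applied
literature, kept as an explicit option for comparability. ROC curves
sweep all distinct score thresholds with ties grouped; the trapezoid AUC
is verified against a brute-force pairwise-concordance oracle in the
tests.

## The synthetic benchmark

`simulate_lda_data()` generates the full study environment: a random
rooted ontology DAG (one root, every term linked to 1–2 shallower
parents, diseases mapped to leaf-biased terms) and a planted-block
association matrix — lncRNAs and diseases partitioned into `n_clusters`
blocks, within-block pairs associated with probability `signal`, others
with probability `noise`. Block structure is exactly the "similar
diseases share lncRNAs" premise, which makes it the right minimal
generative model for this pipeline and gives a tunable ground truth.

Defaults: 80 lncRNAs × 40 diseases, 4 blocks, signal 0.6, noise 0.05,
ontology of 60 terms with depth 4. The matrix size and density yield
roughly 600 positives — small enough that the full test suite runs in
about two minutes on one CPU, large enough that fold-level AUC estimates
are stable to a few hundredths; the ontology size gives each disease a
non-trivial ancestor closure without dominating runtime.

What the generator does **not** emulate: the heavy-tailed degree
distributions of real catalogues, correlation between ontology position
and association blocks (the simulated ontology is independent of the
blocks, so the semantic channel contributes no signal here — it is
exercised, not stressed), annotation biases, and catalogue scale. Passing
benchmarks on this generator therefore demonstrates correctness of the
machinery and learnability of block structure, not real-data headline
performance.

One property of the block model deserves emphasis because it bounds every
benchmark number: conditional on block membership, cells are independent
Bernoulli draws, so no ranker can beat the block-membership oracle other
than through the transductive kernel imprint described above. At the
default signal/noise the oracle's expected AUC is about 0.84 — the
information ceiling of the benchmark itself. Observed cross-validated
AUCs just below (or, via the imprint, slightly above) that value indicate
a classifier extracting essentially all available signal, not a deficient
one; raising `signal` or lowering `noise` raises the ceiling, which the
learnability-monotonicity test exploits.

The masking-recovery check hides 10% of planted positives before any
similarity is computed, refits, and compares the scores of hidden pairs
with those of random never-associated pairs, pooling scores across seeded
repetitions into one one-sided rank-sum test. Pooling across refits mixes
slightly different score scales; with the observed effect sizes this
costs power but not validity, and keeps the statistic simple.

## Known limitations

* Prediction for a new pair reuses training-time similarity matrices; no
  transductive recomputation after masking (optimistic bias, above).
* The information-content semantic model is an interpretation of a
  method cited only by reference; results depending on it should be
  checked against `model = "model1"`.
* Diseases absent from the ontology silently fall back to kernel-only
  similarity; a warning-free design choice that callers can audit via the
  fitted model's `$coverage` field.
* lncRNA-level (cold-start) generalisation is not evaluated by the
  default pair-level folds.
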