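---
title: "Masked pathway networks and their attribution: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked pathway networks and their attribution: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frbinn)
```

## The problem and the model

Chronic inflammatory diseases split epidemiologically into cancer-prone
(CP-CID) and non-cancer-prone (NCP-CID) conditions. `frbinn` studies this
split with a four-class transcriptome classifier (cancer, CP-CID, NCP-CID,
normal) whose architecture is a biological prior: genes connect only to the
pathways they belong to, pathways only to their superpathways. The prior is
supplied as a GMT file plus a child/parent edge table and compiled into
binary masks $S^l \in \{0,1\}^{n_{l+1} \times n_l}$; the forward pass is

$$h^{(l+1)} = f\big((S^l \odot W^l)\,h^{(l)} + b^l\big), \qquad
\mathrm{pred} = \mathrm{softmax}(W_{out}\,h^{(out)} + b_{out}),$$

with $h^{(0)}$ the preprocessed expression vector. Because the Hadamard
product is applied in *every* forward pass, a masked weight is ineffective
at all times — no gradient trick or post-hoc projection is needed, and the
invariant survives any number of training steps (this is tested by
perturbing masked entries of a trained model). The output head is dense:
class logits may draw on every superpathway.

Assumptions worth stating: expression is non-negative and TPM-like; the
hierarchy is a layered DAG (entities in layer $l$ connect only to layer
$l+1$); every retained gene belongs to at least one pathway. Genes in the
expression matrix that belong to no pathway are dropped with a warning
rather than connected densely — connectivity is meant to encode known
relations only. Pathways without a parent are attached to a synthetic
`_ROOT` superpathway so that incomplete edge tables remain usable. Entity
order is lexicographic within each layer, making masks and every
downstream ranking bit-for-bit reproducible.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `epochs` | 500 | full passes of Adam over the training data |
| `batch_size` | 32 | mini-batch size |
| `lr` | 0.001 | Adam learning rate |
| `activation` | `"relu"` | hidden nonlinearity; `"tanh"` available |
| `m_ig`, `m_con` | 800 | path-quadrature steps for IG / conductance |
| `m_shapley` | 800 | model-query budget for Kernel SHAP |
| baseline | zero vector | attribution reference point (network-input space) |
| `k_folds` | 5 | stratified cross-validation folds |

The training defaults are the protocol the framework was designed around;
they are deliberately plain (no early stopping, no class weights, no
regularisation). The attribution step counts trade accuracy of the path
integral against runtime; at 800 steps the completeness identity
$\sum_i IG_i = F(x) - F(x')$ holds to a relative error below $10^{-3}$ on
the networks in the test suite.

Two choices deserve justification because the problem leaves them open:

- **Input transform.** Raw TPM spans orders of magnitude, so inputs are
  mapped through $\log_2(v+1)$ and per-gene z-scaling with *training-fold*
  statistics (constant genes get unit scale). The zero attribution baseline
  therefore corresponds to each gene at its training-cohort mean
  expression, and attributions measure the effect of a gene's deviation
  from that mean. Feeding raw or merely log-transformed values is possible
  (`preprocess = FALSE`) but makes the zero baseline a biologically
  implausible "no expression anywhere" state.
- **Attribution target.** Attributions target the pre-softmax logit of the
  chosen class (numerically stable and unsaturated); the softmax
  probability is available via `attribution_config(target = "prob")`.
  Logits are only defined up to a shared shift, which is part of why
  attribution mass can appear on genes that are evidence *against*
  competing classes (see Limitations).

## Numerical choices

- **Quadrature.** The classic IG sum is a right-endpoint Riemann rule;
  Gauss–Legendre nodes on $[0,1]$ are the default because they converge
  much faster for smooth activations, and both schemes coincide on linear
  models at any step count (tested). Conductance uses the same nodes: at
  each path point the output gradient at the neuron (reverse sweep) is
  multiplied by the neuron's directional derivative along $x - x'$
  (forward sweep), which makes the per-layer sum telescope to
  $F(x) - F(x')$ exactly in the continuum.
- **Kernel SHAP.** Coalition sizes are enumerated outside-in (all size-1
  and size-$(M{-}1)$ coalitions first) while the budget allows, the
  remainder sampled in complement pairs from the kernel's size
  distribution, every row weighted by the Shapley kernel
  $(M-1)/\binom{M}{s}s(M-s)$. The efficiency constraint is imposed by
  eliminating one coefficient from the weighted least-squares system, so
  $\sum_i \phi_i = F(x) - F(\mathrm{background})$ holds for every budget,
  and full enumeration reproduces exact Shapley values (tested against a
  brute-force average over orderings). The SHAP background defaults to the
  IG baseline (zero) for cross-method comparability; a training-mean
  background can be passed explicitly.
- **Initialization.** Glorot-uniform on unmasked entries, zeros elsewhere,
  fully seed-controlled; identical seeds give bitwise-identical fits.
- **Degenerate inputs.** Constant genes scale by 1; $x = x'$ attributes
  exactly zero; argmax ties resolve to the lowest class index; ranking
  ties break lexicographically by gene name (recorded in the object);
  min–max scaling of a constant score vector maps to zeros, so a
  degenerate method drops out of the composite score rather than
  dominating it.
- **Narrow ReLU networks.** Very small hierarchies (a handful of pathways
  feeding two or three superpathways) can collapse during ReLU training
  when every unit of a narrow layer goes silent; the `tanh` activation has
  no such failure mode and is recommended for toy-scale hierarchies. At
  realistic widths (tens of pathways) the default is robust.

## The synthetic cohort generator

The generator emulates the statistical skeleton the framework assumes: a
balanced four-class cohort; log-normal TPM-like marginals (per-gene log2
baseline $\sim N(4, 1.5^2)$); a known round-robin gene/pathway/superpathway
hierarchy; and, for each non-normal class, a planted set of marker genes
shifted by `effect_size` on the log2 scale against noise `noise_sd`. The
planted sets are pairwise disjoint and, because membership is dealt
round-robin, each class's markers span many pathways, so pathway-level
conductance has signal to find. The normal class is the unshifted baseline,
mirroring control cohorts. The frozen `strong_effect_preset()` —
200 genes, 20 pathways of 10 genes, 4 superpathways, 100 samples per class,
20 planted genes per class, effect 2.0 (a 4-fold change), noise 0.5,
seed 20250711 — is the package's canonical validation configuration: the
classes are cleanly separable and the planted truth is known exactly.

What the generator does *not* emulate: batch effects, library-size
variation, gene–gene correlation beyond the planted block structure,
dropout, heterogeneous effect sizes, or the marginals of any real cohort.
Passing tests on synthetic data therefore demonstrate correctness of the
algorithms and recoverability of planted signal under ideal conditions —
not performance on real transcriptomes.

Validation problem sizes: the unit-test networks use 24 genes / 6 pathways
/ 3 superpathways with 25 samples per class; end-to-end checks use the full
preset; the null-soundness check uses 50 samples per class over 5 seeds
with a 50/50 split and 100 epochs, where held-out weighted F1 stays at the
0.25 chance level.

## Design decisions on the analysis side

- Composite gene scores min–max scale each method's mean-absolute
  attribution to $[0,1]$ before summing, since IG and Shapley values live
  on different scales; the scaling rule is recorded on the result object.
- List agreement is the intersection fraction $|A_k \cap B_k|/k$ (a
  Jaccard variant is available), evaluated at $k = 10, 30, 50, 100$ by
  default.
- Top-fraction selection takes $\lceil 0.05\,N \rceil$ genes, so a short
  list never rounds to zero genes.
- The external semantic-refinement step is a pluggable deterministic
  predicate (`refine_genes()`), typically a keep-list file; it preserves
  ranking order among kept genes and reports drops. A live
  language-model adapter is out of scope by design — the pipeline stays
  fully reproducible offline.
- The disease-propensity rule is the strict disjunction
  (RR > 2) ∨ (HR > 2) ∨ (SIR > 1.4); boundary values are not prone, absent
  statistics contribute nothing, and diseases reported only with inverse
  cancer associations carry a protective flag that forces not-prone. The
  shipped nine-disease registry yields five NCP-CIDs and four CP-CIDs.

## Known limitations

- On the strong-effect preset, the trained network's one-vs-rest logits
  legitimately use *other* classes' markers as negative evidence — for a
  CP-CID sample, cancer and NCP-CID marker genes carry weights comparable
  to the CP markers' own. Mean-absolute-attribution rankings for two
  classes consequently share part of their head, and the cross-category
  top-20 intersection stays well above what the per-class planted truth
  alone would give. Relatedly, because 20 markers per class are redundant
  at effect 2.0, the converged network needs only a subset of them and
  leaves the rest with small weights, so the IG top-20 typically recovers
  two-thirds rather than all of a class's planted set. Both effects are
  properties of discriminative training on compact, strongly planted
  cohorts — the attribution machinery itself passes exactness,
  completeness and brute-force-Shapley oracles — and both shrink as the
  gene universe grows and the planted fraction falls.
- Attribution scores are model explanations, not effect sizes: a gene can
  rank highly because the model uses it, including as negative evidence.
- Kernel SHAP at 800 queries over 200 genes solves a 199-coefficient
  regression from 800 rows; individual scores are noisy even though
  top-of-list ranks are stable. Budgets below roughly `genes + 2` are
  refused in spirit (the design matrix degenerates) and should be avoided.
- The network is intentionally small and CPU-friendly; no GPU path, no
  hyperparameter search beyond the three training knobs, and no attribution
  methods beyond the three implemented.
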