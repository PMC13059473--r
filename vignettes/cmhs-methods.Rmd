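---
title: "cmhs: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cmhs: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MHC class I molecules present short peptides (8-12 residues) on the cell
surface; whether a peptide binds a given allele — summarized by its IC50
in nM — determines whether it can be seen by T cells. `cmhs` predicts the
normalized binding affinity `1 - log(IC50)/log(50000)` of an (MHC,
peptide) pair from two complementary views of the pair:

* a **sequence view**: per-residue BLOSUM50 substitution-score rows
  concatenated with protein-language-model-style embeddings, summarized by
  a multi-level CNN feature pyramid;
* a **structure view**: a heterogeneous graph whose MHC nodes carry the
  8-Angstrom Calpha contact graph, whose peptide nodes attach to the
  binding-site (pseudo-sequence) residues, processed by graph attention,
  cross-attention edge scoring, top-k edge-induced subgraph extraction and
  a dual-direction GCN.

The two views are aligned with a contrastive objective and fused by a
linear head into a sigmoid-capped regression output. A binder is defined
by the strict IC50 < 500 nM convention.

## Model components and their assumptions

**Sequence encoding.** Position i of a sequence contributes the BLOSUM50
row of its residue (width 20) plus an embedder vector (width `e`, 320 at
full scale). Peptides are padded to length 12 with zero rows and a mask.
The embedder is a pluggable contract with three implementations: a
deterministic seeded random projection of one-hots (the `stub`, used for
testing and desk-scale runs), a tiny one-head attention encoder whose
Q/K/V projections accept low-rank (LoRA) adapters `W + B A^T` with the
base frozen, and room for an external bridge. The stub preserves residue
identity information exactly (it is an injective linear code), so
desk-scale results measure the architecture rather than a pretrained
model's knowledge.

**Learnable embedding noise.** During training the peptide features
receive additive Gaussian noise with trainable per-feature mean and
log-sd (`sigma = exp(log sigma)` keeps it positive). Two designs are
plausible here — free trainable (mu, log sigma) vectors, or a small
network generating them from the input features; the free-parameter form
was chosen because it is the simpler model and directly interpretable;
the feature-conditioned variant was considered and deliberately not
built (two models of the same nuisance process would double the surface
for no testable gain at desk scale). Noise is applied to peptides only —
MHC features stay clean — and is the identity at inference.

**Feature pyramid.** Level 0 pools the raw encodings; level 1 pools one
CNN layer per track; level 2 pools the second MHC CNN layer with the
(single) peptide CNN layer. Pooling is a global masked max per channel:
it is length-invariant, which is what makes the output width a pure
function of the configuration. Kernels default to 5 (MHC) and 3
(peptide); channels default to the input width so that all three levels
share one per-level width.

**Structure branch.** Residue flexibility is predicted by the Gaussian
Network Model: the Kirchhoff (Laplacian) matrix of the contact graph is
pseudoinverted and its diagonal gives relative B-factors. The written
form `Gamma^{-1}` is singular for any graph, so the Moore-Penrose
pseudoinverse excluding zero modes is used — the universal GNM
convention; `k_B T / gamma` collapses to a single scale (default 1)
because only relative flexibility matters downstream. B-factors enter a
bounded sigmoid `sigma(B) = sigma_min + (sigma_max - sigma_min) /
(1 + exp(-k(B - B_m)))` that converts flexibility into cross-edge noise
sd; `B_m` defaults to the per-structure median, making the map
scale-free. Cross-edge noise has trainable mean `gain * (A - rowmean A)`
with `gain` initialized at 0 so training starts from the clean graph.

**Heterogeneous message passing.** The GAT runs on raw BLOSUM node
features (a deliberate shallow-graph-branch choice: embedder features
belong to the sequence branch only), with
self-loops so isolated nodes are well-defined and head-concatenation as
the default multi-head combination (the literal head-sum remains a
flag). Cross-attention scores every candidate (pseudo-position, peptide
position) edge and normalizes over peptide nodes per MHC node; per
peptide node the top-k (default 5; there is no canonical value, treat
it as a tunable) highest-scoring incident edges induce the
subgraph, ties breaking toward the lower MHC index so extraction is
deterministic. The selected scores form `A_mp`; `A_pm` is its
transpose-oriented twin, and the combined link matrix is their average.
Two GCN directions propagate peptide features into MHC nodes and GAT
outputs into peptide nodes through symmetrically degree-normalized
adjacencies; degrees are computed on `|A|` with a 1e-6 floor because
noise can produce non-positive entries. The two outputs live on
different node sets, so each is masked-mean-pooled to a graph vector
before the convex fusion `alpha * pool(Z_mp) + (1 - alpha) * pool(Z_pm)`
with `alpha = sigmoid(s)`, `s` trainable from 0.

**Contrastive alignment and loss.** Both branch summaries are projected
by `LayerNorm(ReLU(Z W + b))`, unit-normalized, and compared by cosine
similarity at temperature `tau = 1` (values below 1 are allowed but
warn, since they let diagonal similarities exceed 1 and the alignment
term go negative). The loss is `[sum_i (1 - S_ii) + sum_{i != j}
max(0, S_ij - margin)] / B^2` with margin 0.5, weighted `beta_cont =
0.1` against the MSE regression term (`lambda = 1`). Negatives are all
in-batch non-matching pairs. The regression head is
`sigmoid(linear(z))`, matching the normalized affinity range.

## Differentiation and training

No deep-learning framework exists in this R stack, so the package ships
a small reverse-mode autodiff engine on dense matrices (`R/autodiff.R`):
an intrusive linked-list tape of matrix ops with hand-derived adjoints,
checked against central-difference numerical gradients in the test
suite. Two deliberate gradient choices:

* **GCN degree normalization** treats the degrees as stop-gradients:
  gradients flow through the elementwise adjacency factor only. This is
  the standard behavior when adjacency is data; here the adjacency is
  partially learned, and the detached-degree adjoint keeps the operator
  scale stable.
* **Top-k extraction** is a hard, non-differentiable selection; the
  gradient flows through the *scores* of the selected edges (the usual
  straight-through-style treatment of discrete subset selection).

Training uses AdamW (decoupled weight decay), batch 32, seeded
shuffling, per-batch seeded noise draws and per-epoch evaluation-mode
validation loss. Within a batch, allele-level computation (MHC CNN
track, GAT, MHC-side cross-attention term) is built once per allele and
shared across that batch's samples — the DAG accumulates gradients from
all consumers, so sharing is exact; batches are grouped by allele by
default (`train$group_by_allele`) to maximize that sharing. At full
scale the optimizer defaults are lr 1e-3, weight decay 1e-2, 200
epochs, 5-fold cross-validation. The desk-scale `cmhs_small_config()`
(stub embedder width 32, CNN channels 32, 50 epochs) uses lr 3e-3 and
weight decay 1e-3: at 50 epochs the full-scale settings demonstrably
underfit (held-out SRCC ~0.55 against a ~0.79 ceiling on the synthetic
recovery task, improving monotonically with the larger steps). Both are
plain config entries.

## The synthetic world

The generator (`make_dataset()`) emulates the statistical structure the
model assumes, not protein physics:

* **Alleles**: one random ancestral sequence, each allele differing at
  `mutations_per_allele = 8` seeded sites — polymorphism concentrated on
  a shared scaffold. Default length 60 (the real preprocessing cap is
  300; 60 keeps one-CPU budgets while preserving MHC >> peptide).
* **Structures**: seeded self-avoiding random walks with 3.8-Angstrom
  steps (the Calpha virtual bond length), excluded radius 1 Angstrom,
  resampled until the 8-Angstrom contact density is in [0.02, 0.4]. A
  toy geometry: no secondary structure, no realistic B-factor scale.
* **Peptides**: uniform random, lengths 8-12.
* **Affinities**: a planted rule — fixed anchor positions scored by
  BLOSUM50 similarity against fixed pocket residues (a subset of the
  pseudo-positions), standardized over the panel, passed through a
  sigmoid with additive Gaussian noise, and mapped by
  `ic50 = 50000^(1 - a)` so that `normalize_ic50()` inverts the map
  exactly when noise is off. `noise_sd = 0.5` was calibrated so the
  rank-correlation ceiling (clean score vs noisy affinity) is ~0.79;
  the naive Gaussian formula overestimates it because the planted score
  is non-Gaussian.
* **Structure coupling** (off by default): an optional per-allele term
  proportional to standardized pocket contact counts, making part of
  the signal reachable only through structural features — used by the
  ablation tests.

A green end-to-end test therefore establishes that the implementation
can recover a planted, sequence-realizable binding rule at desk scale —
not that it reproduces published IEDB benchmarks, which require the
real corpus, real embeddings/structures and GPU-scale training.

## Numerical choices and degenerate inputs

* Softmax rows with empty support (an MHC node with no candidate edges)
  return zeros rather than NaN and are excluded from normalization.
* LayerNorm uses a 1e-5 variance floor; unit-normalization a 1e-12 norm
  floor with zero rows mapped to zero (and a warning at the public
  `similarity_matrix()` surface).
* Exactly-500 nM IC50 is a non-binder (strict inequality, the benchmark
  convention); the Spearman statistic is computed as Pearson on average
  ranks, which equals the printed `1 - 6 sum d^2 / (n(n^2-1))` formula
  when tie-free and stays defined under ties.
* Contact distances use a strict `< 8` Angstrom test; a pair at exactly
  8 is not a contact.
* Disconnected contact graphs warn and drop one zero mode per component.
* Sequences shorter than a CNN kernel are handled by "same" zero
  padding, never an error.

One caveat the ablation tests make visible: the structure-coupled term
is an allele-level offset, and allele identity is also visible to the
sequence branch under transductive splits, so the full-vs-sequence-only
margin measures inductive bias rather than exclusive information and
sits within seed noise at desk scale. The contrastive-alignment
comparison (full vs `beta_cont = 0`) is the more stable of the two.

## Known limitations

* The built-in embedders do not carry evolutionary knowledge; plugging a
  real protein language model in requires implementing the embedder
  contract against an external bridge.
* Peptide 3D coordinates are never modeled — structures exist for the
  MHC chain only; peptide nodes are sequence-featured and cross edges
  carry no geometric distances.
* The CLI trains single-threadedly; expect minutes, not seconds, for
  thousand-pair datasets.
* `gnm_bfactor()` returns relative flexibilities; absolute
  crystallographic magnitudes are out of scope.
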