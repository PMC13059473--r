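# cmhs

Multimodal prediction of MHC class I peptide binding affinity in R.

MHC class I molecules present peptides of 8–12 residues to T cells;
whether a peptide binds a given allele is summarized by its IC50 (nM),
conventionally normalized to `a = 1 − log(IC50)/log(50000)` and
binarized at the strict 500 nM binder threshold. `cmhs` predicts `a`
for an (MHC, peptide) pair by fusing two views of the pair:

* **Sequence branch** — per-residue features `X = [embedder ‖ BLOSUM50]`
  (the embedder is a pluggable contract: a deterministic stub, a tiny
  built-in attention encoder with low-rank adapters `W + BAᵀ` on its
  Q/K/V projections, the base frozen), summarized by a three-level CNN
  feature pyramid `S_final = [pool(X) ‖ pool(CNN₁) ‖ pool(CNN₂)]` with
  trainable Gaussian noise `ε ~ N(μ, diag σ²)` injected into peptide
  embeddings during training.
* **Structure branch** — a heterogeneous graph: MHC nodes joined by the
  8 Å Cα contact adjacency, peptide nodes linked to the binding-site
  (pseudo-sequence) residues. A Gaussian Network Model predicts residue
  flexibility, `B_i = (k_BT/γ)[Γ⁺]_ii` with `Γ` the contact-graph
  Kirchhoff matrix, which sets B-factor-guided cross-edge noise through
  a bounded sigmoid `g(B) = σ_min + (σ_max − σ_min)/(1 + e^{−k(B−B_m)})`.
  Message passing is GAT → cross-attention edge scores → top-k
  edge-induced subgraph extraction → dual-direction GCN → convex fusion
  `Z = α·pool(Z_mp) + (1−α)·pool(Z_pm)`.

The two branch summaries are projected with `LayerNorm(ReLU(·W + b))`,
aligned by a contrastive loss
`[Σᵢ(1 − S_ii) + Σ_{i≠j} max(0, S_ij − margin)]/B²` on the
temperature-scaled cosine similarity matrix `S`, fused linearly, and
regressed through a sigmoid head. The training objective is
`λ·MSE + β·L_cont` under AdamW. Because no deep-learning framework is
available in this R stack, the package includes a small tape-based
reverse-mode autodiff engine (`?ad_param`), validated against numerical
gradients in the test suite.

A first-class synthetic generator (`make_dataset()`) produces desk-scale
pMHC worlds — polymorphic allele panels, self-avoiding-walk structures,
and IC50 values from a planted, recoverable anchor/pocket BLOSUM50 rule
— so the entire pipeline is testable without downloads.

## Worked example

```r
library(cmhs)
ds <- make_dataset(synthetic_config(n_alleles = 4, n_peptides = 12,
                                    mhc_length = 40, n_pseudo_positions = 10,
                                    seed = 1))
ds
#> <cmhs_dataset: 48 pairs, 4 alleles, 12 peptides>

# GNM flexibility of one allele's structure
b <- gnm_bfactor(gnm_kirchhoff(contact_adjacency(ds$coords[["allele01"]])))
round(range(b), 3)
#> [1] 0.090 0.531

cfg <- cmhs_small_config(list(train = list(epochs = 8), seed = 2))
model <- train(ds, cfg)
model
#> <cmhs_model (full, stub embedder w=32): 31147 parameters, trained>
tail(model$history, 2)
#>   epoch train_loss   val_loss        mse contrastive
#> 7     7 0.03539852 0.04235527 0.03123398  0.04164536
#> 8     8 0.03318356 0.05936139 0.02929287  0.03890692

preds <- predict(model, ds, rows = model$val_rows)
metric_report(preds, ds$table[model$val_rows, ])
#> pMHC metrics (n = 9)
#>   SRCC  0.7000
#>   PCC   0.6273
#>   AUROC 0.8500
#>   ACC   0.5556
```

`train_loss`/`mse`/`contrastive` are the per-epoch training loss and its
two components; `val_loss` is computed in evaluation mode (noise layers
off) on a held-out 20%. The metric report scores held-out predictions:
SRCC/PCC against normalized affinities, AUROC/ACC against the 500 nM
binder labels. (An 8-epoch run on 48 pairs is a smoke test; the
acceptance-scale run — 1200 pairs, 50 epochs — reaches held-out
SRCC ≈ 0.69 against the generator's ≈ 0.79 noise ceiling.)

## Command line

```sh
CMHS=$(Rscript -e 'cat(system.file("exec", "cmhs", package = "cmhs"))')
Rscript $CMHS simulate --out data/ --seed 7
Rscript $CMHS bfactor  --pdb data/pdb/allele01.pdb --out bfac.tsv
Rscript $CMHS train    --data data/ --out run/ --seed 7
Rscript $CMHS predict  --checkpoint run/checkpoint.json \
    --mhc data/alleles.fasta --peptides data/peptides.fasta \
    --pdb-dir data/pdb --pseudo data/pseudo_positions.txt --out pred.csv
Rscript $CMHS evaluate --predictions pred.csv --truth data/affinity.csv
Rscript $CMHS crossval --data data/ --out cv/ --seed 7
```

Config files are JSON (`--config`); `--seed` overrides the config seed;
exit codes are 0 (success) and 2 (validation error).

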