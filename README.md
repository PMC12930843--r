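# atacAnno

Cell-type annotation for single-cell ATAC-seq by **label transfer with
graph domain adaptation**. Given an annotated reference dataset and an
unlabelled query profiled on a different platform (snATAC vs sciATAC vs
10x), atacAnno predicts a cell type for every query cell while actively
correcting the batch shift between the two datasets.

It is aimed at epigenomics analysts who already have a peak-by-cell
matrix (CellRanger-style MTX + sidecars) for both datasets and reference
labels as a TSV.

## Method

**Stage 1 — cell embeddings.** Two interchangeable routes:

* *Sequence encoder*: each peak's DNA sequence is embedded (either
  precomputed vectors from a DNA language model, or the built-in
  deterministic k-mer/random-projection embedder), and a feedforward
  network with batch-normalized hidden layers is trained to predict each
  peak's binarized accessibility across all cells,
  `Ŷ = H⁽ᴸ⁾ W⁽ᴸ⁺¹⁾ + b`, with binary cross-entropy. Column *c* of the
  trained output weights `W⁽ᴸ⁺¹⁾ ∈ ℝ^{D×C}` is the embedding of cell *c* —
  the projection that reconstructs that cell's accessibility from
  sequence-level features.
* *LSI*: binarize → TF-IDF (`idf_j = log(1 + C/df_j)`) → truncated SVD,
  embeddings `U·S` (default 128 dims).

Embeddings for reference and query are fitted jointly so both domains
share one coordinate system.

**Stage 2 — graph domain adaptation.** kNN cell graphs are built per
domain (exact search, union-symmetrized, `Â = D̃^{-1/2}(A+I)D̃^{-1/2}`).
Three GCN layers with weights shared between domains classify cells, with
asymmetric propagation depth: the labelled source uses shallow propagation
(`H_s = ReLU(Â_s X_s W₁)`, `Z_s = ReLU(H_s W₂)`, `Ŷ_s = Â_s Z_s W₃`),
while the unlabelled target propagates `K` extra steps
(`Z_t = ReLU(Â_tᴷ (H_t W₂))`) to substitute neighbourhood consensus for
missing labels. Training minimizes `L_cls + λ·L_dom`, where `L_cls` is the
NLL of the reference labels and `L_dom` is the cross-entropy of a domain
discriminator fed `[Z_s; Z_t]` through a **gradient reversal layer**
(identity forward, gradient scaled by `-γ` backward) with the ramp
`γ = 2/(1+e^{-10·e/E}) − 1`, so the shared encoder is driven to make the
two domains indistinguishable while the classifier stays accurate.

A synthetic-data module (`simulate_pair()`) generates labelled
reference/query pairs with type-specific marker peaks, planted sequence
motifs, and a dropout-style query batch effect, so the whole pipeline is
testable without downloads.

## Worked example

```r
library(atacAnno)

sim <- simulate_pair(sim_config(seed = 1))   # 4 types, 400 + 400 cells, 2000 peaks
sim$source$matrix
#> cell_peak_matrix: 400 cells x 2000 peaks, 115164 nonzero entries

res <- annotate_transfer(sim$source$matrix, sim$source$labels,
                         sim$target$matrix,
                         gda = gda_config(n_classes = 4, seed = 1))
head(res$predictions[, 1:4], 3)
#>           cell_id predicted_label    type01      type02
#> 1 query_cell_0001          type01 0.9782035 0.009713334
#> 2 query_cell_0002          type01 0.9899343 0.004677414
#> 3 query_cell_0003          type01 0.9782096 0.009713488

unlist(ground_truth_report(res$predictions, sim$target$labels)[c("accuracy", "macro_f1")])
#> accuracy macro_f1
#>        1        1

tail(res$state$log, 2)    # per-epoch classification / domain losses and γ
#>     epoch   loss_cls  loss_dom     gamma     total
#> 199   199 0.08774409 0.6971282 0.9999045 0.7848723
#> 200   200 0.08617802 0.6989079 0.9999092 0.7850859
```

Every query cell is matched to the correct simulated type (accuracy and
macro-F1 of 1.0); the domain loss settling near `ln 2 ≈ 0.693` means the
discriminator can no longer tell reference from query embeddings — the
batch effect has been aligned away.

Command-line wrappers over the same functions live in `inst/cli/`
(`annotate.R`, `simulate.R`).

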