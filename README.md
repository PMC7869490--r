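# contactsol

Structure-aware protein solubility prediction from sequence, for protein
engineers and bioinformaticians who need a continuous solubility estimate
(the cell-free PURE assay definition: supernatant fraction over total
fraction, in [0, 1]) without an experimental structure.

Low solubility is a standing obstacle in recombinant protein production in
*E. coli*; since solubility is largely encoded in the sequence, it can be
predicted.  `contactsol` goes beyond purely one-dimensional sequence models
by representing each protein as an attributed graph built from a
*predicted* residue–residue contact map, so spatial structure enters the
model while the input remains sequence-derived.

## The model

A protein of length *L* becomes a graph G(F, E): nodes are residues with a
91-dimensional feature vector (BLOSUM62 rows, 7 physicochemical
descriptors, PSSM, HMM profile, predicted structural properties, all
standardized with training-set statistics), and edges are predicted
contacts — either the full probability-weighted map or the top ⌊αL⌋ pairs
(α ∈ 0..7, continuous or discrete weights), with 2-hop sequence
neighbours always connected.  The regression model is

- graph convolution layers (default widths 256, 64) using the
  degree-normalized adjacency **D̃**⁻¹(**A** + **I**), ReLU and layer
  normalization:  G⁽ˡ⁺¹⁾ = LN(ReLU(D̃⁻¹Ã G⁽ˡ⁾ W⁽ˡ⁾)),
- a multi-head self-attention readout
  T = softmax(W₂ tanh(W₁ Mᵀ)), H = (1/r) Σₖ (T M)ₖ, giving a fixed-width,
  permutation-invariant graph embedding (r = 4 heads), and
- a sigmoid linear head S = sigmoid(W₃ Hᵀ + b) ∈ (0, 1).

Training minimizes MSE (reported as RMSE) with Adam; fivefold
cross-validation repeated over seeds, fold-model ensembling, and the full
metric suite (RMSE, R², threshold-0.5 classification metrics, rank-based
AUC) are built in.  Forward and backward passes are compiled
(RcppArmadillo) with hand-derived gradients, finite-difference-checked in
the tests.

The package also parses the external feature formats (PSI-BLAST ASCII
PSSM, HH-suite `.hhm`, SPIDER3 `.spd33`), reads contact maps (dense,
sparse triplets, CASP-RR), evaluates predicted contacts against Cα
contacts of a PDB structure (7.5 Å cutoff), and ships a synthetic-data
generator that emulates every input so the whole pipeline runs and is
tested fully offline.

## Worked example

Simulate 400 proteins, train on 300 with the full contact graph, and
evaluate the 100 held-out proteins:

```r
library(contactsol)
spec <- synthetic_protein_spec()
sim <- simulate_proteins(400, spec, seed = 1)
sp <- split_dataset(sim, fraction = 0.75, seed = 1)
scaler <- fit_feature_scaler(sp$train$features)
train_ds <- build_graph_dataset(sp$train, edge_scheme("full"), scaler)
test_ds  <- build_graph_dataset(sp$test,  edge_scheme("full"), scaler)
fit <- train_model(train_ds, tconfig = train_config(epochs = 40, seed = 1))
fit
#> <solgcn_fit: 300 proteins, 40 epochs run, final train RMSE 0.0326>
pred <- predict(fit, test_ds)
head(pred, 3)
#> # A tibble: 3 × 3
#>   id         predicted actual
#>   <chr>          <dbl>  <dbl>
#> 1 synth_0003     0.869  0.948
#> 2 synth_0004     0.265  0.205
#> 3 synth_0005     0.657  0.783
compute_metrics(pred$predicted, pred$actual)
#> # A tibble: 1 × 12
#>    rmse    r2 threshold    tp    fp    tn    fn accuracy precision recall    f1   auc
#>   <dbl> <dbl>     <dbl> <int> <int> <int> <int>    <dbl>     <dbl>  <dbl> <dbl> <dbl>
#> 1 0.129 0.767       0.5    44    10    39     7     0.83     0.815  0.863 0.838 0.942
```

The held-out R² of 0.77 means the model recovered the planted
graph-dependent solubility function from the noisy predicted contact maps;
RMSE is on the solubility scale (here 0.129), and the classification
metrics describe soluble/insoluble calls at the 0.5 cutoff.  Repeating
the run with `edge_scheme("topk", alpha = 0)` (chain only, no contacts)
drops R² to about 0.52 — the contact map carries real signal.

`cross_validate()` / `ensemble_predict()` reproduce the fivefold ×
five-seed protocol, and `tidy()`, `glance()` and `autoplot()` methods are
provided for fits, CV results and threshold sweeps.  A thin command-line
wrapper lives at `inst/cli/contactsol` with subcommands `simulate`,
`build-graph`, `train`, `cv`, `predict`, `evaluate`.

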