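# structfun

Protein function prediction from backbone geometry with
rotation-equivariant graph networks, in R.

Given a protein chain's 3-D backbone, `structfun` predicts Gene
Ontology (GO) terms. It builds a residue graph whose nodes and edges
carry both rotation-invariant scalars (secondary structure, backbone
dihedrals, solvent accessibility, pluggable per-residue sequence
embeddings, RBF-encoded distances, sequence-offset encodings) and
rotation-equivariant 3-D vector channels (inter-residue and
C&alpha;&rarr;C&beta; directions). A geometric vector perceptron (GVP)
graph network propagates these jointly:

    V' = sigma+(|| W_mu W_h V ||) (*) (W_mu W_h V)
    s' = sigma(W_m concat(|| W_h V ||, s) + b)

followed by GVP message passing with residual scalar-vector layer
norm, a scalar-collapsing GVP producing an L x D invariant feature map
F, two-stage supernode attention pooling (trainable supernode queries
attend over residues, a global query attends over supernodes), and a
sigmoid multi-label head. Training minimizes

    L = BCE(y, yhat) + InfoNCE(z, z'; tau = 0.5)

where z' is the pooled representation of a second view whose lifted
node features receive sign-preserving uniform noise
(h' = h + |eps| sign(h)). Residue-level attribution uses Grad-CAM on
the collapsed feature map: CAM_i = ReLU(sum_j dY/dF_ij * F_ij / D).
Evaluation implements the protein-centric CAFA metrics (Fmax, AUPR,
Smin with information-content weighting over the GO DAG).

The network core, including a small reverse-mode autodiff tape over
BLAS matrices, is implemented in plain R; gradients are checked
against finite differences in the test suite, and all vector channels
are verified to transform exactly by the applied rotation.

A synthetic-structure module generates ideal-geometry backbones with
motif-determined labels, so the complete pipeline trains and evaluates
offline with no downloads.

## Worked example

```r
library(structfun)

# a synthetic 2-term task: "contains a helix >= 12" / ">= 2 strands"
task   <- make_task(n_proteins = 60, n_terms = 2, seed = 11)
graphs <- lapply(task$structures, featurize)

model <- gvp_model(node_scalar_dim = ncol(graphs[[1]]$node_scalar),
                   n_terms = 2, seed = 1)
fit <- train(model, graphs, task$labels,
             split = list(train = 1:42, val = 43:51),
             train_config(learning_rate = 1e-3, batch_size = 8,
                          max_epochs = 12, patience = 6, seed = 1))
fit$report
#> <train_report> 12 epoch(s), best epoch 12 (val 1.5858), seed 1

held <- 52:60
scores <- model_predict(fit$model, graphs[held])
evaluate_predictions(task$labels[held, ], scores)[c("fmax", "aupr")]
#> $fmax
#> [1] 0.875
#> $aupr
#> [1] 0.8701389

cam <- grad_cam(fit$model, graphs[[52]], term = 1)
cam
#> <cam_scores> chain_A / term 1: 14 residues, max 0.002088
```

`fit$report` tracks per-epoch train/validation losses and the early
stopping point. `evaluate_predictions()` returns Fmax (best F1 over
the CAFA threshold grid), micro-AUPR and Smin on the held-out
proteins; with only 12 epochs on 60 proteins the model already ranks
positives far above chance (prevalence here is about 0.5). The
`cam$scores` are nonnegative per-residue contributions toward term 1
("contains a helix &ge; 12") for one held-out protein — this one is a
strand-plus-coil structure with no helix, and its near-zero scores
reflect that. `cam_to_structure()` writes scores into a PDB B-factor
column for viewing.

Real structures enter the same way: `parse_structure("file.pdb")`
followed by `featurize()`, optionally passing a precomputed
language-model embedding matrix. A command-line wrapper for the
pipeline (`simulate`, `featurize`, `train`, `predict`, `explain`,
`evaluate`) is installed at `inst/cli/structfun`.

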