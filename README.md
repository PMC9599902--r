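# a2gcn

Cross-site classification of brain functional-connectivity networks with
an attention graph convolutional network trained under unsupervised
domain adaptation.

## The problem

Resting-state fMRI studies pool data from several imaging sites to gain
sample size, but scanners and protocols shift the distribution of the
derived connectivity matrices, so a classifier trained at one site
degrades at another.  This package is for researchers who have a *labeled*
cohort at one site (patients vs controls) and an *unlabeled* cohort at
another, and want a classifier for the unlabeled site together with an
interpretable ranking of the brain regions driving it.

## The model

Each subject is a dense signed graph over N regions of interest (ROIs):
edge weights are Pearson correlations `e_ij` of the ROI mean time series,
the adjacency matrix has unit diagonal, and the node features are the
connectivity profiles themselves (X = A).  The model stacks

1. two graph-convolution layers
   `H = ReLU(D̃^(-1/2) A D̃^(-1/2) H W)` with absolute-value degrees
   `D̃_ii = Σ_j |A_ij|` (widths 32, 32),
2. a node-attention head (feature-wise max pooling, two N-wide fully
   connected layers, sigmoid) whose scores `a ∈ [0,1]^N` reweight the
   embedding residually, `Z = a ⊙ H + H`,
3. a mean‖max readout `G` (length 64) and a two-layer classifier
   (64 → 64 → 2, dropout 0.4).

Training minimizes `L = L_C + γ₁·L_M + γ₂·L_A`, where `L_C` is source
cross entropy, `L_M = mean|Z_s − Z_t|` aligns node embeddings across
domains, and `L_A = ‖C_s − C_t‖²_F / (4d²)` is the CORAL penalty on the
readout covariances.  The schedule is two-stage (50 epochs alignment-only
with γ₁ = γ₂ = 1, then 100 joint epochs with γ₁ = γ₂ = 0.5), Adam at
learning rate 1e-4.  Target labels are never inputs to fitting.

The package also ships the eight standard baselines (degree/betweenness/
closeness centralities + SVM, DNN on PCA-reduced edge vectors, plain GCN,
DNNC with CORAL, MMD, and adversarial DANN), three ablation variants, a
synthetic two-site cohort generator, the seven usual classification
metrics, a covariance-Frobenius site-shift statistic, and attention-based
ROI ranking.

## Worked example

```r
library(a2gcn)

# a synthetic two-site cohort: 20 ROIs, 60 subjects per site (30 per
# class), class effect 0.3 in a planted 5-ROI block, site shift 0.5
sim <- simulate_cohort(n_rois = 20, n_time = 100, m_per_class = 30,
                       k_informative = 5, delta = 0.3, shift = 0.5,
                       seed = 1)

fit <- a2gcn(sim, seed = 1)
fit
#> Attention GCN with domain adaptation
#>   ROIs: 20   source subjects: 60   target subjects: 60
#>   epochs: 150 (final loss 0.5445)   seed: 1
#>   site shift (CF): 0.4716 (input) -> 0.0578 (readout)

prob <- predict(fit)                      # target class probabilities
truth <- sim$target_labels_heldout        # held out from training
round(metrics_from_predictions(as.integer(prob[, 2] > 0.5),
                               prob[, 2], truth), 3)
#>   ACC   Pre   Rec    F1   BAC   NPV   AUC
#> 0.850 0.920 0.767 0.836 0.850 0.800 0.953

head(rank_rois(fit$target$attention, top_k = 5), 5)
#>   rank   roi roi_index mean_attention
#> 1    1  roi1         1      0.5754104
#> 2    2 roi14        14      0.5658845
#> 3    3 roi10        10      0.5642031
#> 4    4  roi2         2      0.5601722
#> 5    5 roi17        17      0.5376876
```

The fitted model classifies the unlabeled site at 85% accuracy; the
covariance-Frobenius shift between the two sites drops by an order of
magnitude between the input representation and the learned readout; and
the attention ranking places planted informative regions (roi1, roi2 here)
near the top.  Baselines and ablations run through the same interface:

```r
fit_baseline("gcn", sim, seed = 1)        # or dc, bd, bdc, dnn, dnnc, mmd, dann
fit_ablation("a2gcn_m", sim, seed = 1)    # attention + MAE only
run_experiment(sim, "a2gcn", repeats = 10, seed = 1)  # mean ± sd metrics
```

A command-line front end (`inst/cli/a2gcn`) exposes `simulate`,
`build-fcn`, `train`, `evaluate`, `baseline` and `ablate` subcommands over
the same functions; real cohorts enter as a manifest CSV plus per-subject
time-series or connectivity-matrix files (see `?read_manifest`).

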