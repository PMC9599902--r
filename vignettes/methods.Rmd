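---
title: "Attention graph convolution with domain adaptation for brain connectomes: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention graph convolution with domain adaptation for brain connectomes: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(a2gcn)
```

## The problem

Resting-state fMRI cohorts pooled across imaging sites are attractive
(larger samples) but heterogeneous: scanners and protocols shift the
distribution of the derived functional-connectivity networks (FCNs), so a
classifier trained at one site degrades at another.  This package fits a
graph classification model on a *labeled source site* and an *unlabeled
target site* simultaneously, aligning the two feature distributions during
training so the classifier transfers.  The two classes are patients
(label 1) and controls (label 0).

## Data model

Each subject is a graph over N regions of interest (ROIs).  From the T x N
matrix of ROI mean time series, the edge weight between ROIs $i$ and $j$ is
the Pearson correlation

$$e_{ij} = \frac{(v_i - \bar v_i)^\top (v_j - \bar v_j)}
  {\sqrt{(v_i-\bar v_i)^\top(v_i-\bar v_i)}
   \sqrt{(v_j-\bar v_j)^\top(v_j-\bar v_j)}},$$

with the adjacency matrix $A$ having $A_{ii}=1$ and $A_{ij}=e_{ij}$
otherwise.  The node feature matrix is $X = A$: each node is described by
its connectivity profile.  Correlations are kept signed — nothing in the
construction thresholds or rectifies them — and the graph is dense.  An
`abs_adjacency` option exists for the absolute-value convention but is off
by default.  No Fisher z-transform is applied.

## Architecture

1. **Graph convolutions.**  Two layers
   $H^{(l+1)} = \mathrm{ReLU}(\tilde D^{-1/2} A \tilde D^{-1/2} H^{(l)}
   W^{(l)})$ with output widths 32 and 32.  Because the graphs are signed,
   plain row sums can be non-positive and their inverse square root
   undefined; the degree used is $\tilde D_{ii} = \sum_j |A_{ij}|$, which
   reduces to the usual normalization for non-negative graphs.  A `raw`
   mode applies the literal row-sum degree and errors on non-positive
   degrees.

2. **Node attention.**  Each node's embedding row is max-pooled over the
   feature dimension to a scalar, giving a length-N summary per subject.
   Two fully connected layers of width N map this to a per-node score in
   $[0,1]$ via a terminal sigmoid.  The inner activation is not pinned
   down by the published description (the sentence describing the hidden
   widths is garbled); this implementation uses ReLU after the first layer
   and sigmoid after the second, which respects both the "two fully
   connected layers" structure and the sigmoid output.  Max pooling is
   over features (N x D to N x 1), the only reading dimensionally
   consistent with N-wide layers.  Dropout is not applied inside the
   attention block.

3. **Residual reweighting.**  $Z = a \odot H + H$: row $i$ is scaled by
   $1 + a_i$, so even a zero-attention node passes through.

4. **Readout and classifier.**  $G = \mathrm{mean}_i Z_i \,\Vert\,
   \max_i Z_i$ (length $2D = 64$), followed by two fully connected layers
   with output widths 64 and 2 (ReLU and dropout 0.4 on the hidden layer,
   softmax on the logits).

## Losses and training schedule

With $Z$ (per-node, post-attention) and $G$ (post-readout) features for
both domains:

* MAE alignment on node embeddings:
  $L_M = \frac{1}{NMD}\sum |Z^s - Z^t|$ over position-paired subjects;
* CORAL alignment on readouts:
  $L_A = \frac{1}{4d^2}\lVert C_s - C_t \rVert_F^2$, with $C_k$ the sample
  covariance of domain $k$'s readouts;
* cross entropy $L_C$ on the labeled source subjects only.

The objective is $L = L_C + \gamma_1 L_M + \gamma_2 L_A$.  Training is
two-stage: 50 epochs of alignment-only pretraining
($L_C$ off, $\gamma_1=\gamma_2=1$) and 100 epochs of joint training
($\gamma_1=\gamma_2=0.5$), Adam, learning rate $10^{-4}$, dropout 0.4.
Target labels are never an input to any fitting function; the evaluation
layer holds them separately.

Design notes on the open points:

* **CORAL scale $d$.**  The readout has length $2D$; the published
  denominator is written in terms of the node feature width $D$.  The
  default uses the actual length of the vector entering the loss
  ($d = 2D = 64$); `coral_denom = "node_dim"` restores the literal
  convention.  The choice only rescales $\gamma_2$.  Either way the CORAL
  term is numerically tiny at these dimensions ($\lVert C_s - C_t
  \rVert_F \approx 10^{-1}$ gives $L_A \approx 10^{-6}$), so most of the
  alignment pressure comes from the MAE term — a property of the published
  scaling, reproduced faithfully here.
* **Cross entropy.**  The printed sum contains only the $Y \log \hat Y$
  term, which vanishes for class 0; the implementation uses standard
  two-class cross entropy (both terms), the universal reading.
  Probabilities are clipped at $10^{-12}$ with a warning.
* **Subject pairing for $L_M$.**  Source and target subjects are unrelated
  individuals, so the position-wise pairing is re-randomized every epoch
  (and the smaller domain resampled with replacement when sizes differ);
  in expectation $L_M$ is then a distribution-level discrepancy, not a
  subject-level one.  A consequence worth knowing: with *identical*
  source and target cohorts $L_A$ is exactly zero from the first step,
  while $L_M$ is zero only under matching pairing — random re-pairing
  compares different subjects and leaves a small positive value.
* **Minibatch steps.**  All subjects are used every epoch (the protocol is
  transductive), but each epoch is split into seeded minibatches of 16
  subjects per domain rather than taken as one step.  With Adam the update
  magnitude is bounded by the learning rate, so 150 single-step epochs at
  $10^{-4}$ move each weight by at most about $0.015$ — demonstrably too
  little to fit even a linearly separable cohort.  Minibatching preserves
  the stated epoch count and learning rate while providing enough
  optimizer steps to learn; `batch_size` is configurable (setting it to
  the cohort size recovers full-batch).
* **Stage degeneration.**  When every alignment weight is zero the
  pretraining stage would minimize a constant; it is skipped and the
  cross-entropy objective runs for the full 150-epoch budget.  This makes
  the $\gamma_1=\gamma_2=0$ configuration *exactly* the plain-GCN
  baseline (identical trajectory under a shared seed) once attention is
  also disabled.

## Baselines and ablations

Eight competing methods share the cohort interface and the predictions
schema: DC/BD/BDC (weighted degree, betweenness, closeness centralities,
concatenated and fed to a linear SVM), DNN (strict upper-triangle
vectorization, transductive PCA to 64 components, a 64-16-2 network), GCN
(the backbone and classifier without attention or alignment), DNNC (the
DNN pipeline with a 64-32-2 network and a CORAL penalty on the hidden
features), MMD (the full architecture with both discrepancy terms replaced
by a multi-kernel maximum mean discrepancy on the readouts; five Gaussian
bandwidths geometrically spaced around the median pairwise distance), and
DANN (adversarial domain classifier behind a gradient reversal layer with
the standard ramp $\lambda(p) = 2/(1+e^{-10p})-1$).  Centralities use
absolute weights; betweenness and closeness need edge lengths, taken as
$1-|w|$ clipped to $[10^{-6}, 1]$.  The three ablations drop,
respectively, both alignment terms (`a2gcn_a`), the CORAL term
(`a2gcn_m`), and the attention module (`a2gcn_c`).

All gradients (backbone, attention, heads, and all five loss terms) are
analytic and verified against central finite differences in the test
suite.

## The synthetic two-site generator

`simulate_cohort()` stands in for a multi-site cohort.  Subject time
series are i.i.d. draws from a zero-mean multivariate normal whose
correlation matrix composes three effects:

* a base community structure (4 equal blocks, within-block correlation
  0.3, between-block 0.05);
* a class effect: $\pm\delta/2$ on the off-diagonal entries of a planted
  k-ROI block (the first k ROIs);
* a site effect: a domain-specific congruence transform
  $\Sigma \mapsto (I+sE)\,\Sigma\,(I+sE)^\top$ with a fixed random
  symmetric $E$ per domain (entries $\mathcal N(0, 1/N)$), rescaled to a
  correlation matrix.

Injecting the shift in the latent covariance (rather than on the FC
matrices directly) keeps every generated matrix a valid correlation matrix
and exercises the full graph-construction path.  Matrices that lose
positive definiteness are repaired by eigenvalue clipping at $10^{-6}$
(logged in the ground truth; an error is raised if the repair would change
the matrix by more than 50% in Frobenius norm).  The generator emulates
*distributional* site effects and a *correlational* class effect; it does
not emulate hemodynamics, temporal autocorrelation, motion artifacts, or
site differences in scan length — so passing tests certify the method's
behavior under controlled covariance shift, not performance on real
rs-fMRI.

Defaults mirror the real-data setting where a value exists (N = 116 ROIs
as in the AAL atlas, T = 150 time points); tests and the acceptance
experiments use a desk-scale cohort of N = 20, T = 100, 60 subjects per
site (30 per class), a 5-ROI informative block, class effect
$\delta = 0.3$ (0.4 for the attention-recovery experiment) and shift
$s = 0.5$, with 10 repeated seeded fits per experiment.

## Measuring residual site shift

`shift_severity()` reports the covariance-Frobenius (CF) statistic
$\lVert C_s - C_t \rVert_F$.  Before adaptation it is measured on the
model-free input representation — PCA (fit on both sites jointly) of the
vectorized upper-triangle connectivity — and after training on the learned
readout representations, mirroring how the distribution shift is usually
visualized before/after adaptation.  The two spaces have different scales,
so the before/after comparison should be read as "shift visible in the
representation the classifier actually consumes", not as a ratio.

## Attention-based ROI ranking

`rank_rois()` averages each ROI's attention score over the chosen subjects
(the target cohort by default) and returns the top k, ties broken by ROI
index.  On synthetic cohorts the ranking can be scored against the planted
informative block with an exact hypergeometric tail test, which is what
the acceptance experiment does.  In repeated runs the planted regions rank
clearly above chance on average, but the per-run enrichment is not always
individually significant at the 150-epoch, $10^{-4}$-learning-rate budget
— the attention head receives gradient only through the classification
loss and moves slowly at that step size.

## Numerical conventions

* Weight initialization: fan-based uniform (Glorot) limits, zero biases,
  drawn from the run seed; per-repeat seeds are `master_seed + repeat - 1`.
* Max-pooling argmax ties break toward the first index (deterministic);
  ROI-ranking ties break by ROI index.
* Degenerate metric denominators (e.g. no predicted positives) yield `NA`
  rather than 0, and aggregated means/sds propagate them honestly.
* Correlations are clamped to $[-1,1]$ after floating-point rounding;
  loaded matrices may deviate from symmetry by at most $10^{-6}$ (repaired
  by symmetrization) and from unit diagonal by the same tolerance.
* All randomness (initialization, batch shuffling, pairing, dropout)
  flows from a single integer seed; refitting with the same seed is
  bit-identical, and an interrupted fit resumed from its optimizer state
  continues bit-identically.

## Known limitations

* The transductive protocol (train on all of both sites, evaluate on the
  target) matches the published setting but means no held-out-site
  generalization estimate is produced.
* Whether adaptation improves target *accuracy* depends on the geometry
  of the site shift: covariance alignment can be achieved (the CF
  statistic drops reliably) without moving the decision boundary, and on
  easy cohorts all variants can saturate.  The package reports both the
  accuracy ordering and the CF reduction so the two effects can be
  distinguished.
* Only two-class problems and a single source site are supported, as in
  the original design.
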