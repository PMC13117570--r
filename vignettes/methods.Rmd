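---
title: "Multi-omics graph neural networks for driver-gene prioritization: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics graph neural networks for driver-gene prioritization: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivergnn)
```

## The problem and the model

Cancer driver genes are rare (roughly 5–6% of genes on the large public
protein–protein interaction networks carry a confident driver label) and
their evidence is spread over several molecular layers. `drivergnn`
implements a transductive node classifier on a gene–gene interaction graph
whose per-gene features are four 16-dimensional omics summaries — somatic
mutation rate, differential expression, differential DNA methylation and
copy-number alteration rate, one scalar per cancer type per omics.

The forward path is, in order:

1. **Graph operator.** The undirected 0/1 adjacency $A$ gets self loops and
   symmetric normalization,
   $\hat A_{\mathrm{norm}} = \hat D^{-1/2}(A+I)\hat D^{-1/2}$ with
   $\hat D_{ii} = \sum_j (A+I)_{ij}$; this is the propagation operator of
   every graph-convolution layer.
2. **Independent omics encoders.** Each omics block passes through two
   *residual GCN layers*:
   $H^{(l+1)} = \sigma(H^{(l)} W_L) + \sigma(\hat A_{\mathrm{norm}} H^{(l)} W_c)$
   ($\sigma$ = ReLU), widths $16 \to 96 \to 256$, followed by one layer
   normalization ($\varepsilon = 10^{-5}$). Mutation, methylation and CNV
   have their own encoders. Expression is processed by three further
   encoders of the same shape with independent parameters — one per paired
   omics view — whose outputs pass through three independent one-hidden-layer
   MLPs (width 256) and are concatenated and linearly fused back to width
   256.
3. **Attention fusion.** Per node $i$ and omics $m$, an additive attention
   network scores $s_i^{(m)} = v^\top \tanh(W_a H_i^{(m)} + b_a)$
   ($W_a \in \mathbb{R}^{d_a \times d_h}$, $d_a = 64$); a softmax over the
   four omics gives weights $a_i^{(m)}$ and the fused representation
   $H_{\mathrm{fused},i} = \sum_m a_i^{(m)} H_i^{(m)}$.
4. **Feature enhancement.** Label-free topology features — a seven-metric
   centrality battery (degree, normalized betweenness, closeness,
   eigenvector centrality, local clustering, PageRank at damping 0.85, core
   number) and node2vec walk embeddings — plus the teacher's soft-label
   logit are concatenated into $X_{\mathrm{extra}}$, standardized with
   training-fold statistics, passed through a one-hidden-layer MLP and added
   residually: $H_{\mathrm{enhanced}} = H_{\mathrm{fused}} +
   \mathrm{MLP}_{\mathrm{extra}}(X_{\mathrm{extra}})$.
5. **Dual heads.** A residual-GCN projection layer maps to 128 dimensions;
   a 6-layer residual GCN head (width 200, dropout 0.2 after each additive
   merge) and a 3-layer MLP head (input layer-norm, widths 256/128/64,
   dropout on the third layer) produce logits that are summed,
   $\hat y = \hat y_G + \hat y_m$, and converted by a sigmoid.

Training minimizes $L = L_B + \lambda L_K$ with $\lambda = 0.5$:
$L_B$ is class-balanced binary cross-entropy over the labeled training
nodes ($w_p = N/2N_{\mathrm{pos}}$, $w_n = N/2N_{\mathrm{neg}}$;
a focal-loss option with $\gamma = 2$ exists) and $L_K$ is the soft-target
cross-entropy between student and teacher sigmoid outputs over the
distillation node set. Optimization uses AdamW (lr $5.5\times10^{-4}$,
decoupled weight decay $8\times10^{-5}$), 900 epochs by default, with
feature-mask (rate 0.1) and edge-drop (rate 0.1) augmentation re-normalizing
the operator every epoch.

**Teachers.** Soft labels come from an ensemble of high-capacity teachers:
the same architecture with encoder widths 128/512, trained 1200 epochs at
lr $3\times10^{-4}$, weight decay $5\times10^{-5}$, dropout 0.15, with
early stopping (patience 200) on validation average precision and a
parameter EMA (decay 0.995) supplying the final logits. Ten teachers differ
only by seed; their mean logit is the soft label, entering both as an input
feature and through $L_K$.

## Design choices made where the design was open

* **Attention score form.** The printed attention formula carried a
  typographical inconsistency in where the score vector $v$ sits; the
  package uses the standard additive-attention reading
  $v^\top\sigma(W_a s + b_a)$ — the only form that typechecks — with
  $\sigma = \tanh$ (switchable to ReLU) and $d_a = 64$.
* **Expression "interaction" encoders** consume only the expression block;
  cross-omics specialization arises from independent parameters per paired
  view. A `expression_pair_input` switch concatenates the paired 16-dim
  block instead, so both readings are testable.
* **Encoder depth** is two residual layers — inferred from the two stated
  hidden widths (96, 256); depth is not otherwise pinned down.
* **Projection vs head width.** The projection layer outputs 128 while the
  GCN classifier head runs at width 200; both printed values are honored at
  their stated locations and both are configurable.
* **Teacher capacity.** "128 / 512" is read as the teacher's encoder hidden
  widths replacing the student's 96 / 256 (the stated comparison pairs them
  directly); classifier depth stays 6 in both.
* **Per-fold teachers.** Teachers are retrained inside every
  cross-validation fold so soft labels can never carry test-fold label
  information. A single global teacher would be cheaper but is a leak; the
  leak-free protocol is the default and what the tests assert.
* **Distillation node set.** Soft labels exist for all nodes; the KD loss
  averages over training-fold plus unlabeled nodes
  (`distill_include_unlabeled = TRUE`). Test-fold labeled nodes are
  excluded.
* **Ensemble temperature.** The student ensemble combines member logits as
  $\sum_k \mathrm{softmax}(\mathrm{AUPRC}^{\mathrm{val}}/T)_k\,\hat y_k$
  with $T = 0.08$; the $T \to \infty$ limit (plain mean) is available as
  `ensemble_mode = "mean"`. The combination rule behind the printed
  temperature is not fully specified; softmax weighting over validation
  average precision is one defensible reading, not presented as the only
  one.
* **Standardization convention.** Population (ddof = 0) standard deviation;
  zero-variance columns get $\sigma = 1$ so they standardize to exactly
  zero. Statistics always come from the training fold (`source_rows` is
  recorded for audits) and are applied unchanged to validation/test rows.
* **Seven structural metrics.** The exact battery is configurable; the
  default set (degree, betweenness, closeness, eigenvector, clustering,
  PageRank, core number) is the standard centrality battery of the network
  literature the approach builds on.
* **node2vec defaults** follow the original algorithm ($p = q = 1$, walk
  length 80, 10 walks per node, window 10) with a 32-dimensional embedding
  sized for a 13k-node PPI graph. The walker and skip-gram trainer (negative
  sampling, unigram$^{0.75}$ noise, linearly decaying learning rate) are
  implemented in C++ and draw from R's RNG, so a single `set.seed()`
  reproduces embeddings bit-for-bit.
* **Cross-validation shape.** The headline protocol is 10 repeats of
  stratified 5-fold CV; a 75/25 holdout is available by taking single folds
  of a 4-fold plan. Stratification preserves the positive fraction per fold
  to within one node.

## The synthetic benchmark

`synthetic_spec()` / `generate_instance()` produce instances that emulate
the driver-gene setting without any external download:

* a Barabási–Albert graph (attachment 3) whose heavy-tailed degrees mimic
  PPI hubs (a stochastic-block option provides community structure);
* ~5% positives, drawn with probability $\propto \deg^{\,\tau}$
  ($\tau = 0.5$ by default), planting the label–centrality correlation
  observed for real drivers;
* four Gaussian-noise omics blocks with a configurable per-block mean shift
  on positives (1 SD by default, in every block) — blocks with zero shift
  stay pure noise;
* optional label noise flipping a fraction of labels, mimicking undiscovered
  drivers contaminating the negative set (0 by default).

What the generator does *not* emulate: the empirical marginal distributions
of TCGA-derived rates (they are not Gaussian), correlations between omics
blocks, cancer-type structure across the 16 columns of a block, and the
homophily pattern of real PPI edges. A model that passes the recovery tests
here therefore demonstrably learns planted feature and topology signal
through the full pipeline — it is not evidence about absolute AUPRC on real
networks.

## Numerical choices

* All losses use log-sigmoid identities and stay finite for logits up to
  ±500; sigmoid probabilities are computed by `plogis`.
* The gradient engine is a reverse-mode tape over dense matrices with the
  sparse operator treated as a constant; analytic gradients are validated
  against central finite differences through the entire model in the test
  suite.
* Layer-norm $\varepsilon = 10^{-5}$; Adam $\beta = (0.9, 0.999)$,
  $\epsilon = 10^{-8}$; Glorot-uniform initialization; dropout is inverted
  (scaled at train time).
* Ties in ranking metrics: AUROC uses midranks; AUPRC groups tied scores
  into a single threshold and integrates the precision–recall curve
  stepwise (average precision), never trapezoidally.
* Isolated nodes are valid everywhere: they get a pure self-loop in the
  operator, zero for undefined centralities, and length-1 walks.

## Problem sizes used by the tests and the acceptance script

Training-based checks run at desk scale, chosen as the package's own
benchmark sizes: recovery and the acceptance script use a 1000-node
instance with one stratified 80/20 fold, a one-teacher ensemble at 30
epochs and a single student at 60 epochs (the full defaults — 10 teachers,
six students, 900/1200 epochs — are what `model_config()` ships for real
runs); the monotonicity and null-instance controls use 250-node instances.
With 1-SD planted signal the reduced budget already reaches test AUPRC
above 0.9, so the recovery margin over the 0.5 bar is wide; medians over
five seeds rise monotonically across effect sizes 0, 0.5, 1 and 2 SD.

## Known limitations

* Full-batch training on a dense-matrix tape: memory grows with
  $N \times d_h$ per tape node, which is fine for 10⁴-node graphs but would
  need mini-batching or sparse-aware autodiff well beyond that.
* The GAT ablation uses a dense masked-attention implementation, quadratic
  in $N$ — intended for ablation studies at benchmark scale, not for full
  PPI networks.
* Mixed-precision training is not implemented; all computation is double
  precision (the flag exists in the reference setting but has no
  correctness role here).
* Gene identifiers are harmonized by upper-casing and whitespace-stripping
  only; alias-database resolution is out of scope, so inputs must already
  share a symbol scheme.
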