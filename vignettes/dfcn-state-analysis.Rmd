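---
title: "Detecting abnormal dynamic functional network states with graph-convolutional recurrent attention models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting abnormal dynamic functional network states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Subjective cognitive decline (SCD) — self-reported cognitive worsening
without measurable impairment — lacks an objective neural marker.  One
candidate substrate is the *dynamic* functional connectivity network (dFCN):
the brain's region-to-region correlation structure re-estimated in short
sliding windows, so that each window is a transient network "state".  The
hypothesis this package operationalizes is that SCD expresses itself as
abnormal transient states — windows whose connectivity is weaker, more
variable and less efficient than normal — and that a classifier equipped
with a temporal attention mechanism can both detect SCD at the subject level
and point to *which* windows carry the abnormality, at several parcellation
scales simultaneously.

`dfcnstate` implements that full pipeline: dFCN construction, the
graph-convolution + LSTM + attention (G-L-A) classifier, multiscale fusion,
cross-validated evaluation with permutation significance, and the
attention-driven characterization of normal versus SCD-related states.

## From time series to dFCN tensors

Input is a volumes × R matrix of ROI-averaged fMRI signals per subject and
scale (R ∈ {100, …, 500} regions).  After discarding the first 8 volumes, a
rectangular sliding window of 48 s advanced in 16 s strides cuts the series
into T segments; within each segment the R × R matrix of pairwise Pearson
correlations is the dFCN state A_t.  At TR = 0.8 s a 488-volume scan yields
w = 60 and s = 20 volumes and exactly T = 22 windows:

```{r}
library(dfcnstate)
count_windows(488 - 8, window_spec(), tr = 0.8)  # 22
```

Window and stride must convert to whole numbers of volumes at the given TR —
non-integral conversions are rejected rather than rounded, because silent
rounding drifts the window grid.  Windows are 0-based half-open index
ranges; no tapering is applied inside a window (plain Pearson).  No per-ROI
standardization is performed either: Pearson correlation is invariant to
affine rescaling of individual signals, so it would be a no-op.

## The G-L-A model

For one subject the model consumes the T-long sequence of A_t matrices.

**Graph convolution** (shared across windows):
`h_t = ReLU(A_t W_R)` with the nodal feature matrix fixed to the identity, so
the R × d output encodes only the topology of the window's network.

**LSTM over windows** (all maps act on the feature dimension; biases
broadcast over ROIs; ×/+ are element-wise):

    f_t = σ(h_t W_f + h_{t-1} U_f + b_f)        forget rate
    u_t = σ(h_t W_u + h_{t-1} U_u + b_u)        update rate
    c̃_t = tanh(h_t W_c + h_{t-1} U_c + b_c)     candidate context
    C_t = f_t × C_{t-1} + u_t × c̃_t             cell state
    o_t = σ(h_t W_o + h_{t-1} U_o + b_o)        output rate
    h^L_t = o_t × tanh(C_t)

with h^L_0 = C_0 = 0.  The gate nonlinearity σ is configurable: the model as
printed uses ReLU in every gate, and `gla_config(gate_activation = "relu")`
reproduces that form exactly.  ReLU gates, however, are unbounded (forget
and update rates may exceed 1) and, under symmetric fan-in initialization,
half of all gate pre-activations start at exactly zero; in our pilots
ReLU-gated training never left the maximum-entropy plateau.  The
conventional logistic gates (`"sigmoid"`, the trainer's working choice)
bound the rates in (0, 1) and train reliably, so all shipped experiments
use them.  Both variants share every other equation and the same
backpropagation code.

**Attention pooling.**  Each window's hidden state is pooled over the ROI
dimension (mean) to a d-vector m_t.  The unnormalized attention score is
`raw_t = w · tanh(V m_t)`; its softmax over the subject's windows gives
α(t); and `h_ATT = Σ_t α(t) m_t` feeds one dense layer with softmax for the
two-class decision.  Two shape choices here were genuinely open and we fixed
them as follows: all learned LSTM maps are d × d on the feature dimension
(keeping the parameter count independent of R apart from W_R), and the
attention/classifier operate on ROI-pooled d-vectors rather than R × d
matrices — necessary for multiscale feature fusion, where h_ATT vectors from
models with different R are concatenated and must share a width.  Hidden
widths default to d = 16, a = 8 (the source description never states them);
the simulation study uses d = 8, a = 4, ample for its planted effects.

Because the softmax is invariant to the sign of the raw score, "larger raw
score" is not automatically "more SCD-related".  The sign is fixed per
trained model by correlating subject-mean raw scores with the predicted SCD
probability and flipping if negative.

**Loss.**  Weighted cross-entropy with class weights inverse to the class
sample ratio of the training fold (a 64:112 class split weighs errors in
the 112-class by 64/112 relative to the other), batch-reduced by the
weighted mean.  Training uses Adam, learning rate 0.01, batch 30, weight
decay 0.001, 100 epochs by default.  Parameters are initialized uniformly
with fan-in scaling under a recorded seed; training is exactly reproducible
single-threaded.

Gradients are analytic (hand-derived backpropagation through the whole
stack) and are verified against central finite differences on a small
instance (R = 4, d = 3, T = 3) to 1e-4 mixed relative/absolute error.  A
batched implementation stacks subjects along the ROI dimension — every LSTM
equation is element-wise or a right-multiplication, so rows are independent
— and a compiled (RcppArmadillo) port of that pass is used for training;
both are tested for exact gradient equality against the per-subject path.

## Multiscale fusion

Single-scale models are trained independently per scale and frozen.  Three
fusion rules combine them: **majority voting** (probability = positive votes
/ voters, positive iff > 0.5; ties impossible for odd panels and
conservatively negative for even ones), **weighted voting** (a learned
convex combination of the per-scale probabilities; with the simplex
normalization an equal-probability input passes through unchanged and a
one-hot weight recovers that scale), and **feature fusion** (concatenated
h_ATT vectors through two dense layers with batch normalization and a
softmax).  Fusion heads train for 10 epochs at learning rate 0.001, batch
30.  In cross-validation the heads are trained per fold on training-fold
subjects using the fold model's outputs only, and applied to the held-out
fold, so no fused prediction ever sees its own subject during head
training.

## Evaluation

Stratified 5-fold cross-validation (the source protocol says only
"randomly"; stratification prevents single-class test folds in small runs
and a plain-random mode is available).  Metrics: AUROC by the rank
statistic with tie averaging, AUPRC by step integration of the
precision–recall curve, sensitivity and specificity at the 0.5 threshold.
Per-fold metrics are summarized with both a normal-approximate and a
t-based confidence interval — with only five folds the choice matters and
the source protocol does not state which it used, so we report both.
External cohorts are predicted by the majority vote of the five fold
models, with checkpoints untouched.  Permutation significance randomizes
the ground-truth labels (1000 permutations by default); the reported
p-value uses add-one smoothing, (count + 1)/(n + 1), so finite samples
never produce p = 0 — the unsmoothed fraction is available.

## State analysis

Raw attention scores from the five fold models are each z-scored over all
of that model's windows, then averaged; windows with averaged z above 0
(the mean attention level) are labeled SCD-related.  A subject-level
grouping variant (every window of an SCD subject counted as SCD-related) is
available as a flag.

*Edge level:* for every upper-triangle edge, one-sided Mann–Whitney tests
compare strength and one-sided Levene tests (classical mean-centered form;
Brown–Forsythe via `center = "median"`) compare variability between the two
state groups, in both directions, Bonferroni-corrected over the R(R−1)/2
edges of that scale (each scale is its own family; whether the original
analysis also corrected across scales is not stated, and we do not).
Significant edges are aggregated into proportions per hemisphere × RSN
block pair for display on a log10 scale.

*Network level:* states are thresholded (values > τ kept, τ = 0 by default,
diagonal zeroed — self-correlation is not an edge) so all weights are
positive, then summarized by weighted modularity Q (Newman's spectral
bisection on the modularity matrix with Kernighan–Lin-style single-node
refinement sweeps; Q of the returned partition is evaluated directly from
its definition) and weighted global efficiency (mean reciprocal
shortest-path length with edge length 1/weight, disconnected pairs
contributing 0; shortest paths via Dijkstra, cross-checked against a
Floyd–Warshall oracle).  Group comparisons use two-sided rank-sum tests per
scale with Benjamini–Hochberg correction across scales.

*Transitions:* the mean of a subject's z-attention series is the tendency
to occupy SCD-related states; the unbiased (n−1) standard deviation — T is
small, typically 22 — is the transition variability.  Their association
with psychometric scores uses Spearman correlation with a two-sided
bootstrap significance from 1000 pair resamples, BH-corrected within each
property family.

## The synthetic cohort generator

No public data are required for testing: `generate_cohort()` plants the
very effects the pipeline is meant to detect.  Each subject's series
alternates between a *normal* and an *abnormal* latent covariance state on
20-volume epochs aligned to the window stride (so windows are dominated by
single states and ground truth is unambiguous).  States are block-structured
correlation matrices over 7 RSN-like blocks; the abnormal state has lower
within-block correlation (0.24 effective vs 0.50), a flatter
within/between contrast, and a per-epoch uniform strength jitter
(0.55–1.45) that raises windowed-FC variance without changing the sign
structure — together planting decreased strength, increased variability,
and lower efficiency of thresholded states.  Positive-definiteness is
repaired, if ever needed, by logged diagonal loading.  Group structure
enters only through the per-epoch abnormal dwell probability (0.2 for
HC-like vs 0.7 for SCD-like subjects by default), and a synthetic
psychometric score decreases linearly in the realized abnormal dwell
fraction plus Gaussian noise, making the planted brain–behaviour
correlation recoverable.

What the generator does *not* emulate: hemodynamics, autocorrelated BOLD
noise, head motion, spatial maps, site effects, or any empirical SCD effect
size — its distributional choices are artifact-level.  Tests passing on
these cohorts demonstrate that the machinery recovers planted effects of
this kind, not that real SCD cohorts behave this way.

## Problem sizes and numerical choices

The shipped simulation study (`run_simulation_study()`) uses 60 + 60
subjects, scales 100/200/300, 488 volumes at TR 0.8 s, 5-fold CV, d = 8,
a = 4, logistic gates, and 15 training epochs — the planted effect is
strong and the loss plateaus early, so the published 100-epoch schedule is
unnecessary at these sizes.  Network metrics are computed on a seeded
subsample of 60 states per group and scale; the edge-wise comparison runs
at the 100-ROI scale.  Probabilities inside losses are clamped at 1e-12;
batch normalization uses 1e-5 variance flooring and 0.9-momentum running
statistics; zero-variance ROI segments are an error by default (optionally
zeroed with a warning); degenerate constant edges are skipped and counted.

## Limitations

ReLU-gated training as printed appears to require an initialization scheme
the source does not specify; we ship the faithful equations but could not
make them learn, and default the trainer to logistic gates.  The spectral
modularity partition is a heuristic — it is held to within 0.05 of the
exhaustive optimum on small graphs in the test suite, not to optimality.
Bootstrap Spearman p-values are resampling approximations with a resolution
floor of about 2/(n_boot + 1).  All empirical claims about recovery are
claims about the generator's planted conditions.
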