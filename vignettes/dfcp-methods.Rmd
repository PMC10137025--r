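---
title: "Dynamic functional connectome patterns: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectome patterns: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcp)
```

## The problem

Resting-state fMRI group studies — for instance migraineurs against
healthy controls — usually summarise each subject by *static* functional
connectivity: one Pearson correlation per pair of atlas regions (ROIs)
over the whole scan. That throws away the temporal structure of brain
activity: connectivity reorganises on the scale of tens of seconds, and
the way a subject moves between recurring connectivity configurations
("states") can itself carry diagnostic information. This package
implements a classification framework that uses both kinds of
information — a static connectivity-strength profile per subject, and
features describing how the subject's *dynamic* connectome visits a set
of recurring whole-brain patterns — and evaluates it under a leakage-free
repeated cross-validation protocol.

## The pipeline, stage by stage

### Static connectivity strength

For a subject with ROI-averaged series $TS_1,\dots,TS_N$ (rows = time
points), the static connectivity matrix has entries
$\mathrm{Corr}_{ij} = \operatorname{cor}(TS_i, TS_j)$ for $i \ne j$ and
$0$ on the diagonal. The per-ROI *strength* is
$s_i = \sum_j \max(\mathrm{Corr}_{ij}, 0)$ — positive correlations only,
because the physiological meaning of negative resting-state connectivity
is contested. An absolute-value variant
($\sum_j |\mathrm{Corr}_{ij}|$) is available as `mode =
"absolute_sum"`; the positive-sum form is the default because it is the
one the strength definition states, while surrounding descriptions of the
same framework sometimes say "absolute". Both are recorded in output
metadata. Pearson correlation is invariant to per-ROI affine rescaling,
so no detrending/z-scoring choice affects this stage.

### Sliding-window dynamic connectivity and the dFCS matrix

Dynamic connectivity uses a rectangular sliding window of fixed
*duration in seconds* (default sweep 12–60 s), converted per subject to
$w = \mathrm{round}(\text{seconds}/TR)$ samples (minimum 2) so that
cohorts scanned at different repetition times share the same nominal
window. The step is 1 sample. Window $t$ (0-based, half-open
$[t, t+w)$) yields a windowed correlation matrix; its per-ROI absolute
row sum gives column $t$ of the $N \times W$ **dFCS matrix** (dynamic
functional connectivity strength), $W = T - w + 1$. Entries are bounded
by $N-1$. Tapered windows and regularised covariance estimators are out
of scope.

### Quasi-stable segmentation (WQCPs)

Adjacent dFCS columns are similar while the brain stays in one
connectivity regime and jump at transitions. The segmenter computes the
Euclidean distance $d_t$ between columns $t$ and $t+1$ and places a
boundary wherever $d_t > \bar d + \alpha\,\mathrm{sd}(d)$, with
$\alpha = 1$ by default; segments shorter than `min_segment_windows`
(default 2) are merged into the neighbour whose shared boundary distance
is smaller (ties merge left). Each segment's columnwise mean is one
**WQCP** (whole-brain quasi-stable connectome pattern), a length-$N$
vector. Design notes:

* The threshold rule is the simplest reading of "use the adjacent-slice
  Euclidean distance as a change signal". It is affine in the distance
  distribution, so segmentation is invariant to uniform rescaling of the
  dFCS matrix.
* When all distances are equal (sd = 0), nothing exceeds the threshold
  strictly and the whole axis is a single segment.
* Formal change-point machinery (PELT, binary segmentation) is
  deliberately not used: the distance-threshold rule *is* the method
  under study.

### Twice-clustering into DFCPs

Training subjects' WQCPs are pooled and clustered in two stages:
K-means overclustering with $k_0 = \min(2\lceil\sqrt{n}\rceil, n)$
centers (10 restarts, best inertia, fixed seed), then Ward agglomeration
of the $k_0$ centroids. Candidate pattern counts $K$ (default 1–12) are
scored by the total within-cluster sum of squares of the WQCPs, and $K$
is chosen by the elbow rule: the candidate maximising the perpendicular
distance to the line joining the curve's endpoints, ties to the smaller
$K$. The candidate range starts at 1 deliberately: the knee rule
measures curvature against the endpoints, so the large drop from one to
two clusters must be visible for a two-state solution to be selectable,
and an endpoint itself is only chosen when the curve is flat. Final centroids $R_1,\dots,R_K$ (the **DFCPs**) are member means.
The overclustering step keeps hierarchical clustering cheap while the
Ward merge supplies the cluster-count decision; clustering is pooled
across groups (a per-group variant would change the feature space per
fold and is not claimed by this implementation).

### DFCP features

Each subject yields $2K$ dynamic features:

* **Occupancy ratios**: the fraction of the subject's WQCPs assigned to
  each pattern (nearest centroid, Euclidean, ties to the lowest index) —
  a probability vector over states.
* **Mean regression coefficients**: each WQCP is modelled as a linear
  combination $\sum_k \beta_k R_k$ (no intercept, matching the model
  statement); $\beta$ is the least-squares solution, minimum-norm if the
  centroids are rank-deficient; the subject's feature is the mean
  $\beta$ over its WQCPs.

Training subjects are featurised with the same nearest-centroid rule as
test subjects rather than with the clustering's own labels: the two can
disagree only at cluster boundaries, and a single code path removes any
train/test asymmetry. The combined approach appends the $N$ static
strength features, giving $N + 2K$ features before selection.

### SVM-RFE and classification

Features are z-scored with training-split statistics (selection by
weight magnitude across heterogeneous scales — ratios next to strength
sums — would otherwise be meaningless). SVM-RFE then repeatedly fits a
linear SVM and discards the feature with the smallest squared weight
(step 1 by default), producing a full ranking; the retained subset is
the ranking prefix with the best inner stratified 5-fold CV accuracy
(ties to the smaller subset), or a fixed count via `rfe_n_features`.
The final classifier is an SVM tuned by inner stratified CV over
$C \in \{2^{-5},\dots,2^5\}$ and, for the RBF kernel,
$\gamma \in \{2^{-7},\dots,2^1\}$ (ties: smallest $C$, then smallest
$\gamma$), refit on the full training split. The kernel is configurable;
the default is RBF because a tuned $\gamma$ only exists for a nonlinear
kernel, while `kernel = "linear"` reproduces the purely linear variant.

### The protocol

`dfcp_crossval()` runs `repeats` (default 20) repetitions of stratified
5-fold CV — per-group fold sizes differ by at most one — giving 100 runs
with the defaults. Within every fold the DFCP model, the scaler, the RFE
ranking and the tuned hyperparameters are computed from training
subjects only; an optional second cohort can be held out entirely and
scored by every fold's classifier. All seeds derive from one master
seed, so the whole protocol is bit-reproducible, which the test suite
asserts, along with a perturbation test showing that corrupting a
held-out subject cannot change its fold's fitted pipeline. Aggregation
reports mean, sd and a $t$-based 95% CI per metric (accuracy, precision,
recall, specificity, F1; case = positive; zero-denominator metrics are
0 and flagged). Approach comparisons use a pooled-variance two-sample
$t$-test by default (Welch optional). The correlation between window
length and per-window mean metrics uses the five per-window means —
this choice reproduces, to the printed precision, all ten window-length
correlation coefficients of the published benchmark summary bundled in
`reference_window_metrics()`.

## The synthetic cohort generator

Real patient cohorts cannot be redistributed, so validation runs on a
generator that emulates exactly the structure the pipeline consumes:

* $K$ latent connectivity states, each a correlation matrix from random
  rank-2 loadings plus diagonal noise (unit diagonal by construction),
  resampled until pairwise Frobenius separation exceeds a floor
  ($0.15\,N$ by default) so states are distinguishable in dFCS space.
* A semi-Markov state sequence per subject: dwells are a 14-sample
  minimum plus a geometric tail with expected dwell proportional to the
  group's target occupancy (mean dwell 25 samples ≈ 50 s at TR 2 s, in
  the range reported for resting-state connectivity states), successors
  uniform among the other states — so expected time-occupancy equals the
  target exactly.
* Within a dwell, observations are zero-mean Gaussian with the state's
  correlation matrix, plus isotropic noise (sd 0.2).
* Group differences: case vs control occupancy 0.7/0.3 vs 0.3/0.7, and
  a static shift (loading offset 0.3 on 4 designated ROIs) raising the
  case group's strength there.

The reference conditions (the `"strong-effect"` preset) are 34 + 34
subjects, 20 ROIs, $T = 150$ at TR 2 s; the `"null"` preset removes
both group differences and must yield chance-level accuracy — the
negative control for leakage. The generator is deliberately a
second-order model: no hemodynamic response, physiological noise or
scanner drift. Passing tests therefore demonstrate that the pipeline
recovers switching covariance structure and group-differential
occupancy, not that it is robust to every artefact of real fMRI.

## Numerical choices and degenerate inputs

* Zero-variance ROI columns (globally or within a window) get zero
  correlations plus a warning instead of NaN, keeping dFCS bounded.
* Correlations are clamped to $[-1, 1]$ against floating-point overshoot;
  the diagonal is set to exactly 0.
* All-identical WQCPs: no structure, so the smallest candidate $K$ is
  returned with every centroid equal to the common point.
* `kmeans_k0` exceeding the WQCP count is lowered with a warning.
* Window/segment indexing is half-open and 0-based everywhere.
* Tie-breaks are fixed and documented: elbow → smaller $K$; pattern
  assignment → lowest index; RFE subset → smaller; hyperparameters →
  smallest $C$ then $\gamma$.

## Problem sizes used in validation

The shipped tests and the acceptance script use 20-ROI cohorts of
34 + 34 subjects at $T = 150$ with 5 protocol repetitions, and
100-seed loops for the segmentation and feature-selection recovery
properties; these sizes give stable pass/fail behaviour for every
property while keeping a full run in the minutes range on one core.
The pipeline itself is atlas-agnostic — `n_rois` is a parameter with a
246-ROI (Brainnetome-sized) preset — and `repeats = 20` reproduces the
full 100-run protocol.

## A small worked run

```{r example, eval = FALSE}
sim <- simulate_cohort(synthetic_preset("strong-effect", seed = 11))
cv <- dfcp_crossval(sim$cohort, approach = "combined",
                    window_seconds = 24,
                    params = protocol_params(repeats = 5, seed = 11))
summary(cv)
```

## Known limitations

* The segmentation threshold (`alpha`) is a heuristic; the original
  description of the automatic segmenter leaves its internals
  unspecified, and the counts it produces on real data cannot be used to
  pin the rule down.
* Occupancy ratio features are count-based over few segments per subject
  at typical scan lengths, so they are intrinsically noisy; the mean-β
  features partially compensate.
* The generator's Gaussian states make segmentation easier than real
  haemodynamics would; window-length effects in particular should not be
  extrapolated from synthetic runs.
* With RFE subset choice by inner CV, very small training splits can
  select unstable subsets; `rfe_n_features` pins the size when stability
  across folds matters more than per-fold optimality.
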