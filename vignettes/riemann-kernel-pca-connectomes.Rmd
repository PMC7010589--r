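---
title: "Classifying functional connectomes with Riemannian kernel PCA"
author: "riemfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional connectomes with Riemannian kernel PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riemfc)
```

## The problem

Resting-state fMRI yields, for each subject, a functional-connectivity (FC)
matrix: the $k \times k$ Pearson correlations between the time series of $k$
brain regions (ROIs). Diagnostic classifiers commonly flatten this matrix
into a vector of edges, discarding its structure. FC matrices are not
arbitrary vectors: their graph Laplacians are symmetric positive
semidefinite, and the set of symmetric positive-definite (SPD) matrices
forms a Riemannian manifold. `riemfc` implements a pipeline that respects
this geometry:

1. **Geometry** — each FC matrix $A_s$ becomes a graph Laplacian
   $L_s = D_s - W_s$ (with $W_s$ the off-diagonal correlations made
   nonnegative and $D_s$ the degree matrix), regularized to an SPD matrix
   $\hat L_s = L_s + \gamma I$. Distances between subjects use the
   log-Euclidean metric
   $d(\hat L_1, \hat L_2) = \lVert \log \hat L_1 - \log \hat L_2 \rVert_F$.
2. **Decomposition** — kernel PCA with the Gaussian kernel
   $K_{ij} = \exp\!\big(-d^2(\hat L_i, \hat L_j) / 2\sigma^2\big)$,
   double-centered in feature space. Subjects are represented by their
   scores on the leading principal axes.
3. **Classification** — gradient-boosted decision trees (xgboost) on the
   scores, evaluated by stratified 10-fold cross-validation
   (sensitivity / specificity / accuracy), with linear-PCA,
   Euclidean-Gaussian-kernel and raw-edge baselines and a support-vector
   baseline classifier.
4. **Interpretation** — the classifier's per-component importances are
   mapped back to an importance matrix over brain connections by solving
   the kernel-PCA pre-image problem on the SPD manifold.
5. **Seed-based statistics** — Fisher-Z seed-correlation maps, per-unit
   group comparison adjusting for age and sex, and symptom-severity
   regression.

Because clinical FC datasets are typically private, the package ships a
synthetic cohort generator that plants known group differences; every
claim the test suite makes is checked against that known ground truth.

## The synthetic cohort generator

`simulate_cohort()` draws each subject's $T \times k$ ROI time-series
matrix from a multivariate normal. Controls use a base correlation matrix
$R$; patients use $R$ with a configured set of *planted edges* shifted by
a target `effect`, repaired to a valid correlation matrix (eigenvalues
clipped at $10^{-6}$, diagonal renormalized). Design choices:

* **Base matrix** — a Wishart draw with $2k$ degrees of freedom rescaled
  to unit diagonal. This gives heterogeneous but well-conditioned FC
  structure (most $|r| < 0.5$), so modest planted shifts rarely trigger
  the repair step and the realized group difference stays close to the
  requested one (the suite checks $|\bar{\Delta r} - \text{effect}| <
  0.05$ at $n = 60$ per group, $T = 300$).
* **Observation noise** — `noise_sd` adds i.i.d. Gaussian noise on top of
  the latent signal; its default is 0 because additive noise attenuates
  *every* sample correlation toward zero and would bias the realized
  planted effect below its target. Sampling variability at finite $T$
  already provides realistic jitter.
* **Severity scores** — a YBOCS-like total is generated as
  `baseline + coupling * (subject's mean planted-edge sample correlation,
  centered within group) + noise`, with baseline 25 and residual SD 7 for
  patients, 2.4 and 2.9 for controls, floored at 0. Centering the
  covariate within group keeps scores on this scale for any coupling
  strength. Severity-recovery tests use `coupling = -150`: the
  between-subject SD of the planted-edge composite at $T = 300$ is about
  0.024, so this coupling gives a partial correlation near 0.45 and about
  95% power at $n = 61$ — chosen by this power analysis, not by trial.
* **What the generator does not emulate** — subject-level heterogeneity of
  the base correlation structure, autocorrelated BOLD dynamics, head
  motion, site effects. Within-group subjects share one population
  matrix, so between-subject variation is purely sampling noise. Passing
  tests demonstrate the machinery is correct and sensitive under its own
  assumptions; they do not certify accuracy figures on real cohorts.

`simulate_null_maps()` provides the matching harness for the GLM module:
per-subject unit values that are i.i.d. standard normal with group labels
assigned independently, so the true group effect is exactly zero.

## Geometry and kernel

Negative correlations have no standard treatment in a weighted-graph
Laplacian; the package defaults to `weight_transform = "abs"` (magnitude
preserved) with `"clip_negative"` as the alternative, and records the
choice in the object. Self-correlations are removed before degree sums.
The default regularization is $\gamma = 1$; classification accuracy is
insensitive to $\gamma$ over two orders of magnitude (the suite sweeps
$\gamma \in \{0.1, 1, 10\}$ and requires the accuracy range to stay under
5 points). Matrix logarithms are eigendecomposition-based with inputs
symmetrized as $(S + S^\top)/2$ and an SPD tolerance of $10^{-10}$.

**Bandwidth default.** The kernel scale $\sigma$ should sit near the
spread of the matrices. Two readings of "standard deviation of the
entries" exist: pooling all entries of all log-matrices into one sample
(a within-matrix spread), or aggregating the per-entry variance across
subjects. `default_sigma()` uses the latter:
$\sigma^2 = \sum_e \operatorname{Var}_s(\text{entry}_e)$, the mean squared
Frobenius deviation from the mean log-matrix. For independent subjects
$\mathbb{E}\, d^2 = 2\sigma^2$, so typical kernel entries are near
$e^{-1}$ *whatever* $\gamma$ is — this is what makes the pipeline
$\gamma$-insensitive in practice. The pooled reading is available as
`dispersion = "entry"`; it does not track the between-subject scale, and
at small $\gamma$ (where the log amplifies near-null directions of the
Laplacian) it collapses the kernel toward the identity and CV accuracy
toward chance. Both readings coincide in the scalar case.

**Centering and normalization.** The kernel is double-centered before
eigendecomposition ($K_c = K - \mathbf{1}K - K\mathbf{1} +
\mathbf{1}K\mathbf{1}$), the standard requirement for PCA semantics in
feature space; the same statistics are applied to new subjects at
transform time, so a training subject's out-of-sample projection equals
its fit-time score to $10^{-8}$. Eigenvector coefficients are normalized
as $\tilde\alpha = \alpha / \sqrt{\lambda}$ (unit-norm feature-space
axes). Components with $\lambda \le 10^{-10}\lambda_{\max}$ are dropped;
the default component count $n'$ is the smallest capturing 95% of the
centered-kernel trace, capped at $m - 1$.

## Classification

Boosted-tree hyperparameters follow conservative defaults for cohorts of
roughly a hundred subjects: depth 3, 200 rounds, learning rate 0.1, row
subsampling 0.8, single-threaded with a fixed seed for reproducibility.
Importance is split-gain based ("Gini" improvement averaged over trees),
normalized to sum to one. The "SVR" baseline is an
$\varepsilon$-regression support-vector machine on 0/1 labels thresholded
at 0.5, which is how a regression-style SVM yields classification
metrics. Cross-validation is stratified; within each fold the
decomposition is fitted on the training split only and test subjects
enter through the out-of-sample transform, so no information leaks from
the held-out fold. Chance-level behaviour is verified on zero-effect
cohorts: because fold predictions share training data, single-run null
accuracy is more variable than a binomial draw, so the null check uses
the median over three generator seeds against the binomial 95% band.

## Pre-image reconstruction

Tree importances live on the kernel-PCA components; connections live in
matrix space. The target in feature space is
$\sum_k \beta_k \tilde\alpha_k$ with $\beta$ the (optionally
label-signed) component importances. Writing the target plus the
feature-space mean as one combination of the uncentered training images
gives weights $\delta'_i = \delta_i + (1 - \sum_i \delta_i)/m$ with
$\delta_i = \sum_k \beta_k \tilde\alpha_{ik}$ — an exact treatment of
kernel centering under which, at full rank, reconstructing from a
training subject's own feature vector returns that subject *exactly*
(the weights reduce to a one-hot vector). The fixed point is iterated in
the log-matrix domain,

$$\log \hat L_{\text{new}} \;=\;
  \frac{\sum_i \delta'_i\, e^{-d^2(\hat L_{\text{old}}, \hat L_i)/2\sigma^2}
        \log \hat L_i}
       {\sum_i \delta'_i\, e^{-d^2(\hat L_{\text{old}}, \hat L_i)/2\sigma^2}},$$

the log-Euclidean analogue of the classical Gaussian-kernel pre-image
update (a weighted Fréchet mean per iterate; the two coincide in the
commuting/diagonal case). The objective $\sum_i \delta'_i K(\hat L,
\hat L_i)$ is monitored and the step is halved whenever it would
decrease; iteration stops when the relative Frobenius change drops below
`tol` (default $10^{-6}$), and five multiplicatively jittered restarts
guard against poor basins, the best objective winning. A vanishing
weight-sum denominator aborts with a suggestion to sign $\beta$. With
`center = FALSE` the classical uncentered weights $\delta_i$ are used;
that variant is invariant to positive rescaling of $\beta$.

Two design points where the field's conventions genuinely diverge:

* **Signing.** Tree importances are nonnegative, so a raw $\beta$ cannot
  distinguish a component that separates patients upward from downward.
  `discriminative_edges()` therefore signs each component by the
  point-biserial correlation of its training scores with the label. With
  signs, patient- and control-weighted contributions cancel on
  non-discriminative directions instead of averaging to the cohort mean.
* **Reference subtraction.** The raw pre-image is a realistic SPD matrix
  whose off-diagonals are dominated by connectivity common to everyone.
  The reported importance of an edge is therefore the displacement of the
  pre-image from the $\beta = 0$ reconstruction — the cohort's
  log-Euclidean Fréchet mean (`reference = "frechet_mean"`). On planted
  cohorts this is the difference between recovering 4–5 of 5 planted
  edges in the top 10 and recovering 2. `reference = "none"` gives the
  raw recovered adjacency.

Edges are ranked by $|$importance$|$ with lexicographic tie-breaks, and
each edge carries the empirical group difference in mean FC, which
restores effect direction for reporting.

## Seed-based statistics

`seed_map()` averages the seed units' time series, correlates the mean
signal with every unit, clips $r$ at $\pm(1 - 10^{-7})$ and applies
Fisher's $z = \operatorname{atanh}(r)$; the seed's own units are `NA`.
`group_glm()` fits per-unit OLS $z \sim 1 + \text{group} + \text{age} +
\text{sex}$ (vectorized across units; identical to per-unit `lm()`),
reporting the group coefficient's two-sided $t$ with $n - 4$ degrees of
freedom. The default is uncorrected $p < .05$, with Benjamini–Hochberg
FDR available and recorded. With `covariates = character(0)` the group
$t$ equals a pooled-variance two-sample $t$ test exactly, which is how
the suite cross-checks it. `severity_regression()` fits $z \sim 1 +
\text{severity} + \text{age} + \text{sex}$, on patients only by default
(control scores sit near the floor of the scale and would mostly re-encode
group membership); a flag includes all subjects. Sex enters as a single
indicator; designs with a constant sex column are rejected by name.

The package ships an editable AAL-116 label table assigning the 26
cerebellar ROIs to three lobes usable as seeds — anterior (lobules I–V:
Cerebelum 3, 4_5, Vermis 1_2–4_5), posterior (VI–IX incl. Crus I/II and
Vermis 6–9) and flocculonodular (lobule X and Vermis 10). This is an
anatomical best effort, not a canonical standard; `seed_map()` accepts
arbitrary index sets.

## Problem sizes and numerical choices

The validation suite runs on cohorts of 60 + 60 subjects, $k = 20$ ROIs,
$T = 300$ time points, 5 planted edges at effect 0.3 — sizes comparable
to a single-site clinical study and small enough for the whole suite to
run in well under a minute. Symmetry tolerance is $10^{-10}$ (inputs
symmetrized before eigendecomposition), kernel PSD tolerance $10^{-8}$,
component-dropping threshold $10^{-10}\lambda_{\max}$. Stratified folds,
xgboost subsampling and all simulations run under explicit seeds;
re-running with the same seeds is bit-identical.

## Known limitations

* The generator's within-group homogeneity makes classification easier
  than on real cohorts at the same effect size; reported accuracies on
  synthetic cohorts are properties of the pipeline, not clinical claims.
* The log-Euclidean metric is not affine-invariant; that is a deliberate
  trade for a closed-form distance.
* Pre-image reconstruction is a non-convex fixed point; restarts mitigate
  but do not eliminate local basins, and `converged = FALSE` results are
  returned with a warning rather than suppressed.
* Voxelwise maps are supported only as flat unit vectors; there is no
  volume handling, cluster-extent inference, or fMRI preprocessing.
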