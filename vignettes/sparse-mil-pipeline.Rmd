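---
title: "Sparse-representation multi-instance learning for breast ultrasound ROIs"
author: "sparseMIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-representation multi-instance learning for breast ultrasound ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseMIL)
```

## The problem

Computer-aided diagnosis of breast masses works on a square region of
interest (ROI) cropped around a suspected lesion. The ROI carries a single
label — benign or malignant — but the evidence for that label is spread
unevenly across its subregions: a malignant mass is not malignant at every
pixel, and a benign one is not uniformly innocent. Supervised learning on
whole-ROI feature vectors throws this structure away; labelling subregions
by hand is impossible. Multi-instance learning (MIL) is the natural fit:
the ROI is a *bag*, its subregion feature vectors are unlabelled
*instances*, and only bags carry labels. We adopt the generalized MIL
premise that a *fraction* of concept instances — not a single witness —
determines a positive bag, which matches the histology of solid tumours
better than the classical one-positive-instance rule.

`sparseMIL` implements the full pipeline: ROI enhancement, concentric-circle
bag-of-visual-words features with latent Dirichlet allocation (LDA) topic
reduction, conversion of the MIL problem to a single-instance problem by
dictionary learning and l1 sparse coding, relevance vector machine (RVM)
classification combined over dictionary sizes, and a stratified
cross-validation protocol reporting sensitivity, specificity, accuracy and
ROC/AUC. A synthetic-data module generates phantom ROI images and
feature-space bags so that every stage is testable without clinical data.

## Enhancement operators

Four operators prepare a raw ROI for segmentation and feature extraction.
All images are numeric matrices with intensities in $[0,1]$; every operator
maps $[0,1]$ images to $[0,1]$ images (clipping on write).

**Neighbour-tissue suppression.** With $r$ the estimated mass radius and
$(x, y)$ integer pixel offsets from the ROI centre,
$$L(x,y) = R(x,y,\sigma,r)\, I(x,y), \qquad
R = \begin{cases} e^{(r^2 - (x^2+y^2))/2\sigma^2} & x^2+y^2 > r^2 \\
1 & \text{otherwise,} \end{cases}$$
so the mass is untouched and surrounding tissue fades with distance. $R$ is
continuous at the boundary ($R \to 1$ as $x^2+y^2 \to r^2$), bounded in
$(0,1]$, and non-increasing in distance. The default
$\sigma = \text{side} - r$ is the setting that gives the cleanest
downstream segmentation; callers may override it. The radius $r$ itself
comes from `estimateRadius()`: threshold at the level maximizing
between-class variance, take the largest connected bright component of
area $A$, return $\sqrt{A/\pi}$ clipped to $[2, \text{side}/2 - 1]$. No
published recipe exists for this step, so the package uses this
area-inversion estimate throughout (including as the radius feeding the
suppression operator).

**Background correction.** A plane $a + bx + cy$ is fitted to the
intensities by ordinary least squares and subtracted; the residual is
rescaled linearly to the original $[\min, \max]$ intensity range. The
rescale target is a design choice — the residual has to live somewhere in
$[0,1]$, and re-spanning the input range preserves the original dynamic
range without inventing contrast. An exact plane input yields a constant
output; a constant input passes through unchanged.

**Gamma transform.** $G = c X^{r}$ pointwise, default $c = 1$,
$r = 1.5$. Exponents above 1 spread the high-gray range where both the
mass and adhering tissue live. The exponent default is a choice from the
open interval $r > 1$; 1.5 separates the distributions without crushing
the low grays on typical phantoms.

**Gaussian smoothing.** Convolution with the isotropic kernel
$e^{-(x^2+y^2)/2\sigma^2}/2\pi\sigma^2$, truncated at $\pm\lceil 3\sigma
\rceil$ and renormalized so the discrete kernel sums to exactly 1, with
symmetric (reflect) boundary handling — so constants are preserved to
machine precision and smoothing never increases the intensity variance.
The kernel is isotropic in $x^2 + y^2$; an anisotropic diagonal form would
contradict the operator's role as a standard smoothing template.

`segmentROI()` (threshold maximizing between-class variance, largest
component, hole filling) stands in for a full mass segmentation; it is a
deliberately simple component whose contract — exactly one foreground
component, idempotent on its own output — is what the feature stages rely
on.

## Concentric-circle features

After resizing so the longest side is at most 1000 pixels, dense local
descriptors are computed on a regular grid (default step 8): each point is
described by a 4x4-cell, 8-orientation gradient-magnitude histogram (128
dimensions, the SIFT layout), L2-normalized. Dense sampling rather than
keypoint detection keeps the descriptor set deterministic and testable; the
positions depend only on the image shape.

A visual vocabulary of $M$ words (default 200) is learned by k-means with
seeded k-means++ initialisation and Lloyd iterations; ties in both
clustering and word assignment resolve to the lowest index, making every
downstream count reproducible bit-for-bit.

Round masses motivate a radial spatial layout instead of the rectangles of
spatial pyramid matching: half the image diagonal is divided into $N$ equal
portions, giving a central disk and $N-1$ annuli that partition every
pixel. Each descriptor is counted once in the whole-image histogram $F_0$
and once in its zone's histogram $F_i$, so $\sum_i F_i = F_0$ always. The
combined feature is the weighted *concatenation*
$[\lambda_0 F_0, \lambda_1 F_1, \ldots, \lambda_N F_N]$, of dimension
$M(N+1)$ — 1000 for $M = 200$, $N = 4$. (A literal sum of the blocks would
be $M$-dimensional and could not produce that dimension; concatenation is
the only reading consistent with it.) All weights default to 1.

**Topic reduction.** The count vectors are documents for LDA with $K$
topics (default 80), symmetric Dirichlet prior $\alpha = 50/K$ on
document-topic proportions and smoothing $\beta = 0.01$ on topic-word
distributions. Inference is collapsed Gibbs sampling (500 sweeps by
default), with the joint log-likelihood recorded per sweep; new documents
are folded in with the topic-word matrix held fixed, averaging the
smoothed topic counts over post-burn-in sweeps. An all-zero document
returns the uniform prior mean. Each image block (whole image and each
zone) is transformed as its own document.

## From bags to a single-instance problem

Each ROI becomes a bag whose instances are the $K$-dimensional topic
vectors of its $N + 1$ blocks — the zones are the only subregions the
feature model constructs, so they are the natural instances. Given pooled
training instances as columns of $X \in \mathbb{R}^{k \times m}$, a
dictionary $D \in \mathbb{R}^{k \times s}$ with unit-norm columns is
learned so every instance is a sparse linear combination of atoms:
$$\min_{D, \alpha} \sum_e \lVert x_e - D\alpha_e \rVert_2^2
 + \gamma \lVert \alpha_e \rVert_1, \qquad \gamma > 0 .$$

The coding step solves the l1 problem exactly by cyclic coordinate descent
(soft threshold at $\gamma/2$, Gram-matrix covariance updates, active-set
sweeps, convergence when the largest coefficient change falls below
$10^{-8}$). The dictionary step follows the K-SVD structure: for each atom,
a rank-1 SVD of the residual restricted to the columns that use it
proposes a new atom and coefficients. Because the l1 penalty is not part
of what the SVD minimises, each proposal is accepted only if it lowers the
penalised objective; together with warm-started coding (every coordinate
update is a descent step) this makes the recorded objective provably
non-increasing — a property the test suite asserts on every run. Atoms
that no instance uses are re-seeded with the worst-reconstructed data
column, which leaves the objective unchanged. An orthogonal matching
pursuit coder (`ompCode`) is included for comparison with the classical
l0 coding step.

A bag $B$ with codes $\tilde\alpha \in \mathbb{R}^{s \times J}$ is pooled
to one $s$-vector: $b_h = \operatorname{avg}_j |\alpha_h^j|$ (default) or
$\max_j |\alpha_h^j|$. The literature describing this construction names
max pooling but writes the averaging formula; both are implemented and
tested, with `avg` as the default because the formula is the more precise
statement. Either way every bag becomes a fixed-length row and the MIL
problem is an ordinary supervised one.

## Classification and evaluation

The classifier is a relevance vector machine: kernel logistic regression
with an RBF kernel (width defaulting to the median pairwise training
distance), independent Gaussian priors on the weights, and per-weight
precisions re-estimated by evidence maximisation under a Laplace
approximation. Weights whose precision exceeds $10^6$ are pruned; the few
surviving training rows are the relevance vectors. The fit stops when the
largest change in log-precision falls below $10^{-3}$ or after 300 cycles.

One RVM is trained per dictionary size in the size set $S$. At prediction
time labels are combined by majority vote with ties resolved toward
malignant — in a diagnostic setting a false alarm is cheaper than a missed
cancer — and ROC scores are the mean member posterior. (Vote fraction is
an alternative score; the mean posterior is smoother and is what the ROC
sweep uses.)

Evaluation uses stratified k-fold cross-validation (default 10 folds)
with every fitted object — codebook, topic model, dictionaries,
classifiers — trained inside the training fold only; the test suite
checks that flipping held-out labels leaves the learned dictionaries
bit-identical. Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy
(TP+TN)/total are reported as percentages; the ROC curve is a threshold
sweep whose trapezoid AUC equals the rank (Mann-Whitney) statistic,
verified against that identity in tests. Repeats default to 10 where
repetition is requested; the protocol is configurable.

## What the synthetic data emulates

**Phantom images** emulate the two morphologies the field describes:
benign masses as filled ellipses (axis ratio 0.7–1) with smooth margins and
homogeneous intensity; malignant masses as star polygons with random-length
spicules and heterogeneous texture. The background is an intensity plane
with an optional vertical shadow band, and speckle is multiplicative
Rayleigh-derived noise — the standard surrogate for ultrasound speckle.
Defaults (128-pixel side, contrast 0.45, speckle scale 0.12, nine
spicules, slope 0.0015) were chosen once as plausible desk-scale study
conditions. Two deliberate departures from real ultrasound: masses are
generated *brighter* than background, consistent with the
bright-centre assumption built into the radius estimator and segmenter
(real breast-ultrasound masses are typically hypoechoic, i.e. dark), and
the speckle model ignores the point-spread correlation of real speckle.
Passing tests therefore demonstrate that the pipeline recovers the
geometry-plus-texture signal it models — not that it would reach the same
accuracy on clinical images.

**Feature-space bags** implement the generalized-MIL premise directly:
concept instances $\sim N(\mu_+, I)$, background instances
$\sim N(\mu_0, I)$, $\lVert \mu_+ - \mu_0 \rVert = \Delta$; positive bags
contain exactly $\lceil \rho J \rceil$ concept instances and negative bags
none. $\Delta$ is the separation in noise-SD units, so $\Delta = 0$ makes
the classes exchangeable (a built-in null) and accuracy must rise with
$\Delta$ — both are asserted in the acceptance suite.

**Tabular data.** The Breast Cancer Wisconsin (Original) dataset loader
parses the UCI comma-separated dialect (id, nine integer attributes with
`?` for missing bare-nuclei values, class 2/4) and reproduces the
published per-attribute statistics. Records enter the MIL pipeline only as
single-instance bags ($J = 1$): a tabular record has no subregions, and
any richer embedding would be invented structure.

## Numerical choices

* Seeds: every stochastic routine takes a seed, saves and restores the
  caller's RNG state, and derives child seeds (always below $2^{31}$) for
  sub-tasks, so ensembles and cross-validation runs are reproducible
  end-to-end; the pipeline fingerprints its configuration with a content
  hash written into every report.
* Ties: k-means assignment, visual-word assignment and OMP atom selection
  all break ties to the lowest index; ensemble votes break toward
  malignant.
* Initialisation: codebooks start from seeded k-means++ draws;
  dictionaries start from normalized data columns chosen by seeded
  farthest-point selection on angular distance, which avoids the
  near-duplicate initial atoms a uniform draw produces and markedly
  speeds convergence on clustered instance data.
* Tolerances: lasso coordinate updates converge at $10^{-8}$; K-SVD
  monotonicity is asserted at $10^{-9}$ slack; kernel mass and simplex
  checks at $10^{-12}$ and $10^{-9}$.
* Degenerate inputs: constant images are rejected by the radius estimator
  and segmenter ("no mass"); all-zero descriptor windows stay zero
  vectors; all-zero documents get the uniform topic prior; empty bags,
  single-class training sets and mismatched dimensions raise immediate
  errors.

## Problem sizes used by the test and acceptance runs

The shipped suites run the full method at desk scale, chosen so the whole
battery completes comfortably on one CPU: bag-level recovery uses
$\Delta \in \{0, 2, 6\}$, $\rho = 0.5$, $J = 8$, $k = 10$, 50 + 50 bags
with a dictionary of 32 atoms (10-fold CV), and a lighter 25 + 25-bag,
16-atom, 5-fold configuration for the ten-seed monotonicity sweep; the
ensemble experiment uses sizes $\{10, 20, 30, 40, 50\}$ at $\Delta = 3$;
the image pipeline runs 40 phantoms with $M = 64$, $K = 16$,
$S = \{16, 32\}$ and 5-fold CV. Published-scale settings
($M = 200$, $K = 80$, sizes up to 500, 100 repeats) remain available
through the same interfaces.

## Limitations

* The segmentation stand-in is intentionally minimal; the package does not
  attempt wavelet- or knowledge-based mass segmentation.
* Reported accuracies on synthetic phantoms and simulated bags do not
  transfer to clinical image sets; the generators model shape, contrast
  and speckle, not acoustics, posterior features or BI-RADS variability.
* The RVM uses the standard Laplace-approximated evidence updates; no
  marginal-likelihood guarantees are made for the pruned model, and
  posteriors are not calibrated.
* Dictionary learning is batch; there is no online or per-class variant.
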