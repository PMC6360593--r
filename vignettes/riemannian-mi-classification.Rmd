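---
title: "Classifying motor-imagery EEG on the manifold of covariance matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying motor-imagery EEG on the manifold of covariance matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(riemi)
```

## The model

A motor-imagery (MI) brain–computer interface asks a subject to imagine a
movement (left hand, right hand, foot, tongue, ...) and decodes which one
from short multichannel EEG epochs. For an epoched trial
$X_i \in \mathbb{R}^{n \times T_s}$ ($n$ channels, $T_s$ samples, band-pass
filtered so it is effectively zero mean), the spatial covariance matrix

$$P_i = \frac{1}{T_s - 1} X_i X_i^\top$$

is a near-sufficient statistic for the class: imagined movements express as
class-specific spatial power patterns. Covariance matrices live on the cone
of symmetric positive-definite (SPD) matrices, which `riemi` treats with the
affine-invariant Riemannian metric

$$\delta_R(P_1, P_2) = \lVert \log(P_1^{-1} P_2) \rVert_F
 = \Big(\sum_i \log^2 \lambda_i\Big)^{1/2},$$

where $\lambda_i$ are the generalized eigenvalues of the pair. The metric is
invariant under congruence $P \mapsto W P W^\top$, i.e. under any linear
mixing of the channels — which is exactly the nuisance structure of EEG.

Two classification routes are built on this geometry:

* **Method 1 (SSDT-FGMDRM).** Minimum distance to Riemannian mean (MDRM)
  assigns a trial to the class whose Karcher mean is nearest. Fisher
  geodesic discriminant analysis (FGDA) first projects tangent-space
  coordinates onto the most discriminative directions and reconstructs
  "filtered" covariances (FGMDRM). These classifiers sit in the nodes of a
  subject-specific decision tree (SSDT): classes are ranked per subject by
  one-vs-rest cross-validated separability, the most separable classes get
  dedicated binary nodes, and a final multiclass node reclassifies
  everything that passed through.
* **Method 2 (SJGDA + SSDT-KNN).** Trials are mapped to the tangent space
  at the Riemannian mean (vectors of length $n(n+1)/2$), features are
  ranked by (semi-supervised) joint mutual information, a per-subject
  length $m$ is chosen by cross-validated accuracy, polynomial-kernel
  generalized discriminant analysis (GDA) compresses the retained features
  to $d = 1$ dimension, and the concatenation $[f_G \,|\, f_{SJ}]$ feeds
  k-nearest-neighbour nodes of the same tree.

## Geometry: algorithms and numerical choices

All matrix functions (square root, inverse square root, log, exp) use the
symmetric eigendecomposition, with eigenvalues floored at $10^{-12}$ times
the largest before inversion or logarithms. The Karcher mean uses the
classical fixed-point flow

$$M \leftarrow M^{1/2} \exp\!\Big(\eta\, \tfrac1I \sum_i
  \log\big(M^{-1/2} P_i M^{-1/2}\big)\Big) M^{1/2},$$

initialized at the arithmetic mean with step $\eta = 1$, stopping when the
mean ambient tangent displacement falls below `tolerance` (default
$10^{-8}$) times the mean Frobenius norm of the inputs, erring (with the
last iterate attached to the condition) after `max_iterations` (default
100). On SPD matrices with its nonpositive curvature this flow converges
globally; in practice three to six iterations suffice.

Half-vectorization `upper()` scans the upper triangle row-major and scales
off-diagonal entries by $\sqrt 2$. This makes the map a linear isometry
from the tangent metric at the reference into Euclidean space:
$\lVert \mathrm{upper}(\log(P_\Im^{-1/2} P_i P_\Im^{-1/2})) \rVert_2 =
\delta_R(P_\Im, P_i)$, which is the property that makes Euclidean
classifiers in the tangent plane meaningful. The weighting is a
convention; the tests pin it down via the isometry property.

Rank-deficient covariance estimates (short epochs) are shrunk towards
$(\mathrm{tr}(P)/n) I$ with the smallest $\gamma \in \{10^{-6}, 10^{-4},
10^{-2}\}$ restoring a condition number below $10^{10}$, with a message.

## FGDA, ties, and other degrees of freedom

FGDA is implemented as a Fisher discriminant on tangent vectors anchored at
the global Riemannian mean: the basis spans the top $r$ generalized
eigenvectors of (between-class, within-class) scatter, orthonormalized; a
ridge of $10^{-9}\,\mathrm{tr}(S_W)/p$ is added to $S_W$ when it is
ill-conditioned. The default $r = C - 1$ for $C$ classes; with full $r$
the filter is the identity and FGMDRM reproduces MDRM exactly (a tested
reduction). Filtering reconstructs an SPD matrix through the exponential
map, so FGMDRM literally runs MDRM on filtered covariances.

Ties are deterministic everywhere: MDRM distance ties go to the first
class in label order (with a message); KNN vote ties go to the smallest
summed neighbour distance, then label order; ranking ties keep the
original feature or class order; length-selection ties prefer the smallest
$m$.

## The decision tree

For $C$ classes the tree has $\max(C-2, 0)$ binary one-vs-rest nodes plus
one final multiclass node ($2+1$ nodes for four classes, $1+1$ for three;
two classes degenerate to the base classifier with a warning). Node order
comes from stratified 10-fold one-vs-rest CV accuracy ("rest" keeps its
natural imbalance, and plain accuracy is the ranking score). Each later
binary node excludes previously targeted classes from its training pool.
The final node is trained on *all* classes by default so samples leaked
past the binary nodes remain recoverable; `final_scope = "remaining"`
restricts it to the untargeted classes. A sample routed down the tree is
claimed by the first binary node that predicts its own target, otherwise
the final node decides.

A structural property worth knowing (and tested): with the all-classes
final node, the tree can only *lose* relative to its flat counterpart on
samples wrongly captured by a binary node — never on samples passed down.
Conversely it only *wins* where a binary node corrects the flat
classifier on that node's own target. On the synthetic generator below,
where the flat nearest-mean rule is already close to Bayes-optimal, the
two are therefore nearly always tied: the tree is non-inferior but not
systematically better. Real EEG, with its heterogeneous and non-elliptic
class geometry, is where the tree has room to help; synthetic parity is
the honest desk-scale statement of that claim, and the accompanying
checks assert non-inferiority while the stricter "usually wins" claim
does not reproduce under this generator.

## Feature stack (method 2)

*Discretization.* Mutual information is estimated by plug-in on
equal-frequency bins (8 by default; results are stable across 4–16), with
bin edges fitted on all rows, labelled and unlabelled alike.

*JMI ranking.* Greedy forward selection: the first feature maximizes
$I(X_k; Y)$, then candidates are scored by
$\sum_{X_j \in \text{selected}} I(X_k, X_j; Y)$ — the joint of the
candidate and each selected feature with the label — which rewards
complementarity and demotes redundant duplicates. A conditional variant
($\sum_j I(X_k; Y \mid X_j)$) is available as `criterion = "cmim"`. The
implementation is checked against an exhaustive re-evaluation of the
greedy recursion.

*Semi-supervised estimation.* Under the class-prior-change missingness
model, the class-conditional feature distributions $p(x \mid y)$ are
estimated from labelled rows only, the class priors are re-estimated by EM
on the unlabelled marginal, and every MI term is assembled from the
reweighted joint $\pi_y\, p(x \mid y)$. With an empty unlabelled pool the
code path reduces to the supervised estimator bit-for-bit.

*Length selection.* $m$ maximizes stratified-CV accuracy of a downstream
classifier (KNN, $k=5$) over a grid; the grid is capped at the first 100
ranked variables for 22-channel-scale data and 60 for 14-channel-scale
data — both caps are configuration, not hard-coded.

*GDA.* Kernel Fisher discriminant with a polynomial kernel
$k(x, y) = (s \langle x, y\rangle + c)^{\mathrm{deg}}$ (defaults: degree
2, $c = 1$, $s = 1/\text{dim}$). The centered kernel matrix yields
between- and within-class scatter in coefficient space; the denominator is
within-class scatter by default (total scatter available). The
eigenproblem is ridge-regularized with default $10^{-2}$ — deliberately
large for a kernel method: with a near-vanishing ridge the discriminant
memorizes the training set (training-set class separations of order $10^4$
within-class standard deviations) and its projection generalizes poorly,
while $10^{-2}$ costs nothing on separable problems. The ridge escalates
tenfold on numerical failure. Projections are normalized to unit pooled
within-class variance per output dimension, and $d = 1$ by default.

*SJGDA.* The transform is $[f_G \,|\, f_{SJ}]$: the GDA projection
concatenated with the top-$m$ ranked raw tangent features, length $m + d$.

Inside the tree, the whole stack is refit per node on that node's own
binary or multiclass problem by default (`feature_scope = "per_node"`);
a single shared feature space is available as `"global"`.

## Preprocessing

A Butterworth band-pass (prototype order 5, 8–30 Hz — the mu/beta band of
motor imagery) is applied per channel, forward-backward by default for zero
phase (a causal single pass is a flag). Epochs are cut in the half-open
window $[\text{cue} + \mathrm{round}(0.5 f_s),\ \text{cue} +
\mathrm{round}(2.5 f_s))$ — 500 samples at 250 Hz, 256 at 128 Hz. The
0-based half-open convention is fixed and documented because off-by-one
conventions differ across BCI toolchains.

## What the synthetic generator emulates — and what it does not

The generator encodes class identity purely in the spatial covariance:
a Toeplitz base covariance $\Sigma_0[i,j] = \rho^{|i-j|}$ (channel
correlation decay $\rho = 0.3$) plus a class-specific rank-2 perturbation
$\text{sep}_c (u_c u_c^\top + v_c v_c^\top)$ with orthonormal directions —
a stylized version of class-specific spatial power patterns. Per trial, a
covariance is drawn from a Wishart centered on the class covariance
(degrees of freedom `noise_df` model trial-to-trial variability), Gaussian
samples are drawn with it, band-pass filtered, and rescaled by the
filter's white-noise power gain so the covariance scale is preserved.
`separation` may be a per-class vector; zero separation makes all classes
identically distributed, which anchors chance-level behaviour
(accuracy $1/C$, $\kappa \approx 0$) as a generator property.

```{r generator, eval = FALSE}
cfg <- generator_config(n_channels = 8, trials_per_class = 100, classes = 4,
                        separation = 5, noise_df = 200, seed = 11)
dat <- generate_trials(cfg)
covs <- lapply(dat$trials, compute_scm)
model <- mdrm_fit(covs, dat$labels)
```

The generator matches the sufficient statistic of the classifiers under
test, which makes parameter recovery meaningful — and means passing tests
demonstrate correctness of the geometry and the pipelines, *not*
performance on real EEG. Not emulated: realistic forward models, artifacts,
nonstationarity, volume conduction differences across subjects, or
non-Gaussian temporal structure.

Benchmark conditions used by the tests and the acceptance script (chosen
once as representative problem sizes): the recovery benchmark uses 8
channels, 100 trials per class, four classes, Wishart df 200, separation 5,
2-s epochs at 250 Hz; the mixed-separability scenario uses separation
$(6, 6, 0.3, 0.3)$ with df 20, calibrated (on seeds disjoint from the
evaluation seeds) so that two classes are cleanly separable while the
other two confuse each other on roughly a quarter of trials; the
feature-stack comparison uses two classes, 6 channels, 75 trials per
class, separation 1, df 30. Internal cross-validation fold counts are
reduced (3–5) on the smaller problems to keep the suites fast; fold
assignment is always stratified and seeded.

## Cross-validation and leakage

`crossval()` runs stratified k-fold CV of either method. Everything that
is fitted — node ranking, feature ranking, length selection, GDA, all
Riemannian means — happens inside each training fold; held-out labels are
used for scoring only, so permuting them cannot change a fitted model (a
tested invariant). Length selection is therefore re-run per fold, which is
stricter than selecting once per subject. Leave-one-out is the degenerate
case `folds = number of trials`. Reports carry per-fold accuracy and
Cohen's kappa, the aggregated confusion matrix, per-node routing counts,
node order with ranking accuracies, and selected $m$ per node; `tidy()`,
`glance()`, and `autoplot()` methods give tibbles and plots.

## Known limitations

* The affine-invariant metric only; no log-Euclidean or divergence-based
  alternatives.
* Exact eigendecompositions throughout; no large-$n$ approximations.
* The FGDA construction follows the standard tangent-space Fisher
  discriminant; the original filter construction it abstracts is not
  uniquely pinned down by published descriptions, so `r` is configurable
  rather than asserted.
* The semi-supervised MI estimator is one defensible instance of the
  class-prior-change family (EM-reweighted priors over discretized
  marginals); the supervised path is the reference behaviour.
* Readers for competition GDF/MAT archives are not included; epoched
  trials enter as plain matrices or the CSV+JSON trial archive.
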