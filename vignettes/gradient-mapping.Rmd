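---
title: "Macroscale gradient mapping: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macroscale gradient mapping: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradmap)
```

# The problem

Many measures of brain organization arrive as a matrix $X \in \mathbb{R}^{n
\times p}$ whose rows are seed regions and whose columns are features of each
seed — most commonly a connectivity profile (functional correlation,
tractography-derived streamline counts, microstructural covariance) with $p$
target regions. Beyond parcellating such matrices into discrete modules, an
ordering of regions along smooth axes — *gradients* — captures graded,
hierarchical aspects of cortical organization. `gradmap` implements the full
gradient workflow: affinity construction, spectral embedding, cross-dataset
alignment, and statistical comparison against null models that respect
spatial autocorrelation.

# Affinity construction

Dimensionality reduction operates on an $n \times n$ symmetric non-negative
affinity $A$, with $A(i,j)$ the similarity between the feature vectors
$\mathbf{x}_i$ and $\mathbf{x}_j$ of seeds $i$ and $j$.

**Row-wise sparsification.** Before the kernel, each row of $X$ is
thresholded to its top $k = \lceil \texttt{keep\_fraction} \cdot p \rceil$
entries (ties resolved toward the lowest column index, so the operation is
deterministic). Weak entries of connectivity matrices are dominated by noise;
discarding them sharpens the manifold structure. Terminology is a known
source of confusion, so both conventions are accepted explicitly:
`sparsity` is the fraction *zeroed*, `keep_fraction = 1 - sparsity` the
fraction retained. The default keeps the top 10% of each row, the common
choice for dense vertex-level connectomes. For small matrices this default
deserves thought: a top-$k$ graph with $k = 10$ on $n \approx 100$ seeds can
disconnect when latent clusters do not share supports, and the embeddings
(correctly) refuse disconnected graphs. At $n \approx 100$ we recommend and
use `keep_fraction = 0.25` in the package's own validation experiments.
Whether the diagonal of a square input participates in thresholding is not
standardized anywhere; here the diagonal is treated like any other entry.

**Kernels.** Five kernels are provided, all computed on the (sparsified)
rows:

* Gaussian: $A(i,j) = e^{-\gamma\|\mathbf{x}-\mathbf{y}\|^2}$, $\gamma$ the
  inverse width. When `gamma = NULL` the scale-free median heuristic
  $\gamma = 1/(2\,\mathrm{median}\,\|\mathbf{x}_i-\mathbf{x}_j\|^2)$ is
  used; it is computed over all pairs (or a deterministic strided subsample
  above $10^6$ pairs) so the default never consumes random numbers.
* Cosine similarity, and normalized angle
  $1 - \cos^{-1}(\mathrm{cossim})/\pi$, which maps angles into $[0,1]$ and
  needs no clamping.
* Pearson correlation (cosine of the row-demeaned vectors) and Spearman
  rank correlation (Pearson on average ranks; ties receive average ranks).

Correlation-type kernels range over $[-1,1]$; negative similarities are set
to zero by default (`clamp_negative = TRUE`), the standard mitigation, since
the spectral methods require non-negative weights. A precomputed square
symmetric affinity can be passed through unchanged (`kernel =
"precomputed"`). The package default kernel is cosine similarity, the
kernel used in the canonical gradient workflow on functional connectivity.

# Spectral embeddings

All three methods return a `gradient_result` with $n \times m$ coordinates
and the associated spectrum.

**PCA.** The input is column-demeaned ($X_d$) and factorized, $X_d = USV^T$;
the gradients are the scores $US$ and `variance_explained` is
$s_k^2/\sum s^2$.

**Laplacian eigenmaps.** With degree matrix $D$ and Laplacian $L = D - A$,
solve $L\mathbf{g} = \lambda D\mathbf{g}$ and keep the eigenvectors of the
$m$ smallest eigenvalues, excluding the trivial constant eigenvector at
$\lambda = 0$. Numerically this is done through the symmetric form
$I - D^{-1/2} A D^{-1/2}$, which shares eigenvalues with the generalized
problem; eigenvectors map back via $D^{-1/2}$. (The symmetric normalized
Laplacian is $D^{-1/2} L D^{-1/2}$; forms with positive powers of $D$ that
sometimes appear in print are typos, as the $\alpha = 0$ diffusion limit
below makes clear.) Output columns are normalized to unit Euclidean norm,
which also makes them invariant to positive rescaling of $A$.

**Diffusion maps.** The affinity is density-normalized,
$W_\alpha = D^{-\alpha} A D^{-\alpha}$ (the standard Coifman–Lafon form),
and the row-stochastic operator $P_\alpha = D_\alpha^{-1} W_\alpha$ is
eigendecomposed through its symmetric conjugate. The anisotropy parameter
$\alpha \in [0,1]$ controls the influence of sampling density: $\alpha = 0$
reduces to the random-walk operator $D^{-1}A$, $\alpha = 1$ approximates
the Laplace–Beltrami operator, and the default $\alpha = 0.5$ (Fokker–Planck
diffusion) is the convention in the gradient literature. The stationary
eigenvector ($\lambda = 1$) is omitted and gradient $k$ is
$\lambda_k^t \mathbf{g}_k$. The diffusion time has no canonical default;
`t = 0` selects the multiscale scaling $\lambda/(1-\lambda)$, matching
common practice, while any $t > 0$ applies $\lambda^t$ literally.

**Numerical choices.** Eigenvector sign is intrinsically arbitrary; every
returned column is flipped so its largest-magnitude entry is positive (ties
to the lowest index), making results reproducible bit-for-bit. All solvers
are dense symmetric eigendecompositions (`eigen(symmetric = TRUE)`); at the
problem sizes this package targets in its tests and experiments
($n \le 1000$) a dense solve is faster and simpler than iterative methods,
and exact determinism comes for free. Disconnected affinity graphs are an
error (with the component count reported) rather than a silent
per-component embedding: gradients of disconnected graphs are not
comparable across components. Connectivity is checked by union–find on the
nonzero pattern.

# Alignment

Eigenvalue multiplicity can reorder eigenvectors between datasets, and sign
ambiguity can flip them; alignment restores comparability.

**Procrustes.** `procrustes_align()` finds the orthogonal $\psi$ minimizing
$\|\psi(\mathcal{G}_s) - \mathcal{G}_t\|_F$ via the SVD of the
cross-product matrix. Reflections are deliberately allowed — sign flips are
exactly the pathology being repaired. Centering and isotropic scaling are
off by default: gradient sets from the same pipeline are already
commensurate, and the minimal transform changes individual manifolds least.
`generalized_procrustes()` iterates align-then-average; a supplied
reference seeds the first iteration (template mode). Convergence is
declared when total disparity falls below $10^{-10}$ of the template scale
or changes by less than that relative tolerance (the field has no standard
convergence rule; these thresholds are the package's choice), with a
10-iteration default cap. The disparity sequence is non-increasing, which
the tests assert at every iteration.

**Joint embedding.** Alternatively, several datasets sharing the same
features are embedded simultaneously through the block matrix
$\mathcal{J}$ of within- and cross-dataset kernels (all built with the same
kernel). The joint matrix is embedded with LE or DM and sliced back into
per-dataset blocks that live in one shared space. The $\lambda^t$ scaling
uses the joint spectrum (not per-block rescaling), since the whole point is
a single shared operator. Cross-dataset Gaussian kernels share one
$\gamma$, computed from the concatenated rows when unspecified.

# Null models

Correlating a gradient with another cortical map invites inflated test
statistics because both are spatially smooth. Two
autocorrelation-preserving null models are provided; in both cases the
recommendation is to randomize the non-gradient map.

**Spin permutations.** For data on a sphere (e.g., a spherical surface
registration), the sphere is rotated by a Haar-uniform rotation and data
are reassigned by nearest neighbor (`V_r = VR`). Rotations are sampled by
the quaternion method (four standard normals, normalized), which is exactly
uniform over SO(3). Surrogate values are therefore always a re-indexing of
the observed values, and the identity rotation is a fixed point. The
resampling indices depend only on the sphere and the rotations —
`spin_indices()` exposes them so one ensemble can serve many maps. Masked
vertices (e.g., medial wall) propagate their masked status into surrogates;
how masked vertices should interact with nearest-neighbor reassignment has
no established convention, and this source-propagation rule is documented
as the package's choice. Data spanning two hemispheres should be spun per
hemisphere sphere; mirrored-rotation schemes for contralateral hemispheres
exist in the literature but are not implemented here.

**Moran spectral randomization.** For data on an arbitrary mesh, the
spatial weight matrix (inverse distance over the 1-ring neighborhood, or
binary; Gaussian weighting and larger neighborhoods are not implemented in
this version) is doubly centered and eigendecomposed into Moran eigenvector
maps $M$; zero-eigenvalue vectors are dropped. With $r$ the correlations of
the map $u$ with the columns of $M$, surrogates are
$z = \bar{u} + \sigma_u \sqrt{l-1}\, M a^T$. The coefficient vector $a$
must have one entry per eigenvector for the dimensions to work, so the
randomized object is $r$ itself: the `singleton` procedure flips each sign
($a_i = \pm r_i$), the `pair` procedure rotates randomly chosen disjoint
pairs through $\phi \sim \mathcal{U}(0, 2\pi)$
($a_i = q\cos\phi,\ a_j = q\sin\phi$, $q = \sqrt{r_i^2 + r_j^2}$; an odd
leftover element falls back to singleton). This normalization is pinned by
an exact identity: drawing all singleton signs positive reproduces $u$ to
machine precision, which the tests assert. Because Moran's I of a surrogate
is $\sum_i \lambda_i a_i^2 / \sum_i a_i^2$ in the basis coordinates,
singleton draws preserve mean, standard deviation, *and* Moran's I exactly.
Pair draws preserve mean and standard deviation exactly but only part of
the autocorrelation: rotating a random pair moves energy between
eigenvalue bands, so in expectation the surrogate Moran's I shrinks roughly
halfway toward the (near-zero) spectrum mean. The singleton procedure is
therefore preferred unless more than $2^{l-1}$ unique randomizations are
required — that capacity bound is enforced.

**Inference.** `morans_i()` implements the classical ratio-of-quadratic
forms statistic over unmasked vertices, and `empirical_pvalue()` uses the
$(1+k)/(1+n_{\mathrm{perm}})$ estimator (ties count as extreme, so $p = 0$
is impossible); two-tailed values are $2\min(p_L, p_R)$ capped at 1, a
convention consistent with reporting thresholds like $p < 0.001$ at 1000
permutations.

# The synthetic-data generators

All generators are pure functions of their parameters and seed, so every
test input is reproducible from code.

* `planted_gradient_connectome()` draws latent coordinates
  $\theta_i \sim \mathcal{U}[0,1]^d$ and sets
  $X_{ij} = e^{-|\theta_i-\theta_j|/\tau}$ plus symmetric Gaussian noise,
  unit diagonal. The exponential latent kernel (rather than Gaussian) has
  heavier tails, which yields a single cleanly dominant gradient — the
  recovery target. Defaults ($n = 100$, $\tau = 0.2$, noise sd 0.05)
  emulate a parcellated connectivity matrix with a strong principal axis.
* `make_icosphere()` builds subdivided icosahedra ($10 \cdot 4^s + 2$
  vertices), the standard stand-in for spherical registrations.
* `smooth_field()` smooths white noise by iterated 1-ring averaging and
  restandardizes; `n_smooth` tunes spatial autocorrelation (20 sweeps on a
  642-vertex sphere give Moran's I above 0.5 in almost all draws).
* `two_group_gradients()` produces a multi-subject cohort sharing one
  planted connectome plus subject noise, with an optional latent-range
  contraction in group 2 for alignment-and-compare demonstrations.

What these fixtures do *not* emulate: negative correlations, hub structure,
hemispheric asymmetry, subject-specific topography, or measurement
artifacts of real neuroimaging data. Tests passing on them validate the
algebra and the statistical calibration of the methods, not their
neuroscientific interpretation on any particular dataset.

# Problem sizes and experiment settings

The package's own experiments (test suite and `scripts/acceptance.R`) use:
kernel oracles on $6 \times 5$ matrices; closed-form graphs with 3–32
nodes; planted-manifold recovery at $n = 100$ over 20 seeds (with
`keep_fraction = 0.25`, see above); spin and MSR checks on 162- and
642-vertex icospheres; spin-test calibration with 199 rotations and 200
repetitions of independent smooth-field pairs, checked against the 99%
binomial band around the nominal 0.05 level. One rotation ensemble is
shared across calibration repetitions — the indices are data-independent,
so conditional on them the repetitions remain independent.

# Known limitations

* Dense eigensolvers bound practical problem sizes to a few thousand seeds.
* The pair MSR procedure's partial autocorrelation preservation (above) is
  intrinsic to random pairing; pairing within near-degenerate eigenvalue
  bands would preserve more but is not what the procedure specifies.
* No out-of-sample extension (Nyström) for embedding new seeds into an
  existing gradient space.
* File support covers delimited text, MatrixMarket, ASCII PLY and
  ASCII-encoded GIFTI; binary PLY/GIFTI, FreeSurfer binary surfaces, CIFTI
  and volumetric NIfTI are out of scope.
* No surface visualization; gradients are returned as matrices for the
  user's plotting tool of choice.
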