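---
title: "Intuitionistic kernel-spatial fuzzy C-means: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intuitionistic kernel-spatial fuzzy C-means: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ikfcm)
```

# The segmentation model

Brain MR tissue segmentation is treated as one-dimensional fuzzy
clustering of voxel intensities.  Classical fuzzy C-means (FCM) minimizes

$$E(B, A) \;=\; \sum_{x=1}^{f}\sum_{y=1}^{n} b_{xy}^{\,l}\,
  (m_y - a_x)^2,\qquad \sum_x b_{xy} = 1,\; b_{xy}\ge 0,$$

by alternating the closed-form center update
$a_x = \sum_y b_{xy}^l m_y / \sum_y b_{xy}^l$ and membership update
$b_{xy} = \bigl[\sum_g (r_{xy}/r_{gy})^{2/(l-1)}\bigr]^{-1}$, where
$r_{xy} = |m_y - a_x|$.  A voxel coinciding with one or more centers is a
*singular point*: its membership is split equally over the coinciding
centers and is zero elsewhere.  `fit_fcm()` implements exactly this
scheme; `defuzzify()` converts memberships to crisp labels by maximum
membership.

The improved algorithm, `fit_ikfcm()`, runs the following pipeline:

1. **Normalization and intuitionistic fuzzification.**  In-mask gray
   levels are min-max normalized to $b_0\in[0,1]$ and passed through the
   quadratic (Yager-type) generator: membership $b = b_0^2$,
   non-membership $a = (1-b_0)^2$, hesitation $\pi = 2 b_0 (1-b_0)$.  The
   triplet sums to one identically; $\pi$ peaks (0.5) at mid-gray, where
   a voxel's brightness is most ambiguous, and vanishes at the extremes.
   The *membership image* $b$ becomes the working intensity for
   clustering; $\pi$ is kept per voxel for step 4.  The defuzzification
   inverse, $m = m_{\min} + \sqrt{b}\,(m_{\max}-m_{\min})$, maps working
   values (including fitted centers) back to the original gray scale.

   The non-membership generator is the unique quadratic choice consistent
   with the hesitation $\pi = 2b_0(1-b_0)$ under the constraint
   $b + a + \pi = 1$; the one-sided form $1 - b_0^2$ would force
   $\pi = 0$ and is not a valid intuitionistic complement here.

2. **Local spatial information.**  `neighborhood_mean()` computes, for
   every voxel, the mean of its $(2p+1)^d$ box neighborhood *excluding*
   the central voxel, with mirror reflection at image borders.  Averaging
   is mask-aware: out-of-mask neighbors are dropped, and a voxel with no
   in-mask neighbor falls back to its own intensity.  The exclusion of
   the center keeps the regularizer a pure neighborhood prior — the
   voxel's own value already carries full weight in the data term.

3. **Kernel-spatial updates.**  Distances are measured after the implicit
   feature map of a Gaussian kernel,
   $d_K(u, v) = \lVert\varphi(u)-\varphi(v)\rVert^2 = 2(1 - e^{-(u-v)^2/\delta^2})$,
   which is bounded by 2, so an outlying intensity saturates rather than
   dominating the objective.  The center update augments each voxel with
   its neighborhood mean,
   $a_x = \sum_y b_{xy}^l (m_y + \theta\bar m_y) \big/ (1+\theta)\sum_y b_{xy}^l$,
   and the membership update scores each voxel–cluster pair with
   $D_{xy} = d_K(m_y, a_x) + \theta\, d_K(\bar m_y, a_x)$,
   normalizing $D_{xy}^{-1/(l-1)}$ over clusters.  The center update is
   deliberately the plain spatially weighted mean (the
   `kernel_weighted_centers` option enables the fully kernelized
   fixed-point variant, default off): keeping the center update linear
   makes $\theta = 0$ reduce *exactly* to classical FCM and keeps centers
   interpretable as working-intensity means.

4. **Hesitation correction.**  With winner $e = \arg\max_x b_{xy}$, the
   non-winning memberships shrink to $\pi_y b_{xy}$ and the winner
   absorbs the freed mass, $b_{ey} = 1 - \pi_y \sum_{x\ne e} b_{xy}$.
   Column sums remain exactly one, the winner never loses mass, and the
   argmax is preserved, so the correction sharpens the partition without
   changing any crisp decision — it changes the *fuzziness profile*:
   unambiguous voxels ($\pi \approx 0$) become crisp, ambiguous mid-gray
   voxels ($\pi \approx 0.5$) stay soft.  The hesitation degrees are
   those of the fuzzification step and are held fixed across iterations;
   no principled per-iteration update of $\pi$ exists for this generator,
   and re-deriving $\pi$ from evolving memberships would let the
   correction feed back on itself.  The `hesitation` option selects
   whether the correction runs every iteration (default), once after
   convergence, or not at all; the last exposes the bare kernel-spatial
   scheme, which is the configuration that reduces to classical FCM.

5. **Termination and defuzzification.**  Iteration stops when the maximum
   absolute membership change falls below `tol` or after `max_iter`
   iterations.  Centers are reported sorted ascending, so label $k$ is
   always the $k$-th darkest tissue and label maps are comparable across
   runs; crisp labels are 1..f inside the mask and 0 outside.

# Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `clusters` (f) | — | – | number of tissue classes |
| `fuzzifier` (l) | 2 | – | membership softness; 2 is the field-standard choice, l→1 approaches k-means |
| `theta` (θ) | 0.25 | – | weight of the neighborhood term in both updates |
| `delta` (δ) | 0.2 | working intensity (range [0,1]) | Gaussian kernel width |
| `radius` (p) | 1 | voxels | neighborhood half-width: 3×3 (2-D) or 3×3×3 (3-D) box |
| `tol` (α) | 1e-4 | membership (ikfcm) / intensity (fcm) | convergence threshold |
| `max_iter` (I) | 300 | – | iteration cap |
| `seed` | — | – | initialization seed; identical seeds give bit-identical fits |

Two defaults deserve their rationale:

* **θ = 0.25.**  The spatial term trades noise immunity against boundary
  fidelity.  For structures one voxel thick (a thin cortical ribbon
  against CSF), the neighborhood mean of a boundary voxel is dragged far
  toward the adjacent tissue; if a third cluster center lies between the
  two tissues (a tumor of intermediate brightness), a weight of 0.5 or
  more lets the spatial term overrule the voxel's own intensity and
  reassign the whole boundary shell, and the captured voxels then drag
  that center off its tissue — a self-reinforcing mislabeling that
  persists from any initialization.  At 0.25 the data term keeps priority
  at two-tissue boundaries while the regularizer still suppresses
  isolated noise voxels; accuracy under heavy noise remains monotone in θ
  (tested over θ ∈ {0, 0.5}), so users segmenting very noisy, large-scale
  structures can raise θ deliberately.
* **δ = 0.2.**  After fuzzification the working intensities always span
  [0, 1], so an absolute kernel width is meaningful across images.  0.2
  sits above typical within-tissue spread and below between-tissue
  distances: locally the kernel behaves like the Euclidean metric
  (ratios of $d_K$ approach ratios of squared distances), while distances
  to remote tissues saturate, which is exactly the outlier suppression
  the kernel is for.  The data-driven alternative `delta = "auto"` (the
  standard deviation of the in-mask working intensities) is a
  between-class scale — typically ≈ 0.4 on a four-tissue brain — and
  saturates more aggressively; it is kept as an option rather than the
  default because on piecewise-constant images it can blur the
  distinction between adjacent dim classes.

`fit_fcm()` terminates on the maximum center shift instead (the natural
scale for a method whose state is its centers); both rules are the
standard alternation with tolerance `tol`.

# Initialization, determinism, tie-breaking, degenerate inputs

* Default initialization draws a uniform random membership matrix
  (column-normalized) from the given seed; the RNG state of the session
  is saved and restored, so library calls never perturb user randomness.
  `init = "quantile"` instead places centers at evenly spaced quantiles
  of the *distinct* in-mask intensity levels — identical to data
  quantiles for continuous data, but non-degenerate on
  piecewise-constant images where one plateau holds half the voxels.
* Defuzzification ties break toward the lowest cluster index; the
  Youden-cutoff ties break toward higher specificity, then the higher
  threshold.  Both make every output deterministic.
* Degenerate inputs raise classed errors rather than propagating NaNs:
  constant images (no gray range), fewer distinct intensities than
  clusters, coincident centers, membership rows that are identically
  zero, hesitation values outside [0, 1].  A voxel whose kernel-spatial
  distance is zero for several clusters is split equally among them.
* `1 - e^{-u}` is evaluated as `-expm1(-u)`: for very wide kernels
  ($u \sim 10^{-12}$) the naive form loses ~4 significant digits to
  cancellation, which is visible as spurious membership differences of
  order $10^{-2}$ in the FCM-reduction configuration.

# The phantom generator

`make_phantom()` is the synthetic stand-in for patient volumes.  Tissue
brightness follows the spin-echo signal equation
$S = \beta\,(1 - e^{-T_R/T_1})\,e^{-T_E/T_2}$ — monotone increasing in
$T_R$, decreasing in $T_E$ — with a default acquisition of
$T_R = 1980$ ms, $T_E = 2.28$ ms and 1 mm³ voxels (a short-TE
T1-weighted 3T protocol), and literature-typical 3T relaxation times
(CSF 4000/2000 ms, GM 1300/110 ms, WM 830/80 ms, tumor 1600/150 ms;
unit spin density).  Under this protocol the simulated brightness
ordering is CSF < tumor < GM < WM, with the tumor–GM contrast the
smallest — the difficult pair.  Geometry is a nested set of ellipsoids
(CSF envelope, GM ribbon, WM core) plus an off-center tumor blob inside
the WM; `region()` also paints boxes, whose voxel counts are exactly
predictable, for counting tests.  Noise models: additive Gaussian,
Rician (the true distribution of magnitude MR noise — magnitude of a
complex signal with i.i.d. Gaussian noise on both channels), and
salt-and-pepper (a fraction of in-mask voxels forced to the in-mask
extremes).  Everything is deterministic given the seed, and ground-truth
labels, the tissue table and the noise description travel with the image.

What the phantom does *not* emulate: bias fields / intensity
inhomogeneity, partial-volume mixing at tissue interfaces, realistic
cortical folding, and multi-echo acquisitions.  Tests passing on
phantoms therefore demonstrate correctness of the optimization and its
claimed invariances (normalization, reduction, noise-direction
properties) — not clinical-grade performance on real scanner data, where
inhomogeneity correction and registration (both out of scope here) come
first.

# Evaluation stack

Cluster labels are arbitrary, so `match_labels()` first permutes
predicted labels to maximize total overlap with the reference (exact
assignment by exhaustive permutation search, f ≤ 8; deterministic
first-optimum tie-break).  `binary_metrics()` then reports exact
one-vs-rest confusion counts and accuracy/sensitivity/specificity/Dice;
`label_volumes()` converts counts to mm³ with the voxel volume.
Sensitivity is NaN (with a warning) when the reference has no positive
voxel.

For grading, `compare_groups()` gates on Shapiro–Wilk normality at
α = 0.05 in each group — Welch's t-test if both pass, Wilcoxon rank-sum
otherwise (groups too small or constant go to the rank-sum branch).
`roc_curve()` builds the empirical ROC over all observed thresholds;
trapezoidal AUC then equals the Mann–Whitney $U/(n_1 n_2)$ with ties
counted one half, an identity the tests verify on every input.  The
"optimal critical value" is the Youden-J maximizer.  The cohort
simulator draws Gaussian group values per parameter; its default table
(five parameters named after diffusion-kurtosis metrics and metabolite
ratios) is synthetic, chosen to give a spread of AUCs, and is not
patient data.

# Problem sizes and runtime

The test-suite fixtures are sized for exactness, not realism: oracle
comparisons use ≤ 100-element instances (where brute-force double loops
are feasible at 1e-12 agreement), recovery and robustness checks use
64×64 slices and 48³–64³ volumes (~10⁵ in-mask voxels), and Monte-Carlo
ROC calibration uses 20 replicate cohorts of 500 subjects per group —
large enough that the empirical AUC's sampling error (≈ 0.004 for the
mean) resolves the 0.02 calibration band against the binormal closed
form $\Phi(d/\sqrt2)$.  A 64³ fit converges in a few seconds on one
core; the full suite runs in well under a minute.

# Known limitations

* Clustering is univariate (scalar gray level).  Multichannel
  (T1/T2/PD) feature vectors are not supported.
* Gray-level-histogram acceleration is not implemented; all updates are
  per-voxel (exact, and fast enough at these sizes).
* The spatial term can still erode structures whose thickness is
  comparable to the neighborhood radius when θ is raised well above the
  default; there is no adaptive, edge-stopping θ.
* `match_labels()` is exact but factorial in the number of classes
  (capped at 8).
* DICOM ingestion, registration and motion correction are out of scope;
  input is NIfTI-1 (optionally pre-masked, or masked with
  `extract_brain_mask()`'s threshold + largest-component + closing
  pipeline).
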