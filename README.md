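# ikfcm

Fuzzy C-means tissue segmentation for brain MR images, with an improved
variant that combines **intuitionistic fuzzification**, a
**Gaussian-kernel-induced distance**, **spatial neighborhood
regularization** and a **hesitation-degree correction** of the membership
matrix — plus the evaluation stack that goes with it: cluster-validity
indices, a spin-echo phantom simulator with ground truth, volumetry and
confusion-matrix metrics, and ROC/AUC statistics for two-group tumor
grading.

The package is aimed at medical-image-analysis researchers who want a
reproducible, fully scriptable implementation of spatially constrained
kernel FCM for gray-matter / white-matter / CSF / lesion segmentation of
NIfTI volumes, and at methodologists who need a controlled synthetic bench
for comparing fuzzy segmentation algorithms.

## The model

Classical FCM minimizes the weighted within-cluster scatter

$$E = \sum_{x=1}^{f}\sum_{y=1}^{n} b_{xy}^{\,l}\,\lVert m_y - a_x\rVert^2 ,
\qquad \sum_{x=1}^{f} b_{xy} = 1,$$

over memberships $b_{xy}\in[0,1]$ and centers $a_x$, where $m_y$ are voxel
intensities and $l>1$ is the fuzzifier.  The improved algorithm makes four
changes:

1. **Intuitionistic fuzzification.**  Gray levels are min-max normalized to
   $b_0$ and mapped to the triplet membership $b=b_0^2$, non-membership
   $a=(1-b_0)^2$, hesitation $\pi = 2b_0(1-b_0)$ (so $b+a+\pi \equiv 1$).
   Clustering runs on $b$; $\pi$ quantifies per-voxel brightness ambiguity.
2. **Kernel-induced distance.**  Squared distances are replaced by
   $d_K(u,v) = 2\bigl(1 - e^{-(u-v)^2/\delta^2}\bigr)$, the feature-space
   distance of a Gaussian kernel.  Distances saturate at 2, so outlying
   intensities cannot dominate the objective.
3. **Spatial regularization.**  Each voxel's neighborhood mean
   $\bar m_y$ (mask-aware, center excluded) enters both updates:
   centers $a_x = \sum_y b_{xy}^l (m_y + \theta \bar m_y) /
   \bigl[(1+\theta)\sum_y b_{xy}^l\bigr]$ and memberships
   $b_{xy} \propto \bigl[d_K(m_y,a_x) + \theta\, d_K(\bar m_y,a_x)\bigr]^{-1/(l-1)}$.
4. **Hesitation correction.**  Each iteration, the winning membership of
   voxel $y$ absorbs $(1-\pi_y)$ of the competitors' mass:
   non-winners scale to $\pi_y b_{xy}$, the winner becomes
   $1-\pi_y\sum_{x\neq e} b_{xy}$.  Columns still sum to one and the
   argmax is preserved; ambiguous voxels stay fuzzy, unambiguous ones
   become crisp.

Partitions are compared with the partition coefficient
$V_{pc} = \tfrac1n\sum b_{xy}^2$, partition entropy
$V_{pe} = -\tfrac1n\sum b_{xy}\ln b_{xy}$, and the Xie–Beni index
(compactness over separation).  The grading module provides the
Shapiro-gated t / rank-sum comparison, the empirical ROC with trapezoidal
AUC, and the Youden-optimal critical value.

## Worked example

Simulate a 64³ four-tissue spin-echo phantom (TR 1980 ms, TE 2.28 ms,
1 mm³ voxels) with mild Gaussian noise and segment it:

```r
library(ikfcm)
ph  <- make_phantom(shape = c(64, 64, 64), sigma = 0.0067, seed = 42)
fit <- fit_ikfcm(ph$image, clusters = 4, seed = 1)
fit
#> <ikfcm fit> 4 clusters, 100024 voxels, 15 iterations (converged)
#>   centers: 0.007772 0.404148 0.539496 0.897182
validity_report(fit)
#> <validity_report> n = 100024, f = 4
#>   Vpc = 0.966691  Vpe = 0.0826997  Vxb = 0.0148245
segmentation_accuracy(fit$labels, ph$labels)
#> [1] 1
label_volumes(match_labels(fit$labels, ph$labels), ph$image$voxel_size)
#>   label count volume_mm3
#> 1     1 48584      48584   # CSF
#> 2     2 32037      32037   # gray matter
#> 3     3 18602      18602   # white matter
#> 4     4   801        801   # tumor
```

The four centers are the tissues' working intensities (fuzzified gray
levels, darkest to brightest: CSF, tumor, GM, WM — `fit$centers_intensity`
maps them back to the original gray scale).  `Vpc` near 1 and `Vpe` near 0
say the partition is nearly crisp; every in-mask voxel matches the ground
truth, and the volumetry converts exact voxel counts to mm³.

Grading statistics on a simulated two-group cohort:

```r
grading_report(simulate_grading_cohort(n_per_group = 40, seed = 7))
#>   parameter   auc critical_value sensitivity specificity  p_value method
#> 1        MK 0.985          0.776       0.975       0.950 6.02e-20      t
#> 2        AK 0.793          0.843       0.500       0.950 1.61e-06      t
#> ...
```

Each row is one biomarker: its AUC for separating high- from low-grade
subjects, the Youden-optimal critical value with its sensitivity and
specificity, and the p-value of the (normality-gated) two-group test.

## Command line

```sh
inst/cli/ikfcm phantom  --out ph --shape 64,64,64 --sigma 0.02 --seed 7
inst/cli/ikfcm segment  --input ph_image.nii.gz --mask ph_labels.nii.gz \
                        --algorithm ikfcm --clusters 4 --seed 1 --out seg
inst/cli/ikfcm evaluate --pred seg_labels.nii.gz --truth ph_labels.nii.gz --out eval.json
inst/cli/ikfcm roc      --input cohort.csv --out grading.csv
```

Exit codes: 0 success, 1 usage, 2 data/format, 3 numerical failure.  Every
run report records the full parameter set and seed, so results reproduce
bit-exactly.

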