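---
title: "Fuzzy C-means segmentation of intracranial hemorrhage on brain CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy C-means segmentation of intracranial hemorrhage on brain CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyct)
```

## The problem

Acute intracranial hemorrhage (ICH) is hyperdense on non-contrast head CT:
blood attenuates more than brain parenchyma and less than bone, so on the
Hounsfield scale the tissue ordering is
CSF < white matter < gray matter < blood < skull. That ordering makes
intensity clustering a natural segmentation strategy, and fuzzy C-means
(FCM) the classical soft-clustering tool for it: each pixel receives a
membership in every tissue class rather than a hard label, which copes with
partial-volume mixing at tissue interfaces.

Plain FCM, however, ignores where a pixel sits: an impulse-noise pixel in
the middle of white matter is assigned purely by its gray value, producing
the isolated misclassified "pseudo-spots" familiar from noisy CT. This
package implements both the standard FCM baseline and an improved variant
that folds three ideas into the update equations -- intuitionistic
fuzzification of the gray scale, a kernel-induced distance, and a spatial
neighborhood constraint -- plus a hesitation-degree correction of the
membership matrix, and wires the result into a complete hemorrhage
quantification pipeline (windowing, skull stripping, clustering, region
growing, volumetry) exercised entirely on synthetic phantoms.

## Standard FCM

For samples $m_1,\dots,m_n$ (gray values), $f$ cluster centers $a_x$ and a
fuzzifier $l > 1$, FCM minimizes

$$E(B, A) = \sum_{x=1}^{f}\sum_{y=1}^{n} b_{xy}^{\,l}\,\lVert m_y - a_x\rVert^2,
\qquad \sum_x b_{xy} = 1,$$

by alternating the center update
$a_x = \sum_y b_{xy}^l m_y / \sum_y b_{xy}^l$ and the membership update
$b_{xy} = \big[\sum_g (r_{xy}/r_{gy})^{2/(l-1)}\big]^{-1}$ with
$r_{xy} = \lVert m_y - a_x \rVert$. A sample that coincides exactly with one
or more centers gets its membership split evenly over the coinciding
centers and zero elsewhere, so zero distances never enter a division.
`fcm()` starts from a seeded random column-stochastic membership matrix
(uniform Dirichlet per column, centers updated first) and stops when the
maximum center shift falls below `tol` or `max_iter` is reached. The
objective is non-increasing along the iterations, which the test suite
checks on dozens of random instances. Labels come from the maximum
membership, ties to the lowest cluster index; for one-dimensional features
the centers are reported in ascending order so that cluster 1 is always the
darkest tissue.

## The improved algorithm

`ifcm()` works on a normalized image $b \in [0,1]$ re-expressed as an
intuitionistic fuzzy set: membership $\mu = b^2$, non-membership
$\nu = (1-b)^2$ and hesitation $\pi = 2b(1-b)$, which partition unity
exactly. The hesitation degree is largest at mid-gray, where a pixel's
brightness class is most ambiguous. Clustering operates on the fuzzified
intensity $\mu$; three modifications enter the updates:

* **Kernel-induced distance.** Dissimilarities are measured as
  $\lVert\phi(x)-\phi(a)\rVert^2 = 2(1 - K(x,a))$ with a Gaussian kernel
  $K(x,a)=\exp(-(x-a)^2/\sigma^2)$. The distance saturates at 2 for
  far-apart values, which caps the influence of outlying intensities. The
  kernel family is not dictated by the method's description; the Gaussian
  RBF is the standard choice in kernelized FCM and is the one that yields
  this closed form. The bandwidth defaults to the standard deviation of the
  fuzzified intensities.
* **Spatial constraint.** Each pixel is coupled to its neighborhood context
  $\bar m_y$ (the median, by default, over the $(2p+1)\times(2p+1)$ window,
  mirror-padded at borders): the center update becomes
  $a_x = \sum_y b_{xy}^l (m_y + \theta \bar m_y) / [(1+\theta)\sum_y b_{xy}^l]$
  and the membership update uses
  $D_{xy} = \lVert\phi(m_y)-\phi(a_x)\rVert^2 + \theta\,\lVert\phi(\bar m_y)-\phi(a_x)\rVert^2$,
  normalized as $b_{xy} = [\sum_g (D_{xy}/D_{gy})^{1/(l-1)}]^{-1}$.
* **Hesitation correction.** After each membership update the winning
  membership of each pixel absorbs mass from the others, scaled by the
  pixel's hesitation: losers $b_{xy} \leftarrow \pi_y b_{xy}$, winner
  $b_{ey} \leftarrow 1 - \pi_y \sum_{x\neq e} b_{xy}$. This conserves the
  column sum, never demotes the winner, is the identity at $\pi = 1$ and
  yields a crisp assignment at $\pi = 0$.

Iteration stops when the maximum absolute membership change falls below
`tol`. Deblurring substitutes the memberships of each gray level back into
the image and labels every pixel by maximum membership, clusters ordered by
ascending center.

### Clustering domain: gray levels or pixels

Following the method's own formulation, the membership matrix is extended
to the *gray level* by default: the image is quantized to at most `levels`
gray levels, each level is one weighted sample (weight = pixel count), and
a level's context is the mean context of its pixels. This is orders of
magnitude faster than per-pixel clustering and exact on clean images. The
`mode = "pixel"` variant clusters every pixel with its own neighborhood
context; it is the configuration that actually rescues isolated
impulse-noise pixels, because two pixels with the same gray value but
different surroundings can then be labeled differently. The noise-robustness
comparison in the acceptance suite uses pixel mode for exactly that reason.

### Initialization

`ifcm()` does **not** use random initialization. With a random
column-stochastic membership matrix every initial center lands at the
global weighted mean of the samples -- a symmetric fixed point of the
updates. Euclidean FCM escapes it quickly (tiny asymmetries amplify fast),
but the saturating kernel updates amplify them so slowly that the
membership-change stopping rule can fire while the centers are still
degenerate. We observed exactly that: all centers collapsed onto one value
on realistic phantoms. The method's own description derives the initial
membership matrix from the intuitionistic fuzzification of the gray levels,
i.e. from the data; accordingly `ifcm()` initializes centers at evenly
spaced quantiles of the distinct fuzzified gray values. This is
deterministic, so repeated fits are bit-identical; `fcm()` keeps the
classical seeded random start.

### Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `fuzzifier` (l) | 2 | partition softness; 2 is the standard choice and the experimental setting of the method |
| `tol` (alpha) | 1e-4 | stopping threshold, per the experimental setting |
| `radius` (p) | 2 | 5 x 5 neighborhood window, per the experimental setting |
| `theta` | 3.8 | spatial constraint weight. Must exceed 1 for the neighborhood term to outweigh an impulse pixel's exact intensity match to a wrong center (the kernel distance of such a pixel to the wrong center is 0, while its context contributes at most 2 theta); 3.8 is the weight established in the spatially-constrained FCM literature |
| `sigma` | sd of fuzzified intensities | Gaussian kernel bandwidth, on the scale of the data |
| `context_mode` | median | the median context preserves edges; the mean context blends across region boundaries and measurably displaces the centers of thin structures |
| `levels` | 256 | gray-level quantization of the default clustering domain |

## The phantom generator

`generate_slice()` builds a 2-D head phantom: an elliptical skull ring
enclosing a gray-matter cortex and a white-matter interior, CSF as two
paramedian ventricle ellipses, and an optional hemorrhage (ellipse or
seeded irregular blob emulating the unclear, incomplete bleeding edges seen
on real CT). Tissue means default to standard radiology values (air -1000,
CSF 8, white 28, gray 38, blood 65, bone 600 HU), which respect the
diagnostic intensity ordering; truth labels are exact and noise (additive
Gaussian, salt-and-pepper) perturbs only the HU image.
`generate_volume()` stacks slices with an ellipsoidal through-slice lesion
profile sized to a target volume in mL, at a default spacing of
1 x 1 x 6 mm (6 mm is a routine head-CT slice thickness).

CSF is deliberately modeled as ventricles rather than as a thin
subarachnoid rim: at the phantom sizes used for testing a concentric rim
would be ~3 px wide, thinner than the 5 x 5 spatial window, so any
spatially regularized method would destroy the class *by construction* --
which is a property of such a caricature geometry, not of real anatomy,
where the dominant CSF space visible at this resolution is ventricular.

What the phantom does **not** emulate: partial-volume gradients at tissue
interfaces, beam hardening and streak artifacts, anatomical variability,
hemorrhage heterogeneity (fluid levels, perilesional edema), and
non-axial geometry. Passing the phantom tests therefore demonstrates the
algorithmic properties (exact recovery, noise robustness, volumetric
bookkeeping), not clinical-grade performance on patient data.

## The pipeline

`quantify_hemorrhage()` chains the full workflow: brain-window each slice
(level 40, width 120 HU), strip the skull (largest connected bone
component above 300 HU, filled, eroded by 1 px, bone excluded), cluster the
whole stack in **one** pooled fit -- a single consistent center set means
the hemorrhage cluster exists volume-wide and is simply absent from
lesion-free slices -- then select the brightest cluster lying at least 50%
inside the intracranial mask, grow its connected components (8-connectivity)
dropping speckle below `min_area_px` (default 10 px), and convert the voxel
count to milliliters. A skull-stripped volume contains one intensity class
fewer, so the default cluster count drops from 6 to 5 there.

## Numerical choices and degenerate inputs

* Ties in defuzzification go to the lowest cluster index (deterministic).
* Exact center coincidence routes through the crisp-split rule, never an
  epsilon.
* Borders are mirror-padded for the neighborhood context and the
  Laplacian-of-Gaussian filter; the LoG response is flushed to zero below
  float-noise level so constant regions produce no spurious zero-crossings.
* The LoG edge detector places each zero-crossing on the pixel with the
  smaller absolute response and scores it by local gradient magnitude;
  the default strength threshold is Otsu's threshold over the observed
  strengths. Scale, bone threshold and strength threshold are exposed, as
  the method's description quantifies none of them.
* Probability-style hemorrhage maps are thresholded strictly above 0.5.
* Two empty masks have Dice 1 (a correct no-lesion prediction is not an
  error); the relative volume error of a zero-truth case is undefined and
  reported as `NA`. Relative errors are reported as fractions.
* A constant image has no gray range and is rejected by `normalize_gray()`
  rather than silently producing NaNs.
* Validity indices use the standard definitions (Bezdek's partition
  coefficient and entropy with natural log, the Xie-Beni ratio), since the
  method names them without printing formulas.

## Problem sizes in the test and acceptance suites

The suites run on 128 px phantoms (256 px for the noiseless recovery
checks, where center accuracy is compared at the single-gray-level scale
and boundary-pixel contamination shrinks with size), cohorts of 10 slices,
and 10 seeded replicates for the noise-robustness comparison. These sizes
were chosen so that every documented property is exercised at full
strength -- each phantom structure spans many multiples of the spatial
window -- while the whole suite stays fast enough to run routinely.

## Known limitations

* The spatial term biases centers of structures whose width approaches the
  neighborhood window; the median context mitigates but does not remove
  this.
* Gray-level mode cannot distinguish two pixels with identical gray value
  but different surroundings; use pixel mode when impulse noise matters.
* The improved update equations are not the gradient flow of a single
  objective (the hesitation correction is applied outside the variational
  derivation), so no monotone objective trace exists for `ifcm()`; the
  membership-change criterion is the stopping rule.
* Cluster-count selection is the user's responsibility; the pipeline
  defaults (5 stripped / 6 unstripped) assume the standard head-CT tissue
  inventory.
* DICOM support covers explicit-VR little-endian single-frame CT series --
  the common export format -- not compressed transfer syntaxes.
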