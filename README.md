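# fuzzyct

Fuzzy C-means segmentation and volume quantification of intracranial
hemorrhage (ICH) on non-contrast brain CT.

Acute blood is hyperdense on head CT — brighter than brain parenchyma,
darker than bone — so hemorrhage can be segmented by soft intensity
clustering. This package is for image-analysis researchers and
methods developers who need a complete, reproducible reference
implementation of that idea: the classical fuzzy C-means (FCM) baseline, an
improved FCM that adds intuitionistic fuzzification, a kernel-induced
distance and a spatial neighborhood constraint, and everything around them
(CT I/O and Hounsfield windowing, skull stripping, region-growing lesion
extraction, volumetry, evaluation metrics, label-synchronized augmentation,
and a synthetic brain-phantom generator so every result is reproducible
without patient data).

## The model

Standard FCM minimizes

    E(B, A) = sum_x sum_y  b_xy^l  || m_y − a_x ||²,    sum_x b_xy = 1,

alternating the weighted-mean center update with the inverse-distance
membership update `b_xy = [ sum_g (r_xy / r_gy)^(2/(l−1)) ]^(−1)`.

The improved algorithm (`ifcm()`) re-expresses the normalized image as an
intuitionistic fuzzy set — membership μ = b², non-membership ν = (1−b)²,
hesitation π = 2b(1−b), with μ + ν + π = 1 — and clusters the fuzzified
intensity with three changes:

* distances are kernel-induced, `‖φ(x) − φ(a)‖² = 2(1 − exp(−(x−a)²/σ²))`;
* every sample is coupled to its neighborhood context m̄ with weight θ,
  in both the center update `a_x = Σ b^l (m + θ m̄) / [(1+θ) Σ b^l]` and
  the dissimilarity `D = ‖φ(m)−φ(a)‖² + θ‖φ(m̄)−φ(a)‖²`;
* after each sweep the hesitation degree sharpens each pixel's column:
  non-winning memberships are scaled by π and the winner absorbs the
  difference.

Iteration stops on the maximum membership change; defuzzification assigns
each gray level (or pixel) to its maximum-membership cluster, clusters
ordered darkest to brightest. See the methods vignette
(`vignettes/fuzzy-cmeans-ct.Rmd`) for parameter defaults and the design
rationale.

## Worked example

Segment a noisy synthetic phantom slice and quantify a phantom hemorrhage
volume:

```r
library(fuzzyct)

sl  <- generate_slice(phantom_spec(size = 128, lesion = list(area_px = 400),
                                   gaussian_sd = 3, seed = 7))
g   <- apply_window(sl$hu, "brain")     # HU -> [0,1], level 40 / width 120
fit <- ifcm(g, clusters = 6, seed = 1)
summary(fit)
#> Improved fuzzy C-means summary
#>   centers: 2.318e-06, 0.05961, 0.1636, 0.2337, 0.4945, 1
#>   sizes:   6156, 455, 3501, 3769, 395, 2108
#>   Vpc: 0.97877  Vpe: 0.054517  Vxb: 0.060665
#>   iterations: 4 (converged)

round(dice_per_class(fitted(fit), sl$labels + 1L), 4)
#>      1      2      3      4      5      6
#> 1.0000 0.9989 0.9495 0.9531 1.0000 1.0000
```

The six centers sit on the fuzzified tissue intensities (air, CSF, white,
gray, hemorrhage, bone, darkest first); `sizes` are pixels per cluster, and
Vpc near 1 / Vpe near 0 say the partition is nearly crisp. The per-class
Dice row compares the label map against the phantom's ground truth —
hemorrhage (class 5) is recovered exactly despite 3 HU of Gaussian noise.

```r
ph <- generate_volume(phantom_spec(size = 128, gaussian_sd = 3, seed = 11),
                      n_slices = 10, target_ml = 15)
q  <- quantify_hemorrhage(ph$volume, seed = 1)   # window, strip, cluster, grow
lesion_report(q$mask, ph$volume$spacing, case = "phantom11")
#>        case slices voxels volume_ml stratum
#> 1 phantom11      5   2494    14.964 5-25 mL
```

The pipeline recovers the rasterized truth volume (14.97 mL) to within
0.1%.

A thin command-line wrapper ships in `inst/scripts/fuzzyct`
(`fuzzyct segment|lesion|evaluate|phantom|convert ...`).

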