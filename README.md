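# depthseg: depth-guided crop segmentation

`depthseg` generates crop segmentation masks from single-channel depth maps,
such as the output of monocular depth estimation models applied to top-down
plant imagery. Under top-down imaging, crop canopies sit on a raised depth
plane above the ground, so a depth map separates crops from soil far more
cleanly than raw RGB does. The package is aimed at plant-phenotyping
pipelines that want pixel-level crop masks without pixel-level manual
annotation: depth thresholding provides pseudo labels, a trimap-based
two-stage self-training loop distills them, and depth-guided edge-preserving
filters clean up predicted masks.

## What it implements

**Pseudo-mask generation** from a depth map `D` (intensities 0–255), by
three histogram thresholding strategies with the convention that crop is the
high-depth class (`M = 1` iff `D > T*`):

- **Otsu**: `T* = argmax_T w0(T) w1(T) (u0(T) − u1(T))²`, the classic
  between-class variance criterion over the 256-bin intensity histogram.
- **GHT** (generalized histogram thresholding): a Bayesian split objective
  `argmax_T f⁽⁰⁾(T) + f⁽¹⁾(T)` whose per-side Gaussian log-likelihoods are
  regularized by conjugate priors with hyper-parameters (ν, τ, κ, ω); the
  family interpolates between Otsu, minimum-error, and weighted percentile
  thresholding.
- **Gradient-guided histogram thresholding** (the package's centerpiece),
  built for scenes whose background depth drops off across the frame (a
  common artifact of oblique shooting angles and depth-model bias, which
  breaks both methods above):
  1. row/column depth normalization `Dn(i,j) = D(i,j) − min D(i,:)`, then
     subtract column minima of the intermediate — removes any separable
     background bias `f(i) + g(j)` exactly;
  2. Sobel gradient map `G` and Canny edge map `E` of `Dn`;
  3. a coarse target region `Mt` from dilating `E` and filling contours;
  4. gradient-level weights `γ_k = Σ_{l=k} e / Σ e` over `p` levels, the
     edge-weighted histogram `R_T = Σ_{Dn=T} γ_l e` and its rescaled
     cumulative sequence `S_T` (with `S_255 = 255`);
  5. a bounded sigmoid fit `255 / (1 + exp(−a(T − b)))` to `S`; the
     threshold is the slope maximum `T* = round(b)`, applied to the
     S-transformed depth inside `Mt`.

**Two-stage self-training** (over any backend honoring the
`SegmentationBackend` contract; a logistic per-pixel toy backend ships with
the package): stage one trains on pseudo masks; pixels where the stage-one
prediction disagrees with its own training label become `ignore` (128) in an
XOR trimap `M_c`; stage two retrains from the stage-one weights on the
confident pixels only.

**Mask refinement** with a guided filter or joint bilateral filter using the
depth map (or RGB luma) as guidance, then re-binarization at 0.5.

**Evaluation** by pooled mIoU: per class, intersections and unions are
summed across all images before dividing, then averaged over the two
classes — plus canopy-coverage statistics.

**Synthetic scenes**: a seeded generator of depth/mask/RGB triples with
plateau-profile crop blobs, separable background bias and Gaussian noise, so
the whole pipeline is testable with no external data.

## Worked example

A biased in-field scene where plain Otsu fails and the gradient-guided
method recovers the crops:

```r
library(depthseg)

spec <- sceneSpec(background = 5, rowBias = 1.0, colBias = 0.3,
                  blobHeight = 60, seed = 11)
sc <- generateScene(spec)
sc$coverage
#> [1] 0.1888428

resO <- generatePseudoMask(sc$depth, "otsu")
resG <- generatePseudoMask(sc$depth, "ggt")
c(otsu = resO$threshold, ggt = resG$threshold)
#> otsu  ggt
#>   93   38

miou(list(resO$mask), list(sc$mask))
#> EvalReport over 1 mask pair(s)
#>   IoU background: 0.5001
#>   IoU crop:       0.2948
#>   mIoU:           0.3974 (39.74)

miou(list(resG$mask), list(sc$mask))
#> EvalReport over 1 mask pair(s)
#>   IoU background: 0.9998
#>   IoU crop:       0.9990
#>   mIoU:           0.9994 (99.94)
```

The background drop-off here spans about 165 intensity units while the crops
rise only 60 above their local ground, so Otsu's single global threshold
(93) labels the far half of the field as crop (mIoU 0.40). Normalization
flattens the ramp, edges isolate the crop boundaries, and the sigmoid
midpoint of the edge-weighted cumulative histogram lands at 38 on the
transformed map, recovering the blobs almost exactly (mIoU 0.999).

A command-line wrapper for batch runs ships in `inst/scripts/depthseg.R`
with subcommands `simulate`, `pseudolabel`, `filter`, `selftrain`,
`evaluate`.

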