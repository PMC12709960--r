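---
title: "Depth-guided crop segmentation: methods and design notes"
author: "depthseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-guided crop segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthseg)
```

## The problem and its assumptions

Pixel-accurate crop masks are the supervision bottleneck of plant
phenotyping: hand-labeling a single field image takes tens of minutes.
Monocular depth estimation offers a shortcut. Under the top-down or
near-top-down views standard in phenotyping, crop canopies occupy a depth
plane distinctly above the ground, so in the depth map — a single-channel
image whose intensity encodes relative depth — crops read brighter than
soil, and the canopy boundary carries a strong depth gradient. `depthseg`
turns that structure into segmentation masks.

Two assumptions matter. First, a depth plane must actually separate crops
from background; scenes without it (dense closed canopies, strongly
three-dimensional backgrounds) are outside the method's reach, and
downstream screening of overlays (`blendOverlay`) exists precisely to
discard such frames. Second, depth is *relative*: monocular models provide
no metric calibration, so every algorithm here operates on per-image 8-bit
intensities, and floating-point depth input is min–max rescaled to [0, 255]
per image.

## Thresholding models

### Otsu and the GHT family

`otsuThreshold` maximizes the between-class variance
$\sigma_B^2(T) = w_0(T)\,w_1(T)\,(u_0(T)-u_1(T))^2$ over all 256 splits of
the intensity histogram, where $w_c$ are class probabilities and $u_c$
class means for the split $\{\le T\}$ vs $\{> T\}$.

`ghtThreshold` implements the generalized histogram thresholding objective:
each side of a candidate split is scored by a Gaussian log-likelihood whose
variance estimate is shrunk toward $\tau^2$ by a conjugate
inverse-chi-squared prior of strength $\nu$, plus a Beta($\kappa$, $\omega$)
prior on the mixture weight. The shipped defaults
($\nu=\tau=\kappa=0$, $\omega=0.5$) follow the reference implementation of
the method and correspond to the minimum-error-thresholding corner of the
family. The Otsu corner is reached as $\nu \to \infty$ with $\tau \to 0$
(jointly, so that $\nu\tau^2$ still dominates the within-class scatter) and
$\kappa = 0$; the test suite exercises this correspondence numerically with
$\nu = 10^{18}$, $\tau = 10^{-2}$.

Both searches break ties toward the smallest maximizing threshold so runs
are bit-reproducible, and both reject histograms with fewer than two
populated bins. Binarization everywhere is strictly-greater-than-threshold,
with crop as the high-depth class.

### Gradient-guided histogram thresholding

Field and UAV depth maps frequently show a background drop-off across the
frame — the ground plane is not level in depth, due to shooting angle and
depth-model bias. A single global threshold then cannot separate crops from
the bright end of the background ramp. The gradient-guided pipeline
(`generatePseudoMask(method = "ggt")`) addresses this in five steps:

1. **Depth normalization** (`normalizeDepth`): subtract from each row its
   minimum, then from each column of the intermediate its minimum. Any
   separable additive field $f(i) + g(j)$ is removed exactly, and the
   operation is idempotent. The column minima are deliberately taken over
   the *row-normalized intermediate*, not the original map: subtracting both
   minima of the raw map can drive pixels negative, while the sequential
   form is nonnegative by construction. Normalization is gated by the
   manifest scenario tag — enabled for `in-field` and `uav`, disabled for
   `lab`, where backgrounds are flat and normalization would only amplify
   noise; a per-run override is available.
2. **Gradient and edges**: Sobel magnitude $G=\sqrt{S_x^2+S_y^2}$ (kernel
   size 3) and a Canny edge map $E$ (hysteresis thresholds 50/125 on the
   0–255 scale). In depth maps, strong gradients come almost exclusively
   from the crop–ground depth step, not from texture — this is what makes
   edge information trustworthy here.
3. **Target region** `Mt`: dilate `E` with a 30×30 square structuring
   element to bridge broken contours, then fill contour interiors
   (`EBImage::fillHull`). The "size 30" is read as one dilation with a
   30-pixel element, not 30 iterated dilations — the construction is meant
   to *slightly* connect edges, and a single stated number fits one element
   size.
4. **Edge-weighted histogram**: gradient magnitudes are quantized into
   $p=3$ levels $l_{ij} = \min(\lfloor p\,g_{ij}/\max G\rfloor,\,p-1)$ (the
   clamp puts maximal gradients in the top level, since the raw formula
   reaches $p$), each level gets weight
   $\gamma_k = \sum_{l=k} e_{ij} / \sum e_{ij}$, and
   $R_T = \sum_{D_n = T} \gamma_{l_{ij}} e_{ij}$ accumulates edge mass per
   intensity. Its cumulative rescaling $S_T$ (nondecreasing, $S_{255}=255$)
   concentrates dynamic range exactly at the intensities where crop
   boundaries live. $R$ is accumulated over all pixels with the binary edge
   indicator as the gate; the target region enters only later, as a mask on
   the transformed depth — restricting $R$ itself to `Mt` would couple two
   independently-motivated mechanisms.
5. **Sigmoid threshold**: fit $c/(1+e^{-a(T-b)})$ with $c=255$ fixed,
   $a \in (0,5]$, $b \in [0,255]$ by bounded least squares over all 256
   points of $S$ (the sequence is defined everywhere, so the fit uses it
   everywhere). The slope of a sigmoid is maximal at its midpoint, so
   $T^* = \mathrm{round}(b)$. The transformed depth
   $D_t = S[\mathrm{round}(D_n)]$, zeroed outside `Mt`, is binarized at
   $T^*$.

If any stage degenerates — a constant map (no gradient), no Canny edges, an
all-zero weighted histogram, or a failed fit — the pipeline falls back to
the Otsu result and flags the failed stage in its diagnostics, so batch runs
degrade gracefully scene by scene rather than aborting.

## Self-training and the trimap

Pseudo masks carry label noise. The two-stage loop (`twoStageTrain`)
exploits a simple observation: a model trained on noisy labels will
typically *disagree* with exactly the labels that were wrong, because
pixel-level noise is uncorrelated with the features while true structure is
not. Stage one fits the backend to the pseudo masks; the XOR trimap
(`makeTrimap`) marks every pixel where the stage-one prediction differs
from its own training label as ignore (serialized 128); stage two refits,
warm-started from the stage-one state, with ignore pixels excluded from the
loss. Warm starting is mandatory in the orchestration — stage two is a
refinement of stage one, not a fresh model. The trimap is computed on the
raw stage-one prediction, before any mask filtering, since refinement
belongs to inference, not to the training loop.

The shipped `ToyPixelBackend` is a full-batch logistic regression over
three depth-derived per-pixel features (scaled intensity, normalized
intensity, 5×5 local mean). It exists to exercise the orchestration —
ignore semantics, warm start, determinism, reporting — at desk scale, not to
compete with deep segmentation networks; adapters to real trainers plug in
behind the `SegmentationBackend` contract. Its defaults (learning rate 10,
500 epochs) are the smallest budget at which the optimizer is converged on
the package's canonical scenes; an unconverged stage one makes the
distillation comparison meaningless, because stage two then measures
leftover optimization progress rather than label quality.

## Mask refinement

Predicted masks are refined as probability-like maps on [0, 1] with one of
two edge-preserving filters, then re-binarized at 0.5 — the natural
majority-vote contract for a soft mask, chosen because pooled mIoU needs
binary inputs. The guidance is the depth map by default (RGB luma is
supported for comparison): depth edges coincide with true crop boundaries,
while RGB edges also follow leaf texture and soil clutter.

- `guidedFilter`: within each $(2r+1)^2$ window the output is an affine
  function of the guidance, $a_k = \mathrm{cov}(I,p)/(\mathrm{var}(I)+
  \epsilon)$, $b_k = \bar p - a_k \bar I$, averaged over all windows
  containing a pixel. With constant guidance, or as $\epsilon \to \infty$,
  it collapses exactly to a double box mean — a limit the tests verify
  against an independently coded reference.
- `jointBilateralFilter`: Gaussian spatial weights (sd `sigmaSpace` pixels,
  truncated at the window edge) times Gaussian range weights on guidance
  differences (sd `sigmaColor` on the 0–255 scale), over a square window of
  diameter `d` rounded up to odd. Defaults `d = 20`, `sigmaColor = 25`,
  `sigmaSpace = 15`.

All window operations use reflective (edge-inclusive symmetric) borders:
field images are interior-dominated, and reflection avoids the darkening
bias of zero padding.

## Evaluation

`miou` pools per class across the whole evaluated set — intersections and
unions are summed over images *before* dividing, then averaged over the two
classes. This dataset-level pooling (rather than a mean of per-image IoUs)
weighs images by pixel count, which matters under strong class imbalance
and heterogeneous image sizes. A class absent from every prediction and
every ground truth scores IoU 1 by convention; under pooling this can only
trigger when a class never occurs anywhere in the set. `canopyCoverage` and
`coverageHistogram` (half-open bins, last bin closed) summarize crop
fraction, the main difficulty axis of depth thresholding: high-coverage
scenes squeeze the ground plane out of the histogram.

## The synthetic generator

`generateScene` emulates the one property everything above relies on:
foreground blobs raised above a background plane, with an optional
separable background bias and additive Gaussian noise, quantized to integers
only at write time. Each blob is a plateau with a cosine shoulder of width
2 px descending to half the blob height at the support boundary, then a
step to the background. This shape was chosen against two requirements that
pull in opposite directions: noiseless unbiased scenes must have two depth
populations separated widely enough that Otsu provably recovers the ground
truth mask (the rim step of $0.5\Delta$ guarantees a gap of at least
$0.5\Delta$), while blob boundaries must still carry the strong localized
gradients the edge-weighted histogram keys on (the step and the shoulder
provide them). The ground-truth mask is the full blob support. Coverage
targeting, when requested, iterates blob placement until the crop fraction
is within ±0.05 of the target.

The canonical study conditions used by the test suite and the acceptance
script are 128×128 scenes with 6 blobs of radius 10–18 px and noise sd 2:
unbiased scenes use background 40 and blob height 100; biased scenes use
background 5, row bias 1.0/px and column bias 0.3/px (a drop-off of ~165
intensity units across the frame) with blob height 60, so the background
ramp dominates the crop contrast — the regime where a single global
threshold must fail. Batches of 20 scenes keep the full suite under half a
minute. One pseudorandom stream per scene, seeded from the scene spec,
makes every artifact bit-reproducible without touching global RNG state.

What the generator does *not* emulate — plant morphology, occlusion,
non-separable background relief, depth-model artifacts such as halos at
thin structures — bounds what passing tests show: they validate the
algorithms' contracts and their behavior in the regimes the methods were
designed for, not performance on real imagery.

## Numerical choices

- Intensity binning uses round-half-away-from-zero (10.5 → 11), applied
  identically in histograms and in the $S$ lookup.
- All argmax threshold searches return the smallest maximizer on ties.
- Canny applies no Gaussian pre-smoothing (the caller smooths if needed);
  non-maximum suppression is strict on the positive gradient side and
  non-strict on the negative, so a two-pixel plateau thins to one pixel;
  hysteresis is 8-connected geodesic dilation of strong pixels within weak
  ones, run to a fixed point.
- GHT masses and variances are clipped at $10^{-30}$ so empty split sides
  score neutrally instead of producing NaNs.
- The sigmoid fit runs L-BFGS-B from $a_0 = 0.1$, $b_0$ at the first
  crossing of 127.5, plus restarts at $b \in \{64, 128, 192\}$, keeping the
  best; failure of all restarts triggers the Otsu fallback.
- Trimap ignore pixels are `NA` in memory (R's native missing-label
  sentinel) and 128 on disk.

## Limitations

The gradient-guided method assumes the background bias is separable per
row/column; radial or saddle-shaped relief is only partially removed. The
edge-weighted histogram needs Canny to fire somewhere on the crop boundary
— extremely low-contrast scenes fall back to Otsu. The toy backend is
linear per pixel and cannot represent spatial context; conclusions about
self-training transfer only through the backend contract, not from the toy
model's absolute numbers. Depth maps are consumed as 8-bit; 16-bit depth
calibration is out of scope.
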