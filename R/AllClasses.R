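#' @import methods
NULL

#' Ignore label used in trimaps
#'
#' In-memory trimaps mark uncertain pixels with \code{NA_integer_}; on disk
#' the same pixels are serialized as gray value 128 (between the background 0
#' and foreground 255). \code{IGNORE_LABEL} is the on-disk code.
#' @export
IGNORE_LABEL <- 128L

## ---- image grid classes -----------------------------------------------

#' Single-channel depth map
#'
#' A numeric matrix of relative depth intensities in \[0, 255\], as produced
#' by monocular depth estimation models and re-encoded as 8-bit grayscale.
#' Under top-down crop imaging, crops sit on a distinct depth plane and read
#' brighter than the ground, which is the prior all thresholding in this
#' package exploits. Rows index image rows, (1,1) is the top-left pixel.
#'
#' @slot .Data numeric matrix, finite values in \[0, 255\], at least 3x3
#' @export
setClass("DepthMap", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (!is.numeric(v)) return("depth values must be numeric")
  if (nrow(v) < 3L || ncol(v) < 3L) return("depth map must be at least 3x3")
  if (!all(is.finite(v))) return("depth values must be finite")
  if (min(v) < 0 || max(v) > 255) return("depth values must lie in [0, 255]")
  TRUE
})

#' Binary crop mask
#'
#' A matrix over \{0, 1\} with 1 marking crop foreground. Used for pseudo
#' masks, model predictions, and ground truth alike.
#' @slot .Data numeric/integer matrix over \{0, 1\}
#' @export
setClass("CropMask", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (!all(v %in% c(0, 1))) return("mask values must be 0 or 1")
  TRUE
})

#' Ternary trimap
#'
#' A matrix over \{0, 1, NA\}: confident background, confident crop, and
#' ignore. Ignore pixels (NA in memory, 128 on disk) are excluded from any
#' training loss; they mark disagreement between a pseudo mask and a
#' stage-one model prediction.
#' @slot .Data integer matrix over \{0, 1, NA\}
#' @export
setClass("Trimap", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (!all(v %in% c(0, 1) | is.na(v))) return("trimap values must be 0, 1 or NA")
  TRUE
})

#' @rdname DepthMap-class
#' @param values numeric matrix in \[0, 255\]
#' @return a \code{DepthMap}
#' @export
DepthMap <- function(values) new("DepthMap", as.matrix(values))

#' @rdname CropMask-class
#' @param labels matrix over \{0,1\} (logical accepted)
#' @return a \code{CropMask}
#' @export
CropMask <- function(labels) {
  m <- as.matrix(labels)
  if (is.logical(m)) m <- m * 1L
  new("CropMask", m)
}

#' @rdname Trimap-class
#' @param labels matrix over \{0,1,NA\}
#' @return a \code{Trimap}
#' @export
Trimap <- function(labels) {
  m <- as.matrix(labels)
  storage.mode(m) <- "integer"
  new("Trimap", m)
}

setMethod("show", "DepthMap", function(object) {
  v <- object@.Data
  cat(sprintf("DepthMap %dx%d, range [%.1f, %.1f], mean %.1f\n",
              nrow(v), ncol(v), min(v), max(v), mean(v)))
})

setMethod("show", "CropMask", function(object) {
  v <- object@.Data
  cat(sprintf("CropMask %dx%d, coverage %.3f\n",
              nrow(v), ncol(v), mean(v == 1)))
})

setMethod("show", "Trimap", function(object) {
  v <- object@.Data
  cat(sprintf("Trimap %dx%d, fg %.3f bg %.3f ignore %.3f\n",
              nrow(v), ncol(v), mean(v == 1, na.rm = TRUE) * mean(!is.na(v)),
              mean(v == 0, na.rm = TRUE) * mean(!is.na(v)), mean(is.na(v))))
})

## ---- parameter classes ------------------------------------------------

#' Parameters of the generalized histogram thresholding family
#'
#' The four prior hyper-parameters of the GHT split objective: \code{nu}
#' (strength of the conjugate inverse-chi-squared variance prior), \code{tau}
#' (its scale), \code{kappa} (strength of the Beta prior on the mixture
#' weight) and \code{omega} (its mean). \code{nu = tau = kappa = 0},
#' \code{omega = 0.5} — the shipped defaults, following the reference
#' implementation of the method — give minimum-error thresholding; large
#' \code{nu} with small \code{tau} and \code{kappa = 0} recovers Otsu's
#' method.
#'
#' @slot nu,tau,kappa nonnegative reals
#' @slot omega real in \[0,1\]
#' @export
setClass("GHTParams",
  representation(nu = "numeric", tau = "numeric", kappa = "numeric",
                 omega = "numeric"),
  validity = function(object) {
    if (length(object@nu) != 1 || !is.finite(object@nu) || object@nu < 0)
      return("nu must be a single nonnegative finite number")
    if (length(object@tau) != 1 || !is.finite(object@tau) || object@tau < 0)
      return("tau must be a single nonnegative finite number")
    if (length(object@kappa) != 1 || !is.finite(object@kappa) || object@kappa < 0)
      return("kappa must be a single nonnegative finite number")
    if (length(object@omega) != 1 || !is.finite(object@omega) ||
        object@omega < 0 || object@omega > 1)
      return("omega must be a single number in [0, 1]")
    TRUE
  })

#' @rdname GHTParams-class
#' @param nu,tau,kappa,omega see class description
#' @return a \code{GHTParams}
#' @export
ghtParams <- function(nu = 0, tau = 0, kappa = 0, omega = 0.5)
  new("GHTParams", nu = nu, tau = tau, kappa = kappa, omega = omega)

#' Configuration of gradient-guided histogram thresholding
#'
#' Defaults follow the recommended settings of the method: Sobel kernel size
#' 3, Canny hysteresis thresholds 50/125, p = 3 gradient levels, a 30-pixel
#' square structuring element for edge dilation, and row/column depth
#' normalization enabled (normalization targets the sloped-background bias of
#' in-field and UAV scenes; disable it for flat lab backgrounds).
#'
#' @slot sobelKsize odd integer >= 3
#' @slot cannyLow,cannyHigh hysteresis thresholds, 0 <= low < high <= 255
#' @slot p integer >= 2, number of gradient levels
#' @slot dilation integer >= 1, side of the square dilation element
#' @slot applyNormalization logical, run row/column depth normalization
#' @export
setClass("GGTConfig",
  representation(sobelKsize = "integer", cannyLow = "numeric",
                 cannyHigh = "numeric", p = "integer", dilation = "integer",
                 applyNormalization = "logical"),
  validity = function(object) {
    if (object@sobelKsize < 3L || object@sobelKsize %% 2L == 0L)
      return("sobelKsize must be odd and >= 3")
    if (object@cannyLow < 0 || object@cannyHigh > 255 ||
        object@cannyLow >= object@cannyHigh)
      return("require 0 <= cannyLow < cannyHigh <= 255")
    if (object@p < 2L) return("p must be >= 2")
    if (object@dilation < 1L) return("dilation must be >= 1")
    TRUE
  })

#' @rdname GGTConfig-class
#' @param sobelKsize,cannyLow,cannyHigh,p,dilation,applyNormalization
#'   see class description
#' @return a \code{GGTConfig}
#' @export
ggtConfig <- function(sobelKsize = 3L, cannyLow = 50, cannyHigh = 125,
                      p = 3L, dilation = 30L, applyNormalization = TRUE)
  new("GGTConfig", sobelKsize = as.integer(sobelKsize), cannyLow = cannyLow,
      cannyHigh = cannyHigh, p = as.integer(p),
      dilation = as.integer(dilation),
      applyNormalization = applyNormalization)

#' Guided filter parameters
#'
#' \code{r} is the window half-size (the window is (2r+1) x (2r+1)); larger
#' windows smooth more aggressively. \code{eps} regularizes the per-window
#' linear coefficient; as eps grows the filter degenerates to a double box
#' mean. The conventional sweep range for r is 1..15.
#' @slot r integer >= 1
#' @slot eps positive real
#' @export
setClass("GuidedFilterParams",
  representation(r = "integer", eps = "numeric"),
  validity = function(object) {
    if (object@r < 1L) return("r must be >= 1")
    if (!is.finite(object@eps) || object@eps <= 0) return("eps must be > 0")
    TRUE
  })

#' @rdname GuidedFilterParams-class
#' @param r,eps see class description
#' @return a \code{GuidedFilterParams}
#' @export
guidedFilterParams <- function(r = 4L, eps = 1e-3)
  new("GuidedFilterParams", r = as.integer(r), eps = eps)

#' Joint bilateral filter parameters
#'
#' \code{d} is the neighborhood diameter (rounded up to an odd window side);
#' \code{sigmaColor} is the range standard deviation applied to guidance
#' intensity differences on the 0..255 scale; \code{sigmaSpace} the spatial
#' standard deviation in pixels. Defaults d = 20, sigmaColor = 25,
#' sigmaSpace = 15 follow the recommended settings for depth-guided mask
#' refinement.
#' @slot d integer >= 1
#' @slot sigmaColor,sigmaSpace positive reals
#' @export
setClass("JointBilateralParams",
  representation(d = "integer", sigmaColor = "numeric", sigmaSpace = "numeric"),
  validity = function(object) {
    if (object@d < 1L) return("d must be >= 1")
    if (object@sigmaColor <= 0 || object@sigmaSpace <= 0)
      return("sigmaColor and sigmaSpace must be > 0")
    TRUE
  })

#' @rdname JointBilateralParams-class
#' @param d,sigmaColor,sigmaSpace see class description
#' @return a \code{JointBilateralParams}
#' @export
jointBilateralParams <- function(d = 20L, sigmaColor = 25, sigmaSpace = 15)
  new("JointBilateralParams", d = as.integer(d), sigmaColor = sigmaColor,
      sigmaSpace = sigmaSpace)

## ---- derived-statistic classes ----------------------------------------

#' Edge-weighted depth histogram
#'
#' Holds the gradient-level weights \code{gamma} (one per level, summing to
#' one over edge pixels), the edge-weighted intensity sequence \code{R}
#' (256 bins), and its cumulative rescaling \code{S} (nondecreasing,
#' S\[256\] = 255), which together drive threshold selection in
#' gradient-guided histogram thresholding.
#' @slot gamma numeric vector of level weights
#' @slot R numeric length-256 vector of nonnegative weights
#' @slot S numeric length-256 nondecreasing vector in \[0,255\]
#' @export
setClass("WeightedDepthHistogram",
  representation(gamma = "numeric", R = "numeric", S = "numeric"),
  validity = function(object) {
    if (length(object@R) != 256L || length(object@S) != 256L)
      return("R and S must have length 256")
    if (any(object@R < 0)) return("R must be nonnegative")
    if (any(diff(object@S) < -1e-9)) return("S must be nondecreasing")
    if (any(object@gamma < 0)) return("gamma must be nonnegative")
    TRUE
  })

#' Sigmoid fit of the cumulative edge-weighted histogram
#'
#' Bounded least-squares fit of c / (1 + exp(-a (T - b))) to the rescaled
#' cumulative sequence S(T), with c fixed at 255, a in (0, 5\], b in
#' \[0, 255\]. The threshold is taken at the slope maximum of the fitted
#' curve, which for a sigmoid is its midpoint b.
#' @slot a,b fitted parameters
#' @slot c constant 255
#' @slot residual sum of squared residuals of the fit
#' @export
setClass("SigmoidFit",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 residual = "numeric"),
  validity = function(object) {
    if (object@a <= 0 || object@a > 5) return("a must lie in (0, 5]")
    if (object@b < 0 || object@b > 255) return("b must lie in [0, 255]")
    if (object@c != 255) return("c is the constant 255")
    if (!is.finite(object@residual) || object@residual < 0)
      return("residual must be finite and nonnegative")
    TRUE
  })

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf("SigmoidFit: a = %.4f, b = %.2f, c = %d, rss = %.3g\n",
              object@a, object@b, as.integer(object@c), object@residual))
})

## ---- synthetic scene specification ------------------------------------

#' Specification of a synthetic crop scene
#'
#' Describes a top-down depth scene: a background plane at \code{background}
#' with optional separable additive bias (\code{rowBias} per row index,
#' \code{colBias} per column index, emulating the depth drop-off of in-field
#' imagery), \code{nBlobs} crop blobs of radius in \code{radiusRange} raised
#' \code{blobHeight} above the background, and i.i.d. Gaussian pixel noise
#' \code{noiseSd}. Each blob is a raised plateau with a smooth cosine
#' shoulder of width \code{shoulder} pixels descending to fraction
#' \code{rimHeight} of the blob height at the support boundary, so blob
#' edges carry both a strong gradient and a clean depth step. The ground
#' truth mask is the full blob support. If \code{coverage} is set, blobs are
#' placed until the crop fraction is within 0.05 of it.
#'
#' @slot height,width image size in pixels (>= 16 each)
#' @slot nBlobs number of crop blobs (>= 0)
#' @slot radiusRange (min, max) blob radius in pixels
#' @slot blobHeight depth contrast of crops over background, in (0, 255]
#' @slot background background plane level in \[0, 255)
#' @slot rowBias,colBias additive background gradient per pixel index
#' @slot noiseSd standard deviation of additive Gaussian noise (>= 0)
#' @slot shoulder shoulder width in pixels (>= 1)
#' @slot rimHeight profile height at the support boundary, fraction in (0,1)
#' @slot coverage optional target crop fraction in (0,1); NA disables
#' @slot seed integer RNG seed for this scene
#' @export
setClass("SceneSpec",
  representation(height = "integer", width = "integer", nBlobs = "integer",
                 radiusRange = "numeric", blobHeight = "numeric",
                 background = "numeric", rowBias = "numeric",
                 colBias = "numeric", noiseSd = "numeric",
                 shoulder = "numeric", rimHeight = "numeric",
                 coverage = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@height < 16L || object@width < 16L)
      return("scene must be at least 16x16")
    if (object@nBlobs < 0L) return("nBlobs must be >= 0")
    if (length(object@radiusRange) != 2L ||
        object@radiusRange[1] > object@radiusRange[2] ||
        object@radiusRange[1] < 2)
      return("radiusRange must be (min, max) with 2 <= min <= max")
    if (object@blobHeight <= 0 || object@blobHeight > 255)
      return("blobHeight must lie in (0, 255]")
    if (object@background < 0 || object@background >= 255)
      return("background must lie in [0, 255)")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@shoulder < 1) return("shoulder must be >= 1")
    if (object@rimHeight <= 0 || object@rimHeight >= 1)
      return("rimHeight must lie in (0, 1)")
    if (!is.na(object@coverage) &&
        (object@coverage <= 0 || object@coverage >= 1))
      return("coverage must lie in (0, 1)")
    lo <- object@background +
      min(0, object@rowBias * (object@height - 1L)) +
      min(0, object@colBias * (object@width - 1L))
    hi <- object@background +
      max(0, object@rowBias * (object@height - 1L)) +
      max(0, object@colBias * (object@width - 1L)) + object@blobHeight
    if (lo < 0 || hi > 255)
      return("background + bias extremes + blobHeight must stay within [0, 255]")
    TRUE
  })

#' @rdname SceneSpec-class
#' @param height,width,nBlobs,radiusRange,blobHeight,background,rowBias,colBias,noiseSd,shoulder,rimHeight,coverage,seed
#'   see class description
#' @return a \code{SceneSpec}
#' @export
sceneSpec <- function(height = 128L, width = 128L, nBlobs = 6L,
                      radiusRange = c(10, 18), blobHeight = 100,
                      background = 40, rowBias = 0, colBias = 0,
                      noiseSd = 2, shoulder = 2, rimHeight = 0.5,
                      coverage = NA_real_, seed = 1L)
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      nBlobs = as.integer(nBlobs), radiusRange = as.numeric(radiusRange),
      blobHeight = blobHeight, background = background, rowBias = rowBias,
      colBias = colBias, noiseSd = noiseSd, shoulder = shoulder,
      rimHeight = rimHeight, coverage = as.numeric(coverage),
      seed = as.integer(seed))

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0(
    "SceneSpec %dx%d: %d blobs r[%.0f,%.0f] dz=%.0f, bg=%.0f, ",
    "bias=(%.2f,%.2f)/px, sd=%.1f, seed=%d\n"),
    object@height, object@width, object@nBlobs, object@radiusRange[1],
    object@radiusRange[2], object@blobHeight, object@background,
    object@rowBias, object@colBias, object@noiseSd, object@seed))
})

## ---- evaluation report -------------------------------------------------

#' Pooled mIoU evaluation report
#'
#' Per-class intersection-over-union pooled across all evaluated images
#' (intersections and unions are summed over images before dividing), the
#' mean over the two classes (background, crop), and an optional per-group
#' breakdown computed the same way on subsets.
#' @slot classIoU named numeric: pooled IoU for background and crop
#' @slot miou mean of the class IoUs, in \[0,1\]
#' @slot perGroup data.frame with columns group, iouBackground, iouCrop,
#'   miou, n (zero rows when no groups were supplied)
#' @slot n number of evaluated mask pairs
#' @export
setClass("EvalReport",
  representation(classIoU = "numeric", miou = "numeric",
                 perGroup = "data.frame", n = "integer"),
  validity = function(object) {
    if (any(object@classIoU < 0 | object@classIoU > 1))
      return("class IoU must lie in [0, 1]")
    if (object@n < 1L) return("n must be >= 1")
    TRUE
  })

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d mask pair(s)\n", object@n))
  cat(sprintf("  IoU background: %.4f\n", object@classIoU[["background"]]))
  cat(sprintf("  IoU crop:       %.4f\n", object@classIoU[["crop"]]))
  cat(sprintf("  mIoU:           %.4f (%.2f)\n", object@miou,
              100 * object@miou))
  if (nrow(object@perGroup) > 0L) {
    cat("  per group:\n")
    for (k in seq_len(nrow(object@perGroup)))
      cat(sprintf("    %-12s mIoU %.4f (n=%d)\n",
                  object@perGroup$group[k], object@perGroup$miou[k],
                  object@perGroup$n[k]))
  }
})

## ---- segmentation backends --------------------------------------------

#' Segmentation backend contract
#'
#' Virtual parent of pluggable per-pixel segmentation models used by the
#' two-stage self-training orchestration. A backend must implement
#' \code{\link{fitBackend}} (honoring ignore labels and an optional warm
#' start) and \code{\link{predictBackend}} (deterministic given state and
#' features). Deep segmentation networks plug in behind this contract; the
#' package ships \code{\linkS4class{ToyPixelBackend}} so the orchestration is
#' testable without one.
#' @export
setClass("SegmentationBackend", representation("VIRTUAL"))

#' Logistic per-pixel toy backend
#'
#' A deterministic logistic classifier over per-pixel depth-derived features
#' (scaled intensity, row/column-normalized intensity, local mean), trained
#' by full-batch gradient descent. It exists to exercise the two-stage
#' self-training loop — ignore-label semantics, warm start, reporting — with
#' desk-scale compute; it is not a competitive segmentation model.
#' @slot learningRate gradient-descent step size
#' @slot epochs number of full-batch epochs
#' @slot seed integer seed (the optimizer itself is deterministic; the seed
#'   is part of the backend contract for stochastic implementations)
#' @export
setClass("ToyPixelBackend", contains = "SegmentationBackend",
  representation(learningRate = "numeric", epochs = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@epochs < 1L) return("epochs must be >= 1")
    TRUE
  })

#' @rdname ToyPixelBackend-class
#' @param learningRate,epochs,seed see class description
#' @return a \code{ToyPixelBackend}
#' @export
toyPixelBackend <- function(learningRate = 10, epochs = 500L, seed = 1L)
  new("ToyPixelBackend", learningRate = learningRate,
      epochs = as.integer(epochs), seed = as.integer(seed))

setMethod("show", "ToyPixelBackend", function(object) {
  cat(sprintf("ToyPixelBackend: lr = %.2f, epochs = %d\n",
              object@learningRate, object@epochs))
})
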