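# Depth-guided edge-preserving post-processing of predicted masks. Both
# filters treat the mask as a probability-like map on [0, 1] and rely on a
# guidance image (normally the depth map: depth edges coincide with true
# crop boundaries, while RGB edges also follow texture).

guidanceMatrix <- function(guidance) {
  if (is(guidance, "DepthMap")) return(pixelValues(guidance))
  if (length(dim(guidance)) == 3L) {
    # luma conversion keeps RGB guidance single-channel, symmetric with depth
    return(0.299 * guidance[, , 1] + 0.587 * guidance[, , 2] +
             0.114 * guidance[, , 3])
  }
  as.matrix(guidance)
}

#' Guided filter
#'
#' The classic local-linear guided filter: within each (2r+1) x (2r+1)
#' window k the output is modeled as an affine function of the guidance I,
#' with \deqn{a_k = cov_k(I, p) / (var_k(I) + \epsilon), \quad b_k =
#' mean_k(p) - a_k\, mean_k(I),} and each pixel averages the models of all
#' windows containing it. Box means use reflective borders. With constant
#' guidance (or as eps grows without bound) the filter reduces exactly to a
#' double box mean of the input.
#'
#' @param input numeric matrix on \[0, 1\]
#' @param guidance a \code{DepthMap}, grayscale matrix, or RGB array
#'   (converted to luma); rescaled to \[0, 1\] internally
#' @param params a \code{\linkS4class{GuidedFilterParams}}
#' @return filtered numeric matrix
#' @export
guidedFilter <- function(input, guidance, params = guidedFilterParams()) {
  stopifnot(is(params, "GuidedFilterParams"))
  validObject(params)
  p <- as.matrix(input)
  I <- guidanceMatrix(guidance)
  stopDim(all(dim(p) == dim(I)), "input and guidance shapes must agree")
  if (max(I) > 1) I <- I / 255
  r <- params@r; eps <- params@eps
  meanI <- boxMean(I, r)
  meanP <- boxMean(p, r)
  corrI <- boxMean(I * I, r)
  corrIP <- boxMean(I * p, r)
  varI <- corrI - meanI^2
  covIP <- corrIP - meanI * meanP
  a <- covIP / (varI + eps)
  b <- meanP - a * meanI
  boxMean(a, r) * I + boxMean(b, r)
}

#' Joint bilateral filter
#'
#' Weighted average over a square neighborhood of side \code{d} (rounded up
#' to odd), with spatial Gaussian weights (sd \code{sigmaSpace}, truncated
#' at the window edge) and range Gaussian weights computed on the guidance
#' image (sd \code{sigmaColor} on the 0..255 intensity scale). Smoothing
#' therefore does not cross guidance edges. As sigmaColor grows the filter
#' reduces to plain truncated spatial Gaussian convolution.
#'
#' @param input numeric matrix on \[0, 1\]
#' @param guidance a \code{DepthMap}, grayscale matrix, or RGB array
#' @param params a \code{\linkS4class{JointBilateralParams}}
#' @return filtered numeric matrix
#' @export
jointBilateralFilter <- function(input, guidance,
                                 params = jointBilateralParams()) {
  stopifnot(is(params, "JointBilateralParams"))
  validObject(params)
  p <- as.matrix(input)
  g <- guidanceMatrix(guidance)
  stopDim(all(dim(p) == dim(g)), "input and guidance shapes must agree")
  if (max(g) <= 1 && min(g) >= 0) g <- g * 255
  r <- params@d %/% 2L
  if (r == 0L) return(p)  # window collapses to the pixel itself
  sc2 <- 2 * params@sigmaColor^2
  ss2 <- 2 * params@sigmaSpace^2
  num <- matrix(0, nrow(p), ncol(p))
  den <- matrix(0, nrow(p), ncol(p))
  pp <- padReflect(p, r)
  gp <- padReflect(g, r)
  h <- nrow(p); w <- ncol(p)
  for (di in -r:r) {
    for (dj in -r:r) {
      ws <- exp(-(di * di + dj * dj) / ss2)
      gs <- gp[r + di + seq_len(h), r + dj + seq_len(w), drop = FALSE]
      ps <- pp[r + di + seq_len(h), r + dj + seq_len(w), drop = FALSE]
      wgt <- ws * exp(-(g - gs)^2 / sc2)
      num <- num + wgt * ps
      den <- den + wgt
    }
  }
  num / den
}

#' Refine a predicted mask with a depth-guided filter
#'
#' Casts the binary mask to \[0, 1\], applies the selected edge-preserving
#' filter under the given guidance, and re-binarizes at strictly greater
#' than 0.5 (majority vote of the probability-like filtered map). With the
#' depth map as guidance, isolated speckles on a flat background are voted
#' out while mask regions aligned with depth steps are preserved.
#'
#' @param mask a \code{\linkS4class{CropMask}}
#' @param guidance a \code{DepthMap}, grayscale matrix, or RGB array
#' @param filter \code{"gf"} (guided filter) or \code{"jbf"} (joint
#'   bilateral filter)
#' @param params filter parameter object matching \code{filter}; defaults
#'   to the shipped defaults of the selected filter
#' @return the refined \code{CropMask}
#' @examples
#' sc <- generateScene(sceneSpec(seed = 11))
#' refined <- refineMask(sc$mask, sc$depth, "jbf")
#' @export
refineMask <- function(mask, guidance, filter = c("gf", "jbf"),
                       params = NULL) {
  filter <- match.arg(filter)
  stopifnot(is(mask, "CropMask"))
  soft <- pixelValues(mask) * 1.0
  out <- if (filter == "gf") {
    guidedFilter(soft, guidance, params %||% guidedFilterParams())
  } else {
    jointBilateralFilter(soft, guidance, params %||% jointBilateralParams())
  }
  CropMask((out > 0.5) * 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
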