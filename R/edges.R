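# Gradient and edge operators used by gradient-guided histogram
# thresholding. Sobel and Canny are written against plain matrices with
# reflective border handling; morphological dilation and hole filling go
# through EBImage.

sobelVectors <- function(ksize) {
  if (ksize %% 2L == 0L || ksize < 3L)
    stop("Sobel kernel size must be odd and >= 3", call. = FALSE)
  smooth <- choose(ksize - 1L, 0:(ksize - 1L))
  deriv <- c(-1, 0, 1)
  if (ksize > 3L) {
    s2 <- choose(ksize - 3L, 0:(ksize - 3L))
    deriv <- stats::convolve(s2, rev(deriv), type = "open")
  }
  list(smooth = smooth, deriv = deriv)
}

imgMat <- function(x) {
  if (is(x, "DepthMap") || is(x, "CropMask") || is(x, "Trimap"))
    pixelValues(x) else as.matrix(x)
}

#' Sobel gradient magnitude
#'
#' Computes \eqn{G = \sqrt{S_x^2 + S_y^2}} of separable Sobel responses with
#' reflective border handling. For the default 3x3 kernel an isolated
#' interior intensity step of height h produces edge-adjacent magnitudes of
#' 4h (the 1-2-1 smoothing row summed).
#'
#' @param depth a \code{DepthMap} or numeric matrix
#' @param ksize odd kernel size >= 3 (default 3)
#' @return matrix of nonnegative gradient magnitudes
#' @export
computeGradient <- function(depth, ksize = 3L) {
  v <- imgMat(depth)
  k <- sobelVectors(as.integer(ksize))
  gx <- convSep(v, k$smooth, k$deriv)
  gy <- convSep(v, k$deriv, k$smooth)
  sqrt(gx^2 + gy^2)
}

#' Canny edge map
#'
#' Standard Canny on a depth map: 3x3 Sobel gradients, four-direction
#' non-maximum suppression, and double-threshold hysteresis (weak edge
#' pixels survive only when connected to a strong one). No Gaussian
#' pre-smoothing is applied; callers smooth beforehand if their input is
#' noisy. Defaults low = 50, high = 125 on the 0..255 intensity scale.
#'
#' @param depth a \code{DepthMap} or numeric matrix
#' @param low,high hysteresis thresholds, 0 <= low < high
#' @return binary edge matrix over \{0, 1\}
#' @export
computeEdges <- function(depth, low = 50, high = 125) {
  if (low < 0 || low >= high)
    stop("require 0 <= low < high", call. = FALSE)
  v <- imgMat(depth)
  k <- sobelVectors(3L)
  gx <- convSep(v, k$smooth, k$deriv)
  gy <- convSep(v, k$deriv, k$smooth)
  mag <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx)
  theta[theta < 0] <- theta[theta < 0] + pi
  dirBin <- floor((theta + pi / 8) / (pi / 4)) %% 4
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(v), ncol(v))
  for (b in 0:3) {
    o <- offs[[b + 1L]]
    nPlus <- shiftReflect(mag, o[1], o[2])
    nMinus <- shiftReflect(mag, -o[1], -o[2])
    # strict on one side so a two-pixel plateau thins to one pixel
    keep <- keep | (dirBin == b & mag > nPlus & mag >= nMinus)
  }
  weak <- keep & mag > low
  strong <- keep & mag > high
  if (!any(strong)) return(matrix(0L, nrow(v), ncol(v)))
  # geodesic dilation of strong within weak, 8-connected, to a fixed point
  kern <- matrix(1L, 3L, 3L)
  cur <- strong * 1L
  repeat {
    grown <- (EBImage::dilate(cur, kern) > 0) & weak
    grownI <- grown * 1L
    if (identical(grownI, cur)) break
    cur <- grownI
  }
  matrix(as.integer(cur), nrow(v), ncol(v))
}

#' Coarse target mask from an edge map
#'
#' Dilates the binary edge map with a square structuring element (side
#' \code{dilation}) to connect fragmented edges, then fills the interiors of
#' the resulting closed contours. The result always contains the dilated
#' edges. This coarse region restricts where the transformed depth map may
#' claim foreground.
#'
#' @param edges binary matrix over \{0, 1\}
#' @param dilation side of the square structuring element (default 30)
#' @return a \code{\linkS4class{CropMask}}
#' @export
buildTargetMask <- function(edges, dilation = 30L) {
  e <- imgMat(edges)
  if (!all(e %in% c(0, 1))) stop("edge map must be binary", call. = FALSE)
  dilation <- as.integer(dilation)
  if (dilation < 1L) stop("dilation must be >= 1", call. = FALSE)
  if (!any(e == 1)) return(CropMask(matrix(0L, nrow(e), ncol(e))))
  d <- if (dilation > 1L) EBImage::dilate(e, matrix(1L, dilation, dilation))
       else e
  filled <- EBImage::fillHull(d)
  CropMask(matrix(as.integer(filled > 0), nrow(e), ncol(e)))
}
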