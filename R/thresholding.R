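# Pseudo-mask generation: three histogram thresholding strategies on a
# depth map. Crops read brighter than ground, so the foreground is always
# the high-intensity class and the binarization convention everywhere is
# strictly-greater-than-threshold. All argmax searches break ties toward
# the smallest threshold for reproducibility.

#' Intensity histogram of a depth map
#'
#' 256 bins indexed by quantized intensity 0..255. Real-valued intensities
#' are binned by round-half-away-from-zero (10.5 goes to bin 11).
#'
#' @param depth a \code{DepthMap} or numeric matrix on \[0, 255\]
#' @return numeric vector of length 256; sums to the pixel count
#' @export
depthHistogram <- function(depth) {
  v <- imgMat(depth)
  tabulate(as.integer(roundHalfUp(v)) + 1L, nbins = 256L)
}

checkHistogram <- function(h) {
  if (length(h) != 256L || any(h < 0) || any(!is.finite(h)))
    stop("histogram must be 256 nonnegative finite counts", call. = FALSE)
  if (sum(h > 0) < 2L)
    stop("degenerate histogram: fewer than two populated intensity bins",
         call. = FALSE)
}

#' Otsu's threshold
#'
#' Returns the threshold T* maximizing the between-class variance
#' \deqn{\sigma_B^2(T) = w_0(T) w_1(T) (u_0(T) - u_1(T))^2} over all splits
#' \{<= T\} vs \{> T\} with both classes nonempty, where w are class
#' probabilities and u class mean intensities. Ties return the smallest
#' maximizer.
#'
#' @param h length-256 intensity histogram (see \code{\link{depthHistogram}})
#' @return integer threshold in \[0, 255\]
#' @export
otsuThreshold <- function(h) {
  checkHistogram(h)
  x <- 0:255
  tot <- sum(h)
  w0 <- cumsum(h)
  m0 <- cumsum(h * x)
  w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- ifelse(valid, m0 / w0, 0)
  mu1 <- ifelse(valid, (m0[256] - m0) / w1, 0)
  sigma <- (w0 / tot) * (w1 / tot) * (mu0 - mu1)^2
  sigma[!valid] <- -Inf
  as.integer(x[which.max(sigma)])
}

#' Generalized histogram threshold
#'
#' The GHT split objective: each side of a candidate split is scored by a
#' Gaussian log-likelihood whose variance is regularized by a conjugate
#' inverse-chi-squared prior of strength \code{nu} and scale \code{tau},
#' plus a Beta(\code{kappa}, \code{omega}) prior on the mixture weight. The
#' returned threshold maximizes the summed score; ties return the smallest
#' maximizer. The family interpolates between Otsu's method, minimum-error
#' thresholding and weighted percentile thresholding.
#'
#' @param h length-256 intensity histogram
#' @param params a \code{\linkS4class{GHTParams}}
#' @return integer threshold in \[0, 255\]
#' @export
ghtThreshold <- function(h, params = ghtParams()) {
  checkHistogram(h)
  stopifnot(is(params, "GHTParams"))
  validObject(params)
  obj <- ghtObjective(h, params)
  as.integer((0:254)[which.max(obj)])
}

# the per-split objective f0 + f1 for splits {0..t} vs {t+1..255},
# t = 0..254; variances and masses clipped away from zero as in the
# reference formulation so empty sides score neutrally
ghtObjective <- function(h, params) {
  nu <- params@nu; tau <- params@tau
  kappa <- params@kappa; omega <- params@omega
  x <- 0:255
  eps <- 1e-30
  cs <- cumsum(h)[1:255]
  csx <- cumsum(h * x)[1:255]
  csx2 <- cumsum(h * x^2)[1:255]
  tot <- sum(h); totx <- sum(h * x); totx2 <- sum(h * x^2)
  w0 <- pmax(cs, eps)
  w1 <- pmax(tot - cs, eps)
  p0 <- w0 / (w0 + w1)
  p1 <- w1 / (w0 + w1)
  mu0 <- csx / w0
  mu1 <- (totx - csx) / w1
  d0 <- pmax(csx2 - w0 * mu0^2, 0)
  d1 <- pmax(totx2 - csx2 - w1 * mu1^2, 0)
  v0 <- pmax((p0 * nu * tau^2 + d0) / (p0 * nu + w0), eps)
  v1 <- pmax((p1 * nu * tau^2 + d1) / (p1 * nu + w1), eps)
  f0 <- -d0 / v0 - w0 * log(v0) + 2 * (w0 + kappa * omega) * log(w0)
  f1 <- -d1 / v1 - w1 * log(v1) + 2 * (w1 + kappa * (1 - omega)) * log(w1)
  f0 + f1
}

#' Binarize a depth map at a threshold
#'
#' Crop is the high-depth class: \code{mask = 1} iff \code{depth > T}.
#'
#' @param depth a \code{DepthMap} or numeric matrix
#' @param threshold integer in \[0, 255\]
#' @return a \code{\linkS4class{CropMask}}
#' @export
applyThreshold <- function(depth, threshold) {
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 255)
  v <- imgMat(depth)
  CropMask((v > threshold) * 1L)
}

#' Row/column depth normalization
#'
#' Subtracts from every row its row minimum, then from every column of the
#' intermediate its column minimum. A purely separable additive background
#' bias f(i) + g(j) — the depth drop-off seen in field and UAV imagery — is
#' removed exactly, leaving crops on a flat zero background. The column
#' minima are taken over the row-normalized intermediate, not the original
#' map, so the output is always nonnegative. The operation is idempotent.
#'
#' @param depth a \code{DepthMap} or numeric matrix
#' @return a normalized \code{\linkS4class{DepthMap}}
#' @export
normalizeDepth <- function(depth) {
  v <- imgMat(depth)
  v <- v - apply(v, 1, min)
  v <- sweep(v, 2, apply(v, 2, min))
  DepthMap(v)
}

#' Quantize gradient magnitudes into p levels
#'
#' \code{l = min(floor(p g / max G), p - 1)}; pixels attaining the maximal
#' gradient land in the top level p - 1.
#'
#' @param G nonnegative gradient magnitude matrix with \code{max(G) > 0}
#' @param p number of levels (>= 2, default 3)
#' @return integer matrix over \{0, ..., p-1\}
#' @export
gradientLevels <- function(G, p = 3L) {
  p <- as.integer(p)
  if (p < 2L) stop("p must be >= 2", call. = FALSE)
  mx <- max(G)
  if (!is.finite(mx) || mx <= 0)
    stop("no gradient: max(G) must be > 0", call. = FALSE)
  L <- pmin(floor(p * G / mx), p - 1L)
  matrix(as.integer(L), nrow(G), ncol(G))
}

#' Edge-pixel weight of each gradient level
#'
#' \deqn{\gamma_k = \sum_{l_{ij}=k} e_{ij} / \sum e_{ij}}: the fraction of
#' edge pixels whose gradient level is k. Weights are nonnegative and sum
#' to one whenever any edge pixel exists.
#'
#' @param L gradient-level matrix from \code{\link{gradientLevels}}
#' @param E binary edge matrix
#' @param p number of levels
#' @return numeric vector of length p
#' @export
levelWeights <- function(L, E, p = 3L) {
  p <- as.integer(p)
  e <- imgMat(E)
  s <- sum(e)
  if (s == 0) stop("no edge pixels", call. = FALSE)
  vapply(0:(p - 1L), function(k) sum(e[L == k]), numeric(1)) / s
}

#' Edge-weighted depth histogram and its cumulative rescaling
#'
#' \code{R[T]} sums \eqn{\gamma_{l_{ij}} e_{ij}} over pixels whose rounded
#' intensity equals T, concentrating histogram mass at intensities observed
#' on strong depth edges; \code{S} is the cumulative sum of R rescaled so
#' that S\[255\] = 255 (nondecreasing by construction).
#'
#' @param depth the (normalized) \code{DepthMap}
#' @param L gradient-level matrix
#' @param E binary edge matrix
#' @param gamma level weights from \code{\link{levelWeights}}
#' @return a \code{\linkS4class{WeightedDepthHistogram}}
#' @export
weightedHistogram <- function(depth, L, E, gamma) {
  v <- imgMat(depth)
  e <- imgMat(E)
  w <- gamma[L + 1L] * e
  idx <- as.integer(roundHalfUp(v)) + 1L
  R <- numeric(256)
  agg <- rowsum(as.vector(w), group = idx)
  R[as.integer(rownames(agg))] <- agg[, 1]
  if (sum(R) <= 0)
    stop("degenerate weighted histogram: all weights zero", call. = FALSE)
  S <- 255 * cumsum(R) / sum(R)
  new("WeightedDepthHistogram", gamma = gamma, R = R, S = S)
}

#' Fit a sigmoid to the cumulative edge-weighted sequence
#'
#' Bounded least squares of \eqn{c / (1 + e^{-a (T - b)})}, c fixed at 255,
#' over a in (0, 5\] and b in \[0, 255\], minimizing the squared error
#' against S(T) at T = 0..255. Optimization is L-BFGS-B started from
#' a = 0.1 with b at the first T where S crosses 127.5, plus three spread
#' restarts of b; the best of the successful runs is kept.
#'
#' @param S length-256 nondecreasing sequence with S\[256\] = 255, or a
#'   \code{WeightedDepthHistogram}
#' @return a \code{\linkS4class{SigmoidFit}}
#' @export
fitSigmoid <- function(S) {
  if (is(S, "WeightedDepthHistogram")) S <- S@S
  stopifnot(length(S) == 256L)
  Tseq <- 0:255
  sse <- function(par) {
    pred <- 255 / (1 + exp(-par[1] * (Tseq - par[2])))
    sum((S - pred)^2)
  }
  b0 <- Tseq[which(S >= 127.5)[1]]
  if (is.na(b0)) b0 <- 128
  starts <- unique(c(b0, 64, 128, 192))
  best <- NULL
  for (b in starts) {
    fit <- tryCatch(
      stats::optim(c(0.1, b), sse, method = "L-BFGS-B",
                   lower = c(1e-4, 0), upper = c(5, 255)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("sigmoid fit failed after restarts", call. = FALSE)
  new("SigmoidFit", a = best$par[1], b = best$par[2], c = 255,
      residual = best$value)
}

#' Threshold at the slope maximum of a fitted sigmoid
#'
#' The sigmoid's derivative \eqn{c a e^{-a(n-b)} / (1 + e^{-a(n-b)})^2} is
#' maximal at its midpoint n = b, so the threshold is b rounded to the
#' nearest integer and clamped to \[0, 255\].
#'
#' @param fit a \code{\linkS4class{SigmoidFit}}
#' @return integer threshold in \[0, 255\]
#' @export
thresholdFromFit <- function(fit) {
  stopifnot(is(fit, "SigmoidFit"))
  as.integer(clip(roundHalfUp(fit@b), 0, 255))
}

#' Generate a pseudo crop mask from a depth map
#'
#' The package's central operation. \code{method = "otsu"} and
#' \code{"ght"} threshold the raw intensity histogram; \code{"ggt"} runs
#' gradient-guided histogram thresholding: row/column depth normalization
#' (when enabled), Sobel gradient and Canny edge maps, a coarse target mask
#' from dilated-and-filled edges, gradient-level edge weights, the
#' edge-weighted cumulative sequence S, a bounded sigmoid fit, and
#' binarization of the S-transformed depth (gated by the target mask) at
#' the sigmoid midpoint.
#'
#' If a ggt stage degenerates (no gradient, no edges, an all-zero weighted
#' histogram, or sigmoid fit failure) the function falls back to the Otsu
#' result and records the failed stage in \code{fallback}; a depth map that
#' is degenerate for Otsu too (single populated intensity bin) raises an
#' error.
#'
#' @param depth a \code{\linkS4class{DepthMap}}
#' @param method one of \code{"otsu"}, \code{"ght"}, \code{"ggt"}
#' @param cfg a \code{\linkS4class{GGTConfig}}
#' @param ghtPars a \code{\linkS4class{GHTParams}} (method = "ght")
#' @return a list with elements \code{mask} (\code{CropMask}),
#'   \code{method}, \code{threshold}, \code{fallback} (\code{NULL} or the
#'   failed stage name) and \code{diagnostics} (for ggt: the normalized
#'   depth \code{Dn}, gradient \code{G}, edges \code{E}, target mask
#'   \code{Mt}, weighted histogram \code{wh}, sigmoid \code{fit}, and the
#'   transformed depth \code{Dt})
#' @examples
#' sc <- generateScene(sceneSpec(rowBias = 0.5, background = 10, seed = 3))
#' res <- generatePseudoMask(sc$depth, method = "ggt")
#' res$threshold
#' @export
generatePseudoMask <- function(depth, method = c("otsu", "ght", "ggt"),
                               cfg = ggtConfig(), ghtPars = ghtParams()) {
  method <- match.arg(method)
  stopifnot(is(depth, "DepthMap"))
  if (method == "otsu") {
    t <- otsuThreshold(depthHistogram(depth))
    return(list(mask = applyThreshold(depth, t), method = "otsu",
                threshold = t, fallback = NULL, diagnostics = list()))
  }
  if (method == "ght") {
    validObject(cfg)
    t <- ghtThreshold(depthHistogram(depth), ghtPars)
    return(list(mask = applyThreshold(depth, t), method = "ght",
                threshold = t, fallback = NULL, diagnostics = list()))
  }
  validObject(cfg)
  otsuFallback <- function(stage, diag) {
    t <- otsuThreshold(depthHistogram(depth))
    list(mask = applyThreshold(depth, t), method = "ggt", threshold = t,
         fallback = stage, diagnostics = diag)
  }
  Dn <- if (cfg@applyNormalization) normalizeDepth(depth) else depth
  G <- computeGradient(Dn, cfg@sobelKsize)
  diag <- list(Dn = Dn, G = G)
  if (max(G) <= 0) return(otsuFallback("no-gradient", diag))
  E <- computeEdges(Dn, cfg@cannyLow, cfg@cannyHigh)
  diag$E <- E
  if (!any(E == 1)) return(otsuFallback("no-edges", diag))
  Mt <- buildTargetMask(E, cfg@dilation)
  diag$Mt <- Mt
  L <- gradientLevels(G, cfg@p)
  gamma <- levelWeights(L, E, cfg@p)
  wh <- tryCatch(weightedHistogram(Dn, L, E, gamma), error = function(e) NULL)
  diag$wh <- wh
  if (is.null(wh)) return(otsuFallback("degenerate-weighted-histogram", diag))
  fit <- tryCatch(fitSigmoid(wh@S), error = function(e) NULL)
  diag$fit <- fit
  if (is.null(fit)) return(otsuFallback("fit-failure", diag))
  t <- thresholdFromFit(fit)
  # transformed depth: monotone intensity remap through S, gated by the
  # coarse target region
  Dt <- wh@S[as.integer(roundHalfUp(imgMat(Dn))) + 1L]
  Dt <- matrix(Dt, nrow(depth), ncol(depth))
  Dt[pixelValues(Mt) == 0] <- 0
  diag$Dt <- Dt
  list(mask = CropMask((Dt > t) * 1L), method = "ggt", threshold = t,
       fallback = NULL, diagnostics = diag)
}
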