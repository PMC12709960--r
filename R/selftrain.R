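# Two-stage self-training over a pluggable per-pixel segmentation backend.
# Stage one trains on depth-derived pseudo masks; the trimap marks pixels
# where stage one disagrees with its own training label as ignore; stage
# two retrains, warm-started from stage one, on the confident pixels only.
# This distills label noise out of the pseudo masks.

#' Trimap from a pseudo mask and a stage-one prediction
#'
#' \deqn{M_c(i,j) = ignore \textrm{ if } M(i,j) \oplus \hat M_i(i,j) = 1,
#' \textrm{ else } M(i,j)} — pixels where the pseudo mask and the inferred
#' mask disagree (elementwise XOR) become ignore (NA in memory, 128 on
#' disk); agreeing pixels keep the pseudo-mask label. The ignore count is
#' exactly the Hamming distance between the two masks.
#'
#' @param pseudo the pseudo \code{CropMask} M
#' @param inferred the stage-one prediction \code{CropMask}
#' @return a \code{\linkS4class{Trimap}}
#' @export
makeTrimap <- function(pseudo, inferred) {
  stopifnot(is(pseudo, "CropMask"), is(inferred, "CropMask"))
  m <- pixelValues(pseudo)
  mi <- pixelValues(inferred)
  stopDim(all(dim(m) == dim(mi)), "masks must have equal shapes")
  out <- matrix(as.integer(m), nrow(m), ncol(m))
  out[m != mi] <- NA_integer_
  Trimap(out)
}

#' Depth-derived per-pixel features for the toy backend
#'
#' Three channels on \[0, 1\]: scaled raw intensity, scaled row/column
#' normalized intensity, and a scaled 5x5 local mean.
#'
#' @param depth a \code{DepthMap}
#' @return H x W x 3 numeric array
#' @export
pixelFeatures <- function(depth) {
  stopifnot(is(depth, "DepthMap"))
  v <- pixelValues(depth)
  feats <- array(0, c(nrow(v), ncol(v), 3L))
  feats[, , 1] <- v / 255
  feats[, , 2] <- pixelValues(normalizeDepth(depth)) / 255
  feats[, , 3] <- boxMean(v, 2L) / 255
  feats
}

flattenSamples <- function(samples) {
  xs <- list(); ys <- list()
  for (s in samples) {
    f <- s$features
    lab <- pixelValues(s$label)
    npx <- length(lab)
    X <- matrix(f, npx, dim(f)[3])
    keep <- !is.na(as.vector(lab))
    xs[[length(xs) + 1L]] <- X[keep, , drop = FALSE]
    ys[[length(ys) + 1L]] <- as.vector(lab)[keep]
  }
  list(X = do.call(rbind, xs), y = do.call(c, ys))
}

#' @describeIn fitBackend full-batch logistic gradient descent on pooled
#'   pixels; trimap ignore pixels are excluded from the loss; \code{state}
#'   (a numeric coefficient vector) warm-starts the descent.
setMethod("fitBackend", "ToyPixelBackend",
  function(backend, samples, state = NULL, ...) {
    if (length(samples) == 0L)
      stop("at least one training sample is required", call. = FALSE)
    dat <- flattenSamples(samples)
    if (length(dat$y) == 0L)
      stop("no labeled pixels to train on", call. = FALSE)
    X <- cbind(1, dat$X)
    y <- dat$y
    w <- if (is.null(state)) numeric(ncol(X)) else {
      stopifnot(length(state) == ncol(X))
      state
    }
    n <- length(y)
    lr <- backend@learningRate
    for (ep in seq_len(backend@epochs)) {
      eta <- as.vector(X %*% w)
      mu <- 1 / (1 + exp(-eta))
      grad <- as.vector(crossprod(X, mu - y)) / n
      w <- w - lr * grad
    }
    w
  })

#' @describeIn predictBackend thresholds the logistic score at 0.5
#'   (equivalently the linear predictor at 0).
setMethod("predictBackend", "ToyPixelBackend",
  function(backend, state, features, ...) {
    h <- dim(features)[1]; wd <- dim(features)[2]
    X <- cbind(1, matrix(features, h * wd, dim(features)[3]))
    eta <- matrix(as.vector(X %*% state), h, wd)
    CropMask((eta > 0) * 1L)
  })

#' Two-stage self-training
#'
#' Stage one fits the backend on the pseudo masks. Each training sample is
#' then re-predicted by the stage-one model, a trimap is formed from the
#' disagreement with the pseudo mask (\code{\link{makeTrimap}}), and stage
#' two refits on the trimaps — ignore pixels excluded from the loss —
#' warm-started from the stage-one state. Backends must support the warm
#' start; the orchestration requires it.
#'
#' @param backend a \code{\linkS4class{SegmentationBackend}}
#' @param samples list of samples, each \code{list(features =, label =)}
#'   with \code{label} a pseudo \code{CropMask}
#' @param groundTruth optional list of ground-truth \code{CropMask}s; when
#'   supplied, per-stage pooled training mIoU is reported
#' @return a list with \code{stage1}, \code{stage2} (backend states),
#'   \code{trimaps}, \code{stage1Masks}, \code{stage2Masks}, and
#'   \code{report} (per-sample ignore fraction; stage mIoU when ground
#'   truth is available)
#' @examples
#' sc <- generateScene(sceneSpec(seed = 5))
#' smp <- list(list(features = pixelFeatures(sc$depth), label = sc$mask))
#' fit <- twoStageTrain(toyPixelBackend(epochs = 50L), smp,
#'                      groundTruth = list(sc$mask))
#' fit$report$ignoreFraction
#' @export
twoStageTrain <- function(backend, samples, groundTruth = NULL) {
  stopifnot(is(backend, "SegmentationBackend"))
  if (!is.list(samples) || length(samples) == 0L)
    stop("samples must be a non-empty list", call. = FALSE)
  stage1 <- fitBackend(backend, samples)
  stage1Masks <- lapply(samples, function(s)
    predictBackend(backend, stage1, s$features))
  trimaps <- mapply(function(s, mhat) makeTrimap(s$label, mhat),
                    samples, stage1Masks, SIMPLIFY = FALSE)
  samples2 <- mapply(function(s, tri) list(features = s$features, label = tri),
                     samples, trimaps, SIMPLIFY = FALSE)
  stage2 <- fitBackend(backend, samples2, state = stage1)
  stage2Masks <- lapply(samples, function(s)
    predictBackend(backend, stage2, s$features))
  report <- list(
    ignoreFraction = vapply(trimaps, function(tr)
      mean(is.na(pixelValues(tr))), numeric(1)))
  if (!is.null(groundTruth)) {
    report$stage1MIoU <- miou(stage1Masks, groundTruth)@miou
    report$stage2MIoU <- miou(stage2Masks, groundTruth)@miou
  }
  list(stage1 = stage1, stage2 = stage2, trimaps = trimaps,
       stage1Masks = stage1Masks, stage2Masks = stage2Masks,
       report = report)
}
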