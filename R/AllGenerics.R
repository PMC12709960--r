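#' Train a segmentation backend
#'
#' Fits the backend on a list of samples, each a list with elements
#' \code{features} (H x W x F numeric array) and \code{label} (a
#' \code{CropMask} or \code{Trimap}; trimap ignore pixels are excluded from
#' the loss). \code{state} supplies a warm start from a previous fit.
#'
#' @param backend a \code{\linkS4class{SegmentationBackend}}
#' @param samples list of list(features=, label=)
#' @param state optional prior state to warm-start from
#' @param ... backend-specific arguments
#' @return an opaque, serializable state object
#' @export
setGeneric("fitBackend", function(backend, samples, state = NULL, ...)
  standardGeneric("fitBackend"))

#' Predict a crop mask from features
#'
#' @param backend a \code{\linkS4class{SegmentationBackend}}
#' @param state a state returned by \code{\link{fitBackend}}
#' @param features H x W x F numeric array
#' @param ... backend-specific arguments
#' @return a \code{\linkS4class{CropMask}}
#' @export
setGeneric("predictBackend", function(backend, state, features, ...)
  standardGeneric("predictBackend"))

#' Matrix of pixel values underlying an image-grid object
#'
#' @param x a \code{DepthMap}, \code{CropMask} or \code{Trimap}
#' @return the underlying base matrix
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))

#' @rdname pixelValues
setMethod("pixelValues", "DepthMap", function(x) x@.Data)
#' @rdname pixelValues
setMethod("pixelValues", "CropMask", function(x) x@.Data)
#' @rdname pixelValues
setMethod("pixelValues", "Trimap", function(x) x@.Data)
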