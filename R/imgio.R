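# On-disk conventions: depth maps, masks and trimaps are 8-bit grayscale
# PNG/TIFF; masks encode foreground as 255, trimaps encode ignore as 128.
# Depth may also come as a delimited numeric text matrix (CSV/TSV), in which
# case non-8-bit values are min-max rescaled onto [0, 255].

fileExt <- function(path) tolower(tools::file_ext(path))

readGrayArray <- function(path) {
  ext <- fileExt(path)
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(a)) == 3L)
    stop("expected a single-channel image, got ", dim(a)[3], " channels",
         call. = FALSE)
  a * 255
}

#' Read a depth map
#'
#' Accepts 8-bit grayscale PNG/TIFF (decoded verbatim onto \[0, 255\]) or a
#' delimited numeric text matrix (.csv/.tsv/.txt). Text input whose values
#' are already 8-bit codes (whole numbers within \[0, 255\]) is taken
#' verbatim; any other numeric input is min-max rescaled onto \[0, 255\]
#' per image — relative monocular depth has no global calibration, so only
#' the per-image ordering is meaningful. A constant floating input maps to
#' all zeros.
#'
#' @param path file path
#' @return a \code{\linkS4class{DepthMap}}
#' @examples
#' d <- generateScene(sceneSpec(seed = 7))$depth
#' f <- tempfile(fileext = ".png")
#' writeDepth(d, f)
#' d2 <- readDepth(f)
#' @export
readDepth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- fileExt(path)
  if (ext %in% c("png", "tif", "tiff")) {
    v <- readGrayArray(path)
  } else if (ext %in% c("csv", "tsv", "txt", "dat")) {
    sep <- if (ext == "csv") "," else ""
    v <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    dimnames(v) <- NULL
    if (!is.numeric(v) || !all(is.finite(v)))
      stop("depth text matrix must be finite numeric", call. = FALSE)
    eightBit <- all(v >= 0 & v <= 255 & v == round(v))
    if (!eightBit) {
      rng <- range(v)
      v <- if (rng[1] == rng[2]) v * 0 else (v - rng[1]) / diff(rng) * 255
    }
  } else {
    stop("unsupported depth format: .", ext, call. = FALSE)
  }
  DepthMap(v)
}

#' Write a depth map as 8-bit grayscale PNG
#' @param depth a \code{DepthMap}
#' @param path output path (.png)
#' @return \code{path}, invisibly
#' @export
writeDepth <- function(depth, path) {
  stopifnot(is(depth, "DepthMap"))
  png::writePNG(roundHalfUp(pixelValues(depth)) / 255, path)
  invisible(path)
}

#' Read / write binary crop masks
#'
#' On disk a mask is an 8-bit grayscale PNG/TIFF over \{0, 255\}; in memory
#' it is a \code{\linkS4class{CropMask}} over \{0, 1\}. Reading rejects any
#' other pixel value, and write-then-read is the identity.
#'
#' @param path file path
#' @return \code{readMask}: a \code{CropMask}
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- roundHalfUp(readGrayArray(path))
  bad <- setdiff(unique(as.vector(v)), c(0, 255))
  if (length(bad))
    stop("mask pixels must be 0 or 255; found ", paste(bad, collapse = ", "),
         call. = FALSE)
  CropMask((v == 255) * 1L)
}

#' @rdname readMask
#' @param mask a \code{CropMask}
#' @return \code{writeMask}: \code{path}, invisibly
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "CropMask"))
  png::writePNG(pixelValues(mask) * 1.0, path)
  invisible(path)
}

#' Read / write trimaps
#'
#' Serialization is 0 (background), 255 (crop), 128 (ignore); in memory the
#' ignore pixels are \code{NA}. Any other on-disk value is rejected.
#'
#' @param path file path
#' @return \code{readTrimap}: a \code{\linkS4class{Trimap}}
#' @export
readTrimap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- roundHalfUp(readGrayArray(path))
  bad <- setdiff(unique(as.vector(v)), c(0, 128, 255))
  if (length(bad))
    stop("trimap pixels must be 0, 128 or 255; found ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- matrix(NA_integer_, nrow(v), ncol(v))
  out[v == 0] <- 0L
  out[v == 255] <- 1L
  Trimap(out)
}

#' @rdname readTrimap
#' @param trimap a \code{Trimap}
#' @return \code{writeTrimap}: \code{path}, invisibly
#' @export
writeTrimap <- function(trimap, path) {
  stopifnot(is(trimap, "Trimap"))
  v <- pixelValues(trimap)
  enc <- matrix(IGNORE_LABEL / 255, nrow(v), ncol(v))
  enc[!is.na(v) & v == 0] <- 0
  enc[!is.na(v) & v == 1] <- 1
  png::writePNG(enc, path)
  invisible(path)
}

#' Read / write RGB images
#' @param path file path
#' @return \code{readRGB}: an H x W x 3 numeric array on \[0, 255\]
#' @export
readRGB <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  a <- switch(fileExt(path),
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = stop("JPEG input not supported in this build; use PNG",
                call. = FALSE),
    stop("unsupported RGB format", call. = FALSE))
  if (length(dim(a)) != 3L || dim(a)[3] < 3L)
    stop("expected a 3-channel RGB image", call. = FALSE)
  a[, , 1:3, drop = FALSE] * 255
}

#' @rdname readRGB
#' @param rgb H x W x 3 array on \[0, 255\]
#' @return \code{writeRGB}: \code{path}, invisibly
#' @export
writeRGB <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  png::writePNG(clip(rgb, 0, 255) / 255, path)
  invisible(path)
}

#' Blend a mask over an RGB image for visual screening
#'
#' Highlights mask foreground by convex combination with a highlight color:
#' on crop pixels the output is \code{(1 - alpha) * rgb + alpha * highlight};
#' background pixels pass through unchanged. Overlays of this kind support
#' rapid visual screening of pseudo-mask quality.
#'
#' @param rgb H x W x 3 array on \[0, 255\]
#' @param mask a \code{CropMask} of matching size
#' @param alpha blend weight in \[0, 1\]
#' @param highlight length-3 highlight color, default pure green
#' @return H x W x 3 array on \[0, 255\]
#' @export
blendOverlay <- function(rgb, mask, alpha = 0.5, highlight = c(0, 255, 0)) {
  stopifnot(is(mask, "CropMask"), alpha >= 0, alpha <= 1)
  m <- pixelValues(mask)
  stopDim(length(dim(rgb)) == 3L && all(dim(rgb)[1:2] == dim(m)) &&
            dim(rgb)[3] == 3L, "rgb and mask shapes must agree")
  out <- rgb
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[m == 1] <- (1 - alpha) * plane[m == 1] + alpha * highlight[ch]
    out[, , ch] <- plane
  }
  clip(out, 0, 255)
}

## ---- dataset manifests -------------------------------------------------

manifestScenarios <- c("in-field", "lab", "uav")

#' Read / write dataset manifests
#'
#' A manifest is a table with columns \code{id}, \code{depth}, \code{rgb},
#' \code{mask}, \code{scenario} (CSV, or an equivalent JSON array of
#' records). Relative paths are resolved against the manifest's directory.
#' Sample ids must be unique; referenced files must exist when
#' \code{checkFiles} is \code{TRUE}. The scenario tag (\code{in-field},
#' \code{lab}, \code{uav}) gates depth normalization downstream: sloped
#' backgrounds occur in field and UAV imagery, not on lab tables.
#'
#' @param path manifest path (.csv or .json)
#' @param checkFiles verify that referenced files exist
#' @return \code{readManifest}: a data.frame with absolute paths
#' @export
readManifest <- function(path, checkFiles = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (fileExt(path) == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("id", "depth")
  if (!all(need %in% names(df)))
    stop("manifest must have at least columns id, depth", call. = FALSE)
  for (col in c("rgb", "mask", "scenario"))
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
  df <- df[, c("id", "depth", "rgb", "mask", "scenario")]
  for (col in c("id", "depth", "rgb", "mask", "scenario"))
    df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$id))
    stop("manifest sample ids must be unique", call. = FALSE)
  known <- is.na(df$scenario) | df$scenario %in% manifestScenarios
  if (!all(known))
    stop("unknown scenario tag(s): ",
         paste(unique(df$scenario[!known]), collapse = ", "), call. = FALSE)
  base <- dirname(normalizePath(path))
  abs <- function(p) {
    rel <- !is.na(p) & p != "" & !grepl("^(/|[A-Za-z]:)", p)
    p[rel] <- file.path(base, p[rel])
    p
  }
  for (col in c("depth", "rgb", "mask")) df[[col]] <- abs(df[[col]])
  if (checkFiles) {
    for (col in c("depth", "rgb", "mask")) {
      p <- df[[col]]
      p <- p[!is.na(p) & p != ""]
      miss <- p[!file.exists(p)]
      if (length(miss))
        stop("manifest references missing file(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' @rdname readManifest
#' @param manifest data.frame with columns id, depth, rgb, mask, scenario
#' @return \code{writeManifest}: \code{path}, invisibly
#' @export
writeManifest <- function(manifest, path) {
  if (fileExt(path) == "json") {
    jsonlite::write_json(manifest, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.csv(manifest, path, row.names = FALSE)
  }
  invisible(path)
}
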