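# Seeded synthetic top-down crop scenes. The generator emulates the one
# property of monocular depth output that the thresholding pipeline relies
# on: crop canopies sit on a raised depth plane above the ground, and the
# ground itself may carry a separable (per-row plus per-column) additive
# bias, the failure mode of plain histogram thresholding on in-field scenes.

blobProfile <- function(d, radius, shoulder, rim) {
  inner <- radius - shoulder
  out <- numeric(length(d))
  out[d <= inner] <- 1
  sh <- d > inner & d <= radius
  out[sh] <- rim + (1 - rim) * 0.5 * (1 + cos(pi * (d[sh] - inner) / shoulder))
  out
}

placeBlobs <- function(spec) {
  h <- spec@height; w <- spec@width
  rmin <- spec@radiusRange[1]; rmax <- spec@radiusRange[2]
  height <- matrix(0, h, w)
  support <- matrix(FALSE, h, w)
  addBlob <- function() {
    r <- stats::runif(1, rmin, rmax)
    ci <- stats::runif(1, r + 1, h - r)
    cj <- stats::runif(1, r + 1, w - r)
    i0 <- max(1L, floor(ci - r)); i1 <- min(h, ceiling(ci + r))
    j0 <- max(1L, floor(cj - r)); j1 <- min(w, ceiling(cj + r))
    ii <- i0:i1; jj <- j0:j1
    d <- sqrt(outer((ii - ci)^2, (jj - cj)^2, "+"))
    prof <- matrix(blobProfile(as.vector(d), r, min(spec@shoulder, r - 1),
                               spec@rimHeight), length(ii), length(jj))
    height[ii, jj] <<- pmax(height[ii, jj], prof)
    support[ii, jj] <<- support[ii, jj] | (d <= r)
  }
  if (is.na(spec@coverage)) {
    for (k in seq_len(spec@nBlobs)) addBlob()
  } else {
    # iterate blob placement until the crop fraction lands in the +-0.05
    # band around the target; restart the layout when a blob overshoots
    target <- spec@coverage
    npix <- h * w
    done <- FALSE
    for (attempt in 1:50) {
      height[] <- 0; support[] <- FALSE
      for (k in 1:1000) {
        addBlob()
        if (sum(support) / npix >= target - 0.05) break
      }
      if (abs(sum(support) / npix - target) <= 0.05) { done <- TRUE; break }
    }
    if (!done)
      stop("could not satisfy coverage target within tolerance", call. = FALSE)
  }
  list(height = height, support = support)
}

#' Generate a synthetic crop scene
#'
#' Builds a depth map, its ground-truth crop mask, and a cosmetic RGB
#' rendering from a \code{\linkS4class{SceneSpec}}. The depth model is
#' \deqn{D(i,j) = clip(bg + \beta_r i + \beta_c j + \Delta\,h(i,j) +
#' \epsilon_{ij},\ 0,\ 255)} with h the blob height profile (1 on plateaus,
#' a cosine shoulder down to the rim fraction at the support edge, 0
#' outside) and Gaussian noise \eqn{\epsilon}. The ground-truth mask is the
#' union of blob supports. Identical specs (including seed) give
#' bit-identical scenes; the generator never touches global RNG state.
#'
#' @param spec a \code{SceneSpec}
#' @return list with elements \code{depth} (\code{DepthMap}), \code{mask}
#'   (ground-truth \code{CropMask}), \code{rgb} (H x W x 3 array on
#'   \[0,255\]) and \code{coverage} (crop fraction)
#' @examples
#' sc <- generateScene(sceneSpec(nBlobs = 4, seed = 42))
#' sc$coverage
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    h <- spec@height; w <- spec@width
    blobs <- placeBlobs(spec)
    bias <- outer(spec@rowBias * (seq_len(h) - 1L),
                  spec@colBias * (seq_len(w) - 1L), "+")
    depth <- spec@background + bias + spec@blobHeight * blobs$height
    if (spec@noiseSd > 0)
      depth <- depth + matrix(stats::rnorm(h * w, 0, spec@noiseSd), h, w)
    depth <- clip(depth, 0, 255)
    mask <- blobs$support * 1L
    # cosmetic rendering: brownish soil, greenish canopy, depth shading
    shade <- 0.75 + 0.25 * blobs$height
    rgb <- array(0, c(h, w, 3))
    soil <- c(131, 101, 57); canopy <- c(58, 148, 63)
    for (ch in 1:3)
      rgb[, , ch] <- ifelse(mask == 1, canopy[ch] * shade, soil[ch]) +
        matrix(stats::rnorm(h * w, 0, 4), h, w)
    list(depth = DepthMap(depth), mask = CropMask(mask),
         rgb = clip(rgb, 0, 255), coverage = mean(mask == 1))
  })
}

#' Generate a batch of scenes and write them to disk
#'
#' Scene \code{k} uses seed \code{baseSeed + k - 1}. Writes
#' \code{depth_k.png}, \code{mask_k.png}, \code{rgb_k.png} and a
#' \code{manifest.csv} under \code{outdir}.
#'
#' @param spec template \code{SceneSpec} (its seed field is overridden)
#' @param n number of scenes (>= 1)
#' @param baseSeed integer base seed
#' @param outdir output directory, created if needed
#' @param scenario scenario tag recorded in the manifest
#' @param writeRgb also write the RGB renderings
#' @return list with \code{manifest} (data.frame), \code{manifestPath} and
#'   \code{scenes} (list of in-memory scenes)
#' @export
generateBatch <- function(spec, n, baseSeed = spec@seed, outdir,
                          scenario = "in-field", writeRgb = TRUE) {
  stopifnot(is(spec, "SceneSpec"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  rows <- vector("list", n)
  scenes <- vector("list", n)
  for (k in seq_len(n)) {
    sk <- spec
    sk@seed <- as.integer(baseSeed + k - 1L)
    sc <- generateScene(sk)
    id <- sprintf("scene_%03d", k)
    dp <- file.path(outdir, paste0("depth_", k, ".png"))
    mp <- file.path(outdir, paste0("mask_", k, ".png"))
    rp <- if (writeRgb) file.path(outdir, paste0("rgb_", k, ".png"))
          else NA_character_
    writeDepth(sc$depth, dp)
    writeMask(sc$mask, mp)
    if (writeRgb) writeRGB(sc$rgb, rp)
    rows[[k]] <- data.frame(id = id, depth = basename(dp),
                            rgb = if (writeRgb) basename(rp) else NA,
                            mask = basename(mp), scenario = scenario,
                            stringsAsFactors = FALSE)
    scenes[[k]] <- sc
  }
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(outdir, "manifest.csv")
  writeManifest(manifest, manifestPath)
  list(manifest = manifest, manifestPath = manifestPath, scenes = scenes)
}
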