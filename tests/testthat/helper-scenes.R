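# Canonical study conditions for simulation-backed tests.
# Unbiased: flat background, strong crop contrast -- classic thresholding
# succeeds here. Biased: separable background drop-off larger than the crop
# contrast -- the failure mode of plain histogram thresholding that the
# gradient-guided method is built for.

unbiasedSpec <- function(seed) sceneSpec(seed = seed)

biasedSpec <- function(seed)
  sceneSpec(background = 5, rowBias = 1.0, colBias = 0.3, blobHeight = 60,
            seed = seed)

# seeded label corruption without polluting the caller's RNG state
flipMask <- function(mask, frac, seed) {
  v <- pixelValues(mask)
  depthseg:::withSeed(seed, {
    idx <- sample(length(v), round(frac * length(v)))
    v[idx] <- 1L - v[idx]
  })
  CropMask(v)
}

# foreground (crop-class) IoU of a single mask pair
fgIoU <- function(pred, gt) {
  p <- pixelValues(pred); g <- pixelValues(gt)
  sum(p == 1 & g == 1) / sum(p == 1 | g == 1)
}
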