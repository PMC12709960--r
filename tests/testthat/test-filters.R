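test_that("guided filter degenerates to a double box mean", {
  depthseg:::withSeed(31, {
    inp <- matrix(runif(30 * 25), 30, 25)
    gRand <- matrix(runif(30 * 25) * 255, 30, 25)
  })
  r <- 3
  ref <- doubleBoxMean(inp, r)

  # constant guidance, any value
  q <- guidedFilter(inp, matrix(42, 30, 25), guidedFilterParams(r, 1e-3))
  expect_lt(max(abs(q - ref)), 1e-6)

  # eps -> Inf limit under arbitrary guidance
  q2 <- guidedFilter(inp, gRand, guidedFilterParams(r, 1e12))
  expect_lt(max(abs(q2 - ref)), 1e-6)

  # constants are preserved under any guidance
  q3 <- guidedFilter(matrix(0.4, 30, 25), gRand, guidedFilterParams(r, 1e-3))
  expect_lt(max(abs(q3 - 0.4)), 1e-9)

  expect_error(guidedFilter(inp, matrix(1, 5, 5)), "dimension")
})

test_that("joint bilateral filter reduces to spatial Gaussian smoothing", {
  depthseg:::withSeed(32, {
    inp <- matrix(runif(24 * 20), 24, 20)
    g <- matrix(runif(24 * 20) * 255, 24, 20)
  })
  q <- jointBilateralFilter(inp, g,
                            jointBilateralParams(d = 9, sigmaColor = 1e6,
                                                 sigmaSpace = 3))
  ref <- spatialGaussian(inp, 4, 3)
  expect_lt(max(abs(q - ref)), 1e-6)

  # constant input passes through any guidance
  qc <- jointBilateralFilter(matrix(0.7, 24, 20), g, jointBilateralParams())
  expect_lt(max(abs(qc - 0.7)), 1e-12)

  expect_error(jointBilateralFilter(inp, matrix(1, 3, 3)), "dimension")
})

test_that("both filters keep [0,1] inputs within [0,1]", {
  depthseg:::withSeed(33, {
    for (rep in 1:5) {
      inp <- matrix(rbinom(400, 1, 0.3), 20, 20) * 1.0
      g <- matrix(runif(400) * 255, 20, 20)
      q1 <- guidedFilter(inp, g, guidedFilterParams(r = 2, eps = 0.1))
      q2 <- jointBilateralFilter(inp, g, jointBilateralParams(d = 7))
      expect_gte(min(q1), -1e-6); expect_lte(max(q1), 1 + 1e-6)
      expect_gte(min(q2), -1e-12); expect_lte(max(q2), 1 + 1e-12)
    }
  })
})

test_that("smoothing does not cross a guidance step", {
  g <- matrix(0, 20, 20); g[, 11:20] <- 200
  depthseg:::withSeed(34, {
    inp <- matrix(0.2, 20, 20); inp[, 11:20] <- 0.8
    inp <- inp + matrix(rnorm(400, 0, 0.05), 20, 20)
  })
  q <- jointBilateralFilter(inp, g, jointBilateralParams(d = 9,
                                                         sigmaColor = 25,
                                                         sigmaSpace = 5))
  stepIn <- mean(inp[, 11]) - mean(inp[, 10])
  stepOut <- mean(q[, 11]) - mean(q[, 10])
  expect_gt(stepOut, 0.9 * stepIn)
})

test_that("refinement removes speckles but preserves depth-aligned regions", {
  # isolated speckles on a flat-depth background vanish
  m <- matrix(0L, 30, 30)
  m[cbind(c(5, 12, 22, 27), c(7, 20, 4, 25))] <- 1L
  flat <- DepthMap(matrix(50, 30, 30))
  ref <- refineMask(CropMask(m), flat, "jbf")
  expect_true(all(pixelValues(ref) == 0))
  refGf <- refineMask(CropMask(m), flat, "gf", guidedFilterParams(r = 3))
  expect_true(all(pixelValues(refGf) == 0))

  # a solid rectangle aligned with a depth step survives
  rect <- matrix(0L, 40, 40); rect[10:30, 10:30] <- 1L
  d <- matrix(20, 40, 40); d[10:30, 10:30] <- 150
  out <- refineMask(CropMask(rect), DepthMap(d), "jbf")
  expect_gte(fgIoU(out, CropMask(rect)), 0.99)
})

test_that("repeated refinement is stable", {
  sc <- generateScene(unbiasedSpec(44))
  noisy <- flipMask(sc$mask, 0.05, 123)
  r1 <- refineMask(noisy, sc$depth, "jbf")
  r2 <- refineMask(r1, sc$depth, "jbf")
  change1 <- sum(pixelValues(r1) != pixelValues(noisy))
  change2 <- sum(pixelValues(r2) != pixelValues(r1))
  expect_lte(change2, change1)
})
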