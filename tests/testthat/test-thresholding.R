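test_that("histogram counts rounded intensities with half-up binning", {
  h <- depthHistogram(DepthMap(rbind(c(0, 0, 5), c(255, 255, 5),
                                     c(10.4, 10.6, 5))))
  expect_equal(sum(h), 9)
  expect_equal(h[0 + 1], 2)
  expect_equal(h[255 + 1], 2)
  expect_equal(h[10 + 1], 1)  # 10.4 rounds down
  expect_equal(h[11 + 1], 1)  # 10.6 rounds up
  expect_equal(h[5 + 1], 3)
  # constant map: a single populated bin
  expect_equal(sum(depthHistogram(DepthMap(matrix(9, 4, 4))) > 0), 1)
})

test_that("otsu matches an exhaustive between-class-variance scan", {
  h <- numeric(256); h[10 + 1] <- 60; h[200 + 1] <- 40
  expect_equal(otsuThreshold(h), 10L)  # smallest maximizer on the tie range

  depthseg:::withSeed(101, {
    for (rep in 1:40) {
      h <- randomHistogram()
      t <- otsuThreshold(h)
      oracle <- otsuBruteForce(h)
      agree <- t == oracle$threshold ||
        abs(otsuObjectiveAt(h, t) - oracle$value) < 1e-9 * max(1, oracle$value)
      expect_true(agree)
    }
  })

  expect_error(otsuThreshold(numeric(256) + c(rep(0, 255), 5)), "degenerate")
})

test_that("ght agrees with a straight-from-formula scan and its limits", {
  # bimodal histogram: threshold lies strictly between the modes
  depthseg:::withSeed(202, {
    h <- randomBimodalHistogram()
  })
  t <- ghtThreshold(h, ghtParams())
  expect_gt(t, 20); expect_lt(t, 240)

  depthseg:::withSeed(303, {
    for (rep in 1:15) {
      h <- randomBimodalHistogram()
      pars <- ghtParams(nu = runif(1, 0, 50), tau = runif(1, 0, 10),
                        kappa = runif(1, 0, 5), omega = runif(1))
      expect_equal(ghtThreshold(h, pars),
                   ghtBruteForce(h, pars@nu, pars@tau, pars@kappa,
                                 pars@omega)$threshold)
    }
  })

  # mirror symmetry: reversing the histogram mirrors the objective
  depthseg:::withSeed(404, { h <- randomBimodalHistogram() })
  pars <- ghtParams(nu = 5, tau = 2, kappa = 1, omega = 0.5)
  obj <- depthseg:::ghtObjective(h, pars)
  objRev <- depthseg:::ghtObjective(rev(h), pars)
  expect_equal(objRev, rev(obj), tolerance = 1e-9)

  # Otsu-recovering corner of the family: nu large, tau small, kappa 0
  otsuLimit <- ghtParams(nu = 1e18, tau = 1e-2, kappa = 0)
  depthseg:::withSeed(505, {
    for (rep in 1:20) {
      h <- randomHistogram()
      expect_equal(ghtThreshold(h, otsuLimit), otsuThreshold(h))
    }
  })

  expect_error(ghtThreshold(numeric(256)), "histogram")
})

test_that("binarization is strictly-greater with crop as the high class", {
  d <- DepthMap(rbind(c(10, 200, 10), c(10, 10, 10), c(10, 10, 10)))
  expect_equal(pixelValues(applyThreshold(d, 10)),
               rbind(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0)))
  expect_true(all(pixelValues(applyThreshold(d, 255)) == 0))
  expect_true(all(pixelValues(applyThreshold(DepthMap(matrix(1, 3, 3)), 0)) == 1))
})

test_that("row/column normalization removes separable bias exactly", {
  expect_true(all(pixelValues(normalizeDepth(DepthMap(matrix(9, 4, 4)))) == 0))

  # hand-derived: rows minus minima (1,3,0), then columns minus (0,0,2)
  d <- DepthMap(rbind(c(1, 2, 5), c(3, 4, 5), c(0, 1, 7)))
  expect_equal(pixelValues(normalizeDepth(d)),
               rbind(c(0, 0, 2), c(0, 0, 0), c(0, 0, 5)))

  # pure separable ramp -> exact zeros; idempotence on a structured map
  i <- 0:19; j <- 0:29
  ramp <- DepthMap(outer(50 + 0.3 * i, 0.2 * j, "+"))
  expect_equal(max(abs(pixelValues(normalizeDepth(ramp)))), 0)

  sc <- generateScene(biasedSpec(8))
  n1 <- normalizeDepth(sc$depth)
  n2 <- normalizeDepth(n1)
  expect_equal(pixelValues(n1), pixelValues(n2), tolerance = 1e-12)
  expect_true(min(pixelValues(n1)) >= 0)
})

test_that("weighted histogram cumulates edge mass into a monotone S", {
  # one edge pixel at intensity 50, unit weight
  d <- matrix(0, 5, 5); d[3, 3] <- 50
  E <- matrix(0L, 5, 5); E[3, 3] <- 1L
  L <- matrix(0L, 5, 5)
  wh <- weightedHistogram(d, L, E, gamma = c(1, 0))
  expect_equal(which(wh@R > 0), 50 + 1)
  expect_true(all(wh@S[1:50] == 0))
  expect_true(all(wh@S[51:256] == 255))

  # two equal-weight edge pixels at 50 and 150: plateaus 0 / 127.5 / 255
  d[2, 2] <- 150; E[2, 2] <- 1L
  wh2 <- weightedHistogram(d, L, E, gamma = c(1, 0))
  expect_equal(unique(wh2@S), c(0, 127.5, 255))
  expect_equal(wh2@S[256], 255)
  expect_true(all(diff(wh2@S) >= 0))

  expect_error(weightedHistogram(d, L, matrix(0L, 5, 5), c(1, 0)),
               "degenerate|zero")
})

test_that("sigmoid fitting recovers the midpoint across the parameter grid", {
  Tseq <- 0:255
  # self-consistency at the documented initialization scale
  S <- 255 / (1 + exp(-0.1 * (Tseq - 100)))
  fit <- fitSigmoid(S)
  expect_lt(abs(fit@a - 0.1), 0.01)
  expect_lt(abs(fit@b - 100), 0.5)

  for (a in c(0.05, 0.5, 2)) {
    for (b in c(40, 128, 200)) {
      S <- 255 / (1 + exp(-a * (Tseq - b)))
      expect_lte(abs(fitSigmoid(S)@b - b), 1)
    }
  }
})

test_that("the threshold sits at the sigmoid midpoint, clamped", {
  mkFit <- function(b) new("SigmoidFit", a = 1, b = b, c = 255, residual = 0)
  expect_equal(thresholdFromFit(mkFit(100)), 100L)
  expect_equal(thresholdFromFit(mkFit(255)), 255L)
  expect_equal(thresholdFromFit(mkFit(0)), 0L)
  expect_equal(thresholdFromFit(mkFit(127.6)), 128L)
})

test_that("pseudo-mask generation recovers unbiased scenes and is deterministic", {
  sc <- generateScene(unbiasedSpec(21))
  res <- generatePseudoMask(sc$depth, "ggt")
  expect_null(res$fallback)
  expect_gte(fgIoU(res$mask, sc$mask), 0.9)
  # bit-identical reruns
  res2 <- generatePseudoMask(sc$depth, "ggt")
  expect_identical(pixelValues(res$mask), pixelValues(res2$mask))
  # diagnostics bundle carries every intermediate stage
  expect_named(res$diagnostics, c("Dn", "G", "E", "Mt", "wh", "fit", "Dt"))

  resO <- generatePseudoMask(sc$depth, "otsu")
  expect_gte(fgIoU(resO$mask, sc$mask), 0.95)
  resG <- generatePseudoMask(sc$depth, "ght")
  expect_gte(fgIoU(resG$mask, sc$mask), 0.9)
})

test_that("degenerate ggt stages fall back to otsu with a named flag", {
  # gentle two-level map: no Canny edge survives the hysteresis floor,
  # but otsu still splits the two populations
  v <- matrix(40, 32, 32); v[, 17:32] <- 44
  res <- generatePseudoMask(DepthMap(v), "ggt",
                            cfg = ggtConfig(applyNormalization = FALSE))
  expect_false(is.null(res$fallback))
  expect_equal(res$fallback, "no-edges")
  expect_equal(res$threshold, otsuThreshold(depthHistogram(DepthMap(v))))

  # constant map: no gradient at all, and otsu itself is degenerate
  expect_error(generatePseudoMask(DepthMap(matrix(7, 16, 16)), "ggt"),
               "degenerate")
})
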