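test_that("depth maps round-trip through 8-bit PNG and rescale float input", {
  d <- DepthMap(matrix(sample(0:255, 400, replace = TRUE), 20, 20))
  f <- tempfile(fileext = ".png")
  writeDepth(d, f)
  expect_equal(pixelValues(readDepth(f)), pixelValues(d))

  # float text input spanning [0, 1] stretches onto [0, 255]
  ftxt <- tempfile(fileext = ".csv")
  m <- matrix(seq(0, 1, length.out = 25), 5, 5)
  write.table(m, ftxt, sep = ",", row.names = FALSE, col.names = FALSE)
  got <- pixelValues(readDepth(ftxt))
  expect_equal(range(got), c(0, 255))
  expect_equal(got, (m - min(m)) / diff(range(m)) * 255, tolerance = 1e-12)

  # constant float input maps to zeros
  write.table(matrix(0.37, 5, 5), ftxt, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_true(all(pixelValues(readDepth(ftxt)) == 0))

  # 8-bit text codes pass verbatim
  write.table(matrix(c(3, 7, 250, 0, 1, 2, 9, 8, 7), 3, 3), ftxt, sep = ",",
              row.names = FALSE, col.names = FALSE)
  expect_equal(sort(unique(as.vector(pixelValues(readDepth(ftxt))))),
               c(0, 1, 2, 3, 7, 8, 9, 250))
})

test_that("multi-channel input is rejected as a depth map", {
  f <- tempfile(fileext = ".png")
  png::writePNG(array(runif(60), c(5, 4, 3)), f)
  expect_error(readDepth(f), "channel")
  expect_error(readDepth(tempfile(fileext = ".png")), "not found")
})

test_that("masks round-trip as 0/255 PNG and reject other codes", {
  m <- CropMask(rbind(c(1, 0), c(0, 1)))
  f <- tempfile(fileext = ".png")
  writeMask(m, f)
  onDisk <- png::readPNG(f) * 255
  expect_equal(onDisk, rbind(c(255, 0), c(0, 255)))
  expect_equal(pixelValues(readMask(f)), pixelValues(m))

  zero <- CropMask(matrix(0, 4, 4))
  writeMask(zero, f)
  expect_equal(pixelValues(readMask(f)), pixelValues(zero))

  png::writePNG(matrix(37 / 255, 3, 3), f)
  expect_error(readMask(f), "37")
})

test_that("trimaps serialize ignore as 128 and round-trip", {
  tri <- Trimap(rbind(c(1L, NA), c(0L, 1L)))
  f <- tempfile(fileext = ".png")
  writeTrimap(tri, f)
  expect_equal(png::readPNG(f) * 255, rbind(c(255, 128), c(0, 255)))
  expect_equal(pixelValues(readTrimap(f)), pixelValues(tri))

  allIgnore <- Trimap(matrix(NA_integer_, 3, 3))
  writeTrimap(allIgnore, f)
  expect_true(all(is.na(pixelValues(readTrimap(f)))))

  png::writePNG(matrix(64 / 255, 3, 3), f)
  expect_error(readTrimap(f), "64")
})

test_that("overlay blending is the stated convex combination", {
  rgb <- array(255, c(2, 2, 3))
  mask <- CropMask(rbind(c(1, 0), c(0, 0)))

  expect_equal(blendOverlay(rgb, mask, alpha = 0), rgb)

  out1 <- blendOverlay(rgb, mask, alpha = 1)
  expect_equal(out1[1, 1, ], c(0, 255, 0))
  expect_equal(out1[1, 2, ], c(255, 255, 255))

  outHalf <- blendOverlay(rgb, mask, alpha = 0.5)
  expect_equal(outHalf[1, 1, ], c(127.5, 255, 127.5))

  expect_error(blendOverlay(array(0, c(3, 3, 3)), mask), "dimension")
})

test_that("manifests validate ids, scenarios and file existence", {
  dir <- tempfile(); dir.create(dir)
  writeMask(CropMask(matrix(0, 4, 4)), file.path(dir, "m.png"))
  writeDepth(DepthMap(matrix(10, 4, 4)), file.path(dir, "d.png"))
  man <- data.frame(id = c("a", "b"), depth = "d.png", rgb = NA,
                    mask = "m.png", scenario = c("lab", "uav"))
  p <- file.path(dir, "manifest.csv")
  writeManifest(man, p)
  got <- readManifest(p)
  expect_equal(got$id, c("a", "b"))
  expect_true(all(file.exists(got$depth)))

  man$id <- c("a", "a")
  writeManifest(man, p)
  expect_error(readManifest(p), "unique")

  man$id <- c("a", "b"); man$scenario <- c("lab", "orbit")
  writeManifest(man, p)
  expect_error(readManifest(p), "scenario")

  man$scenario <- "lab"; man$depth <- "missing.png"
  writeManifest(man, p)
  expect_error(readManifest(p), "missing")
})
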