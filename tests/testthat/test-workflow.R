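# End-to-end wiring of the workflow commands on small scenes.

smallSpec <- function(seed = 1L)
  sceneSpec(height = 64L, width = 64L, nBlobs = 3L, radiusRange = c(6, 10),
            seed = seed)

test_that("simulate -> pseudolabel -> evaluate chains through manifests", {
  simdir <- tempfile()
  man <- suppressMessages(runSimulate(smallSpec(), n = 3, baseSeed = 5,
                                      outdir = simdir, scenario = "in-field"))
  expect_true(file.exists(man))
  expect_true(file.exists(file.path(simdir, "config.json")))

  outdir <- tempfile()
  res <- suppressMessages(runPseudolabel(man, method = "otsu",
                                         outdir = outdir))
  expect_equal(nrow(res$table), 3L)
  expect_s4_class(res$report, "EvalReport")
  expect_gte(res$report@miou, 0.95)
  expect_true(file.exists(file.path(outdir, "report.json")))

  rep <- runEvaluate(res$manifestPath, man)
  expect_equal(rep@miou, res$report@miou, tolerance = 1e-12)
  expect_equal(rep@n, 3L)
})

test_that("scenario tags gate depth normalization", {
  simdir <- tempfile()
  man <- suppressMessages(runSimulate(smallSpec(), n = 1, baseSeed = 9,
                                      outdir = simdir, scenario = "lab"))
  outLab <- tempfile()
  # lab scenes skip normalization: the logged config should reflect it;
  # the forced override must win over the scenario
  suppressMessages(runPseudolabel(man, method = "ggt", outdir = outLab,
                                  normalizationOverride = TRUE))
  cfg <- jsonlite::fromJSON(file.path(outLab, "config.json"))
  expect_true(cfg$normalizationOverride)
})

test_that("filter sweep emits a parameter table and refined masks", {
  simdir <- tempfile()
  man <- suppressMessages(runSimulate(smallSpec(), n = 2, baseSeed = 21,
                                      outdir = simdir))
  pl <- suppressMessages(runPseudolabel(man, method = "otsu",
                                        outdir = tempfile()))
  fdir <- tempfile()
  sw <- suppressMessages(runFilterSweep(pl$manifestPath, filter = "jbf",
                                        values = c(5, 20),
                                        gtManifestPath = man, outdir = fdir))
  expect_equal(nrow(sw$sweep), 2L)
  expect_true(all(sw$sweep$miou >= 0 & sw$sweep$miou <= 1))
  expect_true(file.exists(file.path(fdir, "sweep.tsv")))
  expect_length(list.files(fdir, pattern = "^refined_.*png$"), 2L)
})

test_that("self-training over a manifest writes trimaps and a report", {
  simdir <- tempfile()
  man <- suppressMessages(runSimulate(smallSpec(), n = 2, baseSeed = 31,
                                      outdir = simdir))
  outdir <- tempfile()
  fit <- suppressMessages(runSelfTrain(man, toyPixelBackend(epochs = 80L),
                                       method = "otsu", outdir = outdir))
  expect_length(list.files(outdir, pattern = "^trimap_.*png$"), 2L)
  expect_true(file.exists(file.path(outdir, "report.json")))
  expect_true(!is.null(fit$report$stage1MIoU))
})

test_that("run configs load with validation and empty manifests error", {
  cfgPath <- tempfile(fileext = ".yaml")
  writeLines(c("method: ggt", "seed: 7", "ggt:", "  cannyLow: 40",
               "  cannyHigh: 110", "jbf:", "  d: 10"), cfgPath)
  cfg <- loadRunConfig(cfgPath)
  expect_equal(cfg$ggt@cannyLow, 40)
  expect_equal(cfg$jbf@d, 10L)
  expect_equal(cfg$seed, 7L)

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("ggt:", "  cannyLow: 200", "  cannyHigh: 100"), bad)
  expect_error(loadRunConfig(bad))

  emptyMan <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = character(0), depth = character(0)),
                   emptyMan, row.names = FALSE)
  expect_error(runPseudolabel(emptyMan, outdir = tempfile()), "empty")
})

test_that("the command-line wrapper runs the simulate subcommand", {
  script <- system.file("scripts", "depthseg.R", package = "depthseg")
  expect_true(nzchar(script))
  outdir <- tempfile()
  status <- system2("Rscript", c(script, "simulate", "--outdir", outdir,
                                 "--n", "1", "--seed", "3"),
                    stdout = FALSE, stderr = FALSE,
                    env = paste0("R_LIBS=",
                                 paste(.libPaths(), collapse = .Platform$path.sep)))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(outdir, "manifest.csv")))
})
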