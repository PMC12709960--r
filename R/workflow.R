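# Workflow commands binding the modules into the full pipeline:
# simulate -> pseudolabel -> (filter | selftrain) -> evaluate. Each command
# logs one structured line per record and writes the fully resolved
# configuration next to its outputs so any run can be reproduced from the
# output directory alone.

s4ToList <- function(x) {
  out <- lapply(slotNames(class(x)), function(s) slot(x, s))
  names(out) <- slotNames(class(x))
  out[!vapply(out, is.function, logical(1))]
}

writeEffectiveConfig <- function(outdir, config) {
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
}

ensureDir <- function(outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  outdir
}

#' Load a run configuration file
#'
#' YAML or JSON with optional blocks \code{ggt}, \code{ght}, \code{gf},
#' \code{jbf} overriding the shipped defaults, plus optional top-level
#' \code{method} and \code{seed}. Values are validated through the
#' parameter classes at load time.
#'
#' @param path configuration file (.yaml/.yml/.json)
#' @return list with elements \code{method}, \code{seed}, \code{ggt}
#'   (\code{GGTConfig}), \code{ght} (\code{GHTParams}), \code{gf}
#'   (\code{GuidedFilterParams}), \code{jbf} (\code{JointBilateralParams})
#' @export
loadRunConfig <- function(path) {
  raw <- if (fileExt(path) %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  build <- function(ctor, block) do.call(ctor, as.list(block %||% list()))
  list(method = raw$method %||% "ggt",
       seed = as.integer(raw$seed %||% 1L),
       ggt = build(ggtConfig, raw$ggt),
       ght = build(ghtParams, raw$ght),
       gf = build(guidedFilterParams, raw$gf),
       jbf = build(jointBilateralParams, raw$jbf))
}

#' Simulate a batch of synthetic scenes
#'
#' Wraps \code{\link{generateBatch}}; logs per-scene canopy coverage and
#' writes the resolved scene specification alongside the outputs.
#'
#' @param spec template \code{\linkS4class{SceneSpec}}
#' @param n number of scenes
#' @param baseSeed integer base seed (scene k uses baseSeed + k - 1)
#' @param outdir output directory
#' @param scenario manifest scenario tag
#' @return path of the written manifest, invisibly
#' @export
runSimulate <- function(spec = sceneSpec(), n = 10L, baseSeed = spec@seed,
                        outdir, scenario = "in-field") {
  ensureDir(outdir)
  batch <- generateBatch(spec, n, baseSeed, outdir, scenario = scenario)
  for (k in seq_len(n))
    message(sprintf("simulate %s coverage=%.3f", batch$manifest$id[k],
                    batch$scenes[[k]]$coverage))
  cfg <- s4ToList(spec)
  cfg$n <- n; cfg$baseSeed <- baseSeed; cfg$scenario <- scenario
  writeEffectiveConfig(outdir, cfg)
  invisible(batch$manifestPath)
}

scenarioNormalization <- function(scenario, cfg) {
  if (is.na(scenario)) cfg@applyNormalization
  else scenario %in% c("in-field", "uav")
}

#' Generate pseudo masks for every record of a manifest
#'
#' Runs \code{\link{generatePseudoMask}} per record. For method
#' \code{"ggt"}, depth normalization is gated by the record's scenario tag
#' (enabled for in-field and UAV, disabled for lab) unless
#' \code{normalizationOverride} forces it. Per-record failures are logged
#' and skipped; the command errors only if every record fails. When the
#' manifest carries ground-truth masks an \code{EvalReport} is computed and
#' written as JSON.
#'
#' @param manifestPath input manifest
#' @param method \code{"otsu"}, \code{"ght"} or \code{"ggt"}
#' @param cfg a \code{GGTConfig}
#' @param ghtPars a \code{GHTParams}
#' @param outdir output directory (masks, manifest, log, report)
#' @param normalizationOverride \code{NULL} (scenario-gated) or logical
#' @return list with \code{manifestPath} (output manifest of pseudo
#'   masks), \code{table} (per-record data.frame), \code{report}
#'   (\code{EvalReport} or \code{NULL}), invisibly
#' @export
runPseudolabel <- function(manifestPath, method = "ggt", cfg = ggtConfig(),
                           ghtPars = ghtParams(), outdir,
                           normalizationOverride = NULL) {
  manifest <- readManifest(manifestPath)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  ensureDir(outdir)
  rows <- list(); preds <- list(); gts <- list(); groups <- character(0)
  for (k in seq_len(nrow(manifest))) {
    rec <- manifest[k, ]
    res <- tryCatch({
      depth <- readDepth(rec$depth)
      cfgK <- cfg
      cfgK@applyNormalization <-
        if (!is.null(normalizationOverride)) normalizationOverride
        else scenarioNormalization(rec$scenario, cfg)
      generatePseudoMask(depth, method, cfgK, ghtPars)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("pseudolabel %s method=%s FAILED: %s", rec$id, method,
                      conditionMessage(res)))
      next
    }
    maskPath <- file.path(outdir, paste0("pseudo_", rec$id, ".png"))
    writeMask(res$mask, maskPath)
    iou <- NA_real_
    if (!is.na(rec$mask) && nzchar(rec$mask)) {
      gt <- readMask(rec$mask)
      preds[[length(preds) + 1L]] <- res$mask
      gts[[length(gts) + 1L]] <- gt
      groups <- c(groups, rec$scenario)
      iou <- miou(list(res$mask), list(gt))@miou
    }
    message(sprintf("pseudolabel %s method=%s threshold=%d fallback=%s miou=%s",
                    rec$id, method, res$threshold,
                    res$fallback %||% "none",
                    ifelse(is.na(iou), "NA", sprintf("%.4f", iou))))
    rows[[length(rows) + 1L]] <- data.frame(
      id = rec$id, depth = rec$depth, rgb = rec$rgb, mask = maskPath,
      scenario = rec$scenario, threshold = res$threshold,
      fallback = res$fallback %||% "none", miou = iou,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("pseudo-mask generation failed for every record", call. = FALSE)
  table <- do.call(rbind, rows)
  outManifest <- file.path(outdir, "manifest.csv")
  writeManifest(table[, c("id", "depth", "rgb", "mask", "scenario")],
                outManifest)
  utils::write.csv(table, file.path(outdir, "records.csv"),
                   row.names = FALSE)
  report <- NULL
  if (length(preds) > 0L) {
    report <- miou(preds, gts, groups = groups)
    jsonlite::write_json(
      list(miou = report@miou, classIoU = as.list(report@classIoU),
           n = report@n),
      file.path(outdir, "report.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  writeEffectiveConfig(outdir, c(list(method = method,
                                      normalizationOverride =
                                        normalizationOverride),
                                 s4ToList(cfg), s4ToList(ghtPars)))
  invisible(list(manifestPath = outManifest, table = table, report = report))
}

#' Refine predicted masks and sweep a filter parameter
#'
#' Reads predicted masks from the \code{mask} column of
#' \code{manifestPath}, refines each with the selected depth- or RGB-guided
#' filter, and — when ground-truth masks are supplied — emits a
#' parameter-vs-mIoU sweep table. The refined masks written to disk use the
#' first (or only) parameter value.
#'
#' @param manifestPath manifest whose \code{mask} column holds the masks to
#'   refine
#' @param filter \code{"gf"} or \code{"jbf"}
#' @param guidance \code{"depth"} or \code{"rgb"}
#' @param values parameter values to sweep: window half-sizes r for the
#'   guided filter, diameters d for the joint bilateral filter; defaults
#'   r = 4 / d = 20
#' @param gtManifestPath optional manifest with ground-truth masks (matched
#'   by id) enabling the sweep table
#' @param outdir output directory
#' @param eps,sigmaColor,sigmaSpace fixed filter parameters
#' @return list with \code{sweep} (data.frame value/miou or NULL) and
#'   \code{manifestPath} for the refined masks, invisibly
#' @export
runFilterSweep <- function(manifestPath, filter = c("jbf", "gf"),
                           guidance = c("depth", "rgb"), values = NULL,
                           gtManifestPath = NULL, outdir, eps = 1e-3,
                           sigmaColor = 25, sigmaSpace = 15) {
  filter <- match.arg(filter)
  guidance <- match.arg(guidance)
  manifest <- readManifest(manifestPath)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  ensureDir(outdir)
  if (is.null(values)) values <- if (filter == "gf") 4L else 20L
  masks <- lapply(manifest$mask, readMask)
  guides <- lapply(seq_len(nrow(manifest)), function(k) {
    if (guidance == "depth") readDepth(manifest$depth[k])
    else readRGB(manifest$rgb[k])
  })
  gt <- NULL
  if (!is.null(gtManifestPath)) {
    gtman <- readManifest(gtManifestPath)
    idx <- match(manifest$id, gtman$id)
    if (anyNA(idx)) stop("gt manifest is missing ids", call. = FALSE)
    gt <- lapply(gtman$mask[idx], readMask)
  }
  refineAt <- function(v) {
    params <- if (filter == "gf") guidedFilterParams(r = v, eps = eps)
              else jointBilateralParams(d = v, sigmaColor = sigmaColor,
                                        sigmaSpace = sigmaSpace)
    lapply(seq_along(masks), function(k)
      refineMask(masks[[k]], guides[[k]], filter, params))
  }
  sweep <- NULL
  if (!is.null(gt)) {
    sweep <- data.frame(value = values, miou = NA_real_)
    for (i in seq_along(values)) {
      refined <- refineAt(values[i])
      sweep$miou[i] <- miou(refined, gt)@miou
      message(sprintf("filter %s %s=%g miou=%.4f", filter,
                      if (filter == "gf") "r" else "d", values[i],
                      sweep$miou[i]))
    }
    utils::write.table(sweep, file.path(outdir, "sweep.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  refined <- refineAt(values[1])
  for (k in seq_along(refined))
    writeMask(refined[[k]],
              file.path(outdir, paste0("refined_", manifest$id[k], ".png")))
  out <- manifest
  out$mask <- file.path(outdir, paste0("refined_", manifest$id, ".png"))
  outManifest <- file.path(outdir, "manifest.csv")
  writeManifest(out, outManifest)
  writeEffectiveConfig(outdir, list(filter = filter, guidance = guidance,
                                    values = values, eps = eps,
                                    sigmaColor = sigmaColor,
                                    sigmaSpace = sigmaSpace))
  invisible(list(sweep = sweep, manifestPath = outManifest))
}

#' Run two-stage self-training over a manifest
#'
#' Builds depth-derived features per record, generates pseudo masks with
#' the selected thresholding method, and runs
#' \code{\link{twoStageTrain}} with the given backend. Ground-truth masks
#' in the manifest (if any) are used for reporting only. Trimaps and
#' stage-two predictions are written to \code{outdir} along with a JSON
#' report.
#'
#' @param manifestPath input manifest
#' @param backend a \code{SegmentationBackend}
#' @param method thresholding method for the pseudo labels
#' @param cfg a \code{GGTConfig}
#' @param outdir output directory
#' @return the \code{twoStageTrain} result, invisibly
#' @export
runSelfTrain <- function(manifestPath, backend = toyPixelBackend(),
                         method = "ggt", cfg = ggtConfig(), outdir) {
  manifest <- readManifest(manifestPath)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  ensureDir(outdir)
  samples <- list(); gts <- list()
  for (k in seq_len(nrow(manifest))) {
    depth <- readDepth(manifest$depth[k])
    cfgK <- cfg
    cfgK@applyNormalization <- scenarioNormalization(manifest$scenario[k], cfg)
    pseudo <- generatePseudoMask(depth, method, cfgK)$mask
    samples[[k]] <- list(features = pixelFeatures(depth), label = pseudo)
    if (!is.na(manifest$mask[k]) && nzchar(manifest$mask[k]))
      gts[[k]] <- readMask(manifest$mask[k])
  }
  gt <- if (length(gts) == nrow(manifest) &&
            !any(vapply(gts, is.null, logical(1)))) gts else NULL
  fit <- twoStageTrain(backend, samples, groundTruth = gt)
  for (k in seq_len(nrow(manifest))) {
    writeTrimap(fit$trimaps[[k]],
                file.path(outdir, paste0("trimap_", manifest$id[k], ".png")))
    writeMask(fit$stage2Masks[[k]],
              file.path(outdir, paste0("stage2_", manifest$id[k], ".png")))
    message(sprintf("selftrain %s ignore=%.4f", manifest$id[k],
                    fit$report$ignoreFraction[k]))
  }
  jsonlite::write_json(fit$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeEffectiveConfig(outdir, c(list(method = method,
                                      backend = class(backend)[1]),
                                 s4ToList(backend), s4ToList(cfg)))
  invisible(fit)
}

#' Evaluate predicted masks against ground truth
#'
#' Matches the two manifests by id and computes the pooled
#' \code{\link{miou}} report, grouped by scenario tag when present.
#'
#' @param predManifestPath manifest whose \code{mask} column holds
#'   predictions
#' @param gtManifestPath manifest whose \code{mask} column holds ground
#'   truth
#' @param outdir optional directory for the JSON report
#' @return an \code{\linkS4class{EvalReport}}
#' @export
runEvaluate <- function(predManifestPath, gtManifestPath, outdir = NULL) {
  pm <- readManifest(predManifestPath)
  gm <- readManifest(gtManifestPath)
  idx <- match(pm$id, gm$id)
  if (anyNA(idx)) stop("gt manifest is missing ids", call. = FALSE)
  pred <- lapply(pm$mask, readMask)
  gt <- lapply(gm$mask[idx], readMask)
  groups <- if (all(is.na(pm$scenario))) NULL else pm$scenario
  report <- miou(pred, gt, groups = groups)
  if (!is.null(outdir)) {
    ensureDir(outdir)
    jsonlite::write_json(
      list(miou = report@miou, classIoU = as.list(report@classIoU),
           n = report@n, perGroup = report@perGroup),
      file.path(outdir, "evaluation.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  report
}
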