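# End-to-end pipeline: synthesize -> (optionally augment) -> train ->
# predict -> evaluate, all under one run directory and one global seed from
# which every stage seed is derived. The defaults describe the scaled-down
# desk experiment this package is validated on: 400 training scenes (25%
# negative) and 100 held-out scenes at 128 x 128, mixed difficulty, a
# base-16 network trained 15 epochs.

#' Pipeline configuration
#'
#' One global `seed` deterministically derives the generator, augmentation
#' and training seeds, so a rerun with the same configuration reproduces
#' the report (bit-identical on the same platform/BLAS build).
#'
#' @param seed global seed.
#' @param size canvas (height, width), divisible by 16.
#' @param nTrainPos,nTrainNeg positive/negative training scenes.
#' @param nTestPos,nTestNeg positive/negative held-out scenes.
#' @param difficulty scene difficulty for both splits (see
#'   [sampleSceneParams()]).
#' @param augment expand the training set 4x with [augmentManifest()]?
#'   Off by default: the generator already randomizes pose, size, defocus
#'   and deformation, so the expansion mainly matters for fixed real
#'   datasets.
#' @param baseChannels,upsample network architecture, see [networkConfig()].
#' @param epochs,batchSize,learningRate,lrSchedule,beta,validationFraction
#'   training settings, see [trainConfig()].
#' @param probThreshold,supportThreshold,minArea,connectivity detection
#'   settings, see [nmsConfig()]. `minArea` defaults to 25 px here: half
#'   the area of the smallest generated polar body (4 px semi-axes), so
#'   borderline-small polar bodies are not rejected by their own size.
#' @param tol evaluation centroid tolerance in pixels.
#' @return validated nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L, size = c(128L, 128L),
                           nTrainPos = 300L, nTrainNeg = 100L,
                           nTestPos = 75L, nTestNeg = 25L,
                           difficulty = "mixed", augment = FALSE,
                           baseChannels = 16L, upsample = "transposed",
                           epochs = 15L, batchSize = 8L,
                           learningRate = 2e-3, lrSchedule = "cosine",
                           beta = 0.5,
                           validationFraction = 0.2,
                           probThreshold = 0.5, supportThreshold = 0.1,
                           minArea = 25L, connectivity = 8L, tol = 10) {
  list(seed = as.integer(seed), size = as.integer(size),
       nTrainPos = as.integer(nTrainPos), nTrainNeg = as.integer(nTrainNeg),
       nTestPos = as.integer(nTestPos), nTestNeg = as.integer(nTestNeg),
       difficulty = difficulty, augment = isTRUE(augment),
       network = networkConfig(baseChannels = baseChannels,
                               upsample = upsample),
       training = trainConfig(epochs = epochs, batchSize = batchSize,
                              learningRate = learningRate,
                              lrSchedule = lrSchedule, beta = beta,
                              validationFraction = validationFraction),
       nms = nmsConfig(probThreshold = probThreshold,
                       supportThreshold = supportThreshold,
                       minArea = minArea, connectivity = connectivity),
       tol = tol)
}

#' Predict detections for every entry of a manifest
#'
#' @param net a trained [SegmentationNetwork-class].
#' @param manifest data.frame with an `image` column.
#' @param cfg an [nmsConfig()].
#' @param batchSize images per forward pass (images of equal size are
#'   batched; a mixed-size manifest falls back to single-image passes).
#' @return list of [DetectionResult-class], one per manifest row.
#' @export
predictManifest <- function(net, manifest, cfg = nmsConfig(),
                            batchSize = 8L) {
  n <- nrow(manifest)
  imgs <- lapply(manifest$image, function(p) asPixels(readMicrograph(p)))
  dims <- vapply(imgs, dim, integer(2))
  out <- vector("list", n)
  if (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L)
    batchSize <- 1L
  H <- dims[1, 1]; W <- dims[2, 1]
  for (start in seq(1L, n, by = batchSize)) {
    bi <- start:min(start + batchSize - 1L, n)
    X <- matrix(unlist(lapply(imgs[bi], function(m) as.vector(t(m))),
                       use.names = FALSE), ncol = 1L)
    fw <- netForward(net@params, net@state, X, H, W, length(bi),
                     net@config, training = FALSE)
    p <- f_sigmoid(fw$logits$x)
    for (b in seq_along(bi)) {
      rows <- ((b - 1L) * H * W + 1L):(b * H * W)
      pmap <- ProbabilityMap(fromRowMajor(p[rows], H, W))
      out[[bi[b]]] <- detectFromMap(pmap, cfg)
    }
  }
  out
}

detectionsToFrame <- function(manifest, dets) {
  data.frame(
    image = manifest$image,
    present = vapply(dets, function(d) d@present, logical(1)),
    row = vapply(dets, function(d) d@centroid[1], numeric(1)),
    col = vapply(dets, function(d) d@centroid[2], numeric(1)),
    confidence = vapply(dets, function(d) d@confidence, numeric(1)),
    area = vapply(dets, function(d) d@area, numeric(1)))
}

#' Run the full synthesize-train-evaluate pipeline
#'
#' Executes every stage into `outDir` (data manifests, training history,
#' best checkpoint, per-image predictions, evaluation report) and returns
#' the evaluation report. All randomness is derived from `config$seed`.
#'
#' @param config a [pipelineConfig()].
#' @param outDir run directory (created if needed).
#' @param verbose print stage progress?
#' @return an [EvalReport-class]; artifacts are left under `outDir`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run"),
                        verbose = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- deriveSeeds(config$seed, 4L)

  say("[1/5] generating %d training scenes",
      config$nTrainPos + config$nTrainNeg)
  trainMan <- generateDataset(config$nTrainPos, config$nTrainNeg,
                              config$difficulty,
                              file.path(outDir, "data", "train"),
                              seed = seeds[1], size = config$size)
  say("[1/5] generating %d held-out scenes",
      config$nTestPos + config$nTestNeg)
  testMan <- generateDataset(config$nTestPos, config$nTestNeg,
                             config$difficulty,
                             file.path(outDir, "data", "test"),
                             seed = seeds[2], size = config$size)

  if (config$augment) {
    say("[2/5] augmenting %d -> %d pairs", nrow(trainMan),
        4L * nrow(trainMan))
    trainMan <- augmentManifest(trainMan, file.path(outDir, "data", "aug"),
                                seed = seeds[3])
  } else say("[2/5] augmentation disabled")

  say("[3/5] training (%d epochs, base %d channels)",
      config$training$epochs, config$network$baseChannels)
  netCfg <- config$network
  netCfg$seed <- seeds[4] %% 100000L
  net <- buildNetwork(netCfg)
  trCfg <- config$training
  trCfg$seed <- seeds[4]
  trCfg$checkpointDir <- file.path(outDir, "checkpoint")
  fit <- trainNetwork(net, trainMan, trCfg, verbose = verbose)

  say("[4/5] predicting %d held-out images", nrow(testMan))
  dets <- predictManifest(fit$net, testMan, config$nms)
  utils::write.csv(detectionsToFrame(testMan, dets),
                   file.path(outDir, "predictions.csv"), row.names = FALSE)

  say("[5/5] evaluating with %g px tolerance", config$tol)
  truths <- lapply(testMan$mask, function(p) {
    maskGroundTruth(readLabelMask(p))
  })
  report <- evaluateDetections(dets, truths, tol = config$tol)
  utils::write.csv(report@summary, file.path(outDir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(report@records, file.path(outDir, "records.csv"),
                   row.names = FALSE)
  report
}
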