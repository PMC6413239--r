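# Seeded training loop: Adam on the combined Dice + beta * cross-entropy
# loss over a manifest of image/mask pairs, with an epoch-level history and
# best-validation-loss checkpointing. Fully reproducible: the seed fixes
# the validation split, the per-epoch shuffles and nothing else is random
# (weight initialization is seeded separately in buildNetwork).

#' Training configuration
#'
#' @param epochs number of epochs (>= 1); no early stopping, fixed length
#'   for reproducibility.
#' @param batchSize images per gradient step (>= 1).
#' @param learningRate Adam base step size (> 0), default 1e-3.
#' @param lrSchedule "constant", or "cosine" for half-cosine annealing of
#'   the step size from `learningRate` to ~0 over the epoch budget.
#' @param beta weight of the cross-entropy term in the combined loss.
#' @param seed integer seed for the split and batch shuffles.
#' @param validationFraction fraction of the manifest held out for
#'   validation, in \[0, 1).
#' @param checkpointDir optional directory; the best-validation network is
#'   saved there as `best.rds` (+ JSON sidecar).
#' @return validated list.
#' @export
trainConfig <- function(epochs = 15L, batchSize = 8L, learningRate = 1e-3,
                        lrSchedule = c("constant", "cosine"), beta = 0.5,
                        seed = 1L, validationFraction = 0.2,
                        checkpointDir = NULL) {
  lrSchedule <- match.arg(lrSchedule)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batchSize < 1) stop("batchSize must be >= 1", call. = FALSE)
  if (learningRate <= 0) stop("learningRate must be > 0", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (validationFraction < 0 || validationFraction >= 1)
    stop("validationFraction must lie in [0, 1)", call. = FALSE)
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       learningRate = learningRate, lrSchedule = lrSchedule, beta = beta,
       seed = as.integer(seed), validationFraction = validationFraction,
       checkpointDir = checkpointDir)
}

# Load all pairs of a manifest into memory as row-major pixel vectors.
loadPairs <- function(manifest) {
  n <- nrow(manifest)
  imgs <- vector("list", n); msks <- vector("list", n)
  dims <- NULL
  for (i in seq_len(n)) {
    m <- asPixels(readMicrograph(manifest$image[i]))
    if (is.null(dims)) dims <- dim(m)
    if (!all(dim(m) == dims))
      stop("all images must share one size; ", manifest$image[i],
           " is ", nrow(m), "x", ncol(m), call. = FALSE)
    hasMask <- !is.na(manifest$mask[i]) && nzchar(manifest$mask[i])
    k <- if (hasMask) asPixels(readLabelMask(manifest$mask[i]))
         else matrix(0, dims[1], dims[2])
    imgs[[i]] <- as.vector(t(m))
    msks[[i]] <- as.vector(t(k))
  }
  list(imgs = imgs, msks = msks, H = dims[1], W = dims[2])
}

stackBatch <- function(vecs, idx) {
  matrix(unlist(vecs[idx], use.names = FALSE), ncol = 1L)
}

# Mean combined loss of the current weights over a set of samples
# (inference-mode forward, no gradient).
evalLoss <- function(P, S, cfg, data, idx, beta, batchSize) {
  tot <- c(value = 0, dice = 0, cate = 0)
  HW <- data$H * data$W
  for (start in seq(1L, length(idx), by = batchSize)) {
    bi <- idx[start:min(start + batchSize - 1L, length(idx))]
    X <- stackBatch(data$imgs, bi)
    Tg <- stackBatch(data$msks, bi)
    fw <- netForward(P, S, X, data$H, data$W, length(bi), cfg,
                     training = FALSE)
    p <- f_sigmoid(fw$logits$x)
    for (b in seq_along(bi)) {
      rows <- ((b - 1L) * HW + 1L):(b * HW)
      l <- totalLoss(matrix(p[rows], 1), matrix(Tg[rows], 1), beta)
      tot <- tot + c(l$value, l$dice, l$cate)
    }
  }
  tot / length(idx)
}

#' Train the segmentation network on a manifest
#'
#' Minimizes `diceLoss + beta * cateLoss` with Adam. The manifest is
#' shuffled once under the seed and split into training and validation
#' parts; the returned network carries the weights of the epoch with the
#' lowest validation loss (lowest training loss when
#' `validationFraction = 0`). Per-image losses are computed per sample so
#' the Dice term matches its single-image definition.
#'
#' @param net a freshly built or pre-trained [SegmentationNetwork-class].
#' @param manifest data.frame from [readManifest()] or [generateDataset()].
#' @param config a [trainConfig()].
#' @param verbose print per-epoch losses?
#' @return list with `net` (best checkpoint) and `history` (data.frame with
#'   one row per epoch: trainLoss, valLoss, trainDice, trainCate, valDice,
#'   valCate).
#' @export
trainNetwork <- function(net, manifest, config = trainConfig(),
                         verbose = FALSE) {
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  data <- loadPairs(manifest)
  n <- nrow(manifest)
  cfg <- net@config
  HW <- data$H * data$W
  P <- list2env(net@params, parent = emptyenv())
  S <- list2env(net@state, parent = emptyenv())
  pnames <- names(net@params)
  adamM <- new.env(parent = emptyenv())
  adamV <- new.env(parent = emptyenv())
  for (k in pnames) {
    adamM[[k]] <- net@params[[k]] * 0
    adamV[[k]] <- net@params[[k]] * 0
  }
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8
  stepN <- 0L
  best <- list(loss = Inf, P = NULL, S = NULL)
  hist <- vector("list", config$epochs)

  withSeed(config$seed, {
    perm <- sample(n)
    nVal <- floor(config$validationFraction * n)
    valIdx <- if (nVal > 0) perm[seq_len(nVal)] else integer(0)
    trainIdx <- perm[setdiff(seq_len(n), seq_len(nVal))]
    stopifnot(length(intersect(trainIdx, valIdx)) == 0)
    if (length(trainIdx) == 0)
      stop("validationFraction leaves no training samples", call. = FALSE)

    for (epoch in seq_len(config$epochs)) {
      lrNow <- if (identical(config$lrSchedule, "cosine"))
        config$learningRate * 0.5 *
          (1 + cos(pi * (epoch - 1) / config$epochs))
      else config$learningRate
      order <- sample(trainIdx)
      run <- c(value = 0, dice = 0, cate = 0)
      nb <- 0L
      for (start in seq(1L, length(order), by = config$batchSize)) {
        bi <- order[start:min(start + config$batchSize - 1L, length(order))]
        B <- length(bi)
        X <- stackBatch(data$imgs, bi)
        Tg <- stackBatch(data$msks, bi)
        fw <- netForward(P, S, X, data$H, data$W, B, cfg, training = TRUE)
        p <- f_sigmoid(fw$logits$x)
        dZ <- numeric(length(p))
        for (b in seq_len(B)) {
          rows <- ((b - 1L) * HW + 1L):(b * HW)
          pb <- p[rows]; tb <- Tg[rows]
          l <- totalLoss(matrix(pb, 1), matrix(tb, 1), config$beta)
          if (!is.finite(l$value))
            stop("non-finite loss at epoch ", epoch, ", batch ",
                 nb + 1L, call. = FALSE)
          run <- run + c(l$value, l$dice, l$cate)
          dZ[rows] <- lossGradLogits(pb, tb, config$beta) / B
        }
        pg <- tapeBackward(fw$tape, fw$logits, f_d2f(dZ), P)
        stepN <- stepN + 1L
        corr1 <- 1 - b1^stepN; corr2 <- 1 - b2^stepN
        for (k in pnames) {
          g <- pg[[k]]
          if (is.null(g)) next
          if (is.null(dim(P[[k]]))) g <- as.vector(g)
          adamM[[k]] <- b1 * adamM[[k]] + (1 - b1) * g
          adamV[[k]] <- b2 * adamV[[k]] + (1 - b2) * g^2
          P[[k]] <- P[[k]] - lrNow *
            (adamM[[k]] / corr1) / (sqrt(adamV[[k]] / corr2) + adamEps)
        }
        nb <- nb + 1L
      }
      trainLoss <- run / length(order)
      valLoss <- if (nVal > 0)
        evalLoss(P, S, cfg, data, valIdx, config$beta, config$batchSize)
      else c(value = NA_real_, dice = NA_real_, cate = NA_real_)
      monitor <- if (nVal > 0) valLoss[["value"]] else trainLoss[["value"]]
      if (monitor <= best$loss) {
        best$loss <- monitor
        best$P <- as.list(P)
        best$S <- as.list(S)
      }
      hist[[epoch]] <- data.frame(
        epoch = epoch,
        trainLoss = trainLoss[["value"]], valLoss = valLoss[["value"]],
        trainDice = trainLoss[["dice"]], trainCate = trainLoss[["cate"]],
        valDice = valLoss[["dice"]], valCate = valLoss[["cate"]])
      if (verbose)
        message(sprintf("epoch %d: train %.4f  val %.4f", epoch,
                        trainLoss[["value"]], valLoss[["value"]]))
    }
  })
  history <- do.call(rbind, hist)
  bestNet <- new("SegmentationNetwork", params = best$P, state = best$S,
                 config = cfg)
  if (!is.null(config$checkpointDir)) {
    dir.create(config$checkpointDir, recursive = TRUE, showWarnings = FALSE)
    saveCheckpoint(bestNet, file.path(config$checkpointDir, "best.rds"))
    utils::write.csv(history,
                     file.path(config$checkpointDir, "history.csv"),
                     row.names = FALSE)
  }
  list(net = bestNet, history = history)
}

paramFingerprint <- function(params) {
  lapply(params, function(p) as.integer(if (is.null(dim(p))) length(p)
                                        else dim(p)))
}

#' Save a network checkpoint
#'
#' Weights and running moments go to `path` (RDS); the architecture
#' configuration and a parameter-shape fingerprint go to a JSON sidecar at
#' `<path>.json` so a checkpoint can be validated before loading.
#'
#' @param net a [SegmentationNetwork-class].
#' @param path destination .rds path.
#' @export
saveCheckpoint <- function(net, path) {
  saveRDS(list(params = net@params, state = net@state), path)
  sidecar <- list(config = net@config,
                  fingerprint = paramFingerprint(net@params))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a network checkpoint
#'
#' Requires both the RDS file and its JSON sidecar; errors if either is
#' missing or if the stored weights do not match the sidecar's shape
#' fingerprint. The loaded network's forward pass is bit-identical to the
#' saved one's.
#'
#' @param path .rds path written by [saveCheckpoint()].
#' @return a [SegmentationNetwork-class].
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) stop("sidecar not found: ", sc, call. = FALSE)
  blob <- readRDS(path)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  fp <- paramFingerprint(blob$params)
  stored <- lapply(side$fingerprint, as.integer)
  if (!identical(names(fp), names(stored)) ||
      !isTRUE(all.equal(unname(fp), unname(stored))))
    stop("checkpoint does not match its sidecar fingerprint", call. = FALSE)
  cfg <- side$config
  cfg$baseChannels <- as.integer(cfg$baseChannels)
  cfg$inChannels <- as.integer(cfg$inChannels)
  cfg$seed <- as.integer(cfg$seed)
  new("SegmentationNetwork", params = blob$params, state = blob$state,
      config = cfg)
}
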