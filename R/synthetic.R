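# Synthetic oocyte-scene generator. Produces paired micrograph/mask images
# emulating brightfield oocyte micrographs: a roughly circular cell with a
# zona pellucida ring, textured cytoplasm, an optional small polar body
# lodged between cytoplasm and zona, holding/injection pipette bars, defocus
# blur of the polar body (Gaussian PSF), whole-scene elastic deformation and
# sensor noise. Geometry is exact: the label mask is the rasterized
# polar-body ellipse (after deformation), never the blurred appearance.

#' Scene parameters for the synthetic oocyte generator
#'
#' The polar body sits between the cytoplasm and the zona pellucida: its
#' centre is placed at radius `cellRadius - zonaThickness / 2` from the cell
#' centre, at perimeter angle `pbCenterAngle`.
#'
#' @param cellCenter numeric (row, col) of the oocyte centre in pixels.
#' @param cellRadius oocyte radius in pixels (outer zona edge).
#' @param zonaThickness zona pellucida ring thickness in pixels.
#' @param polarBodyPresent logical: draw a polar body?
#' @param pbCenterAngle angle (radians) of the polar body on the perimeter;
#'   0 points along +col, pi/2 along +row.
#' @param pbSemiAxes numeric (a, b): polar-body ellipse semi-axes in pixels;
#'   each must be >= 2 and <= cellRadius / 3.
#' @param pbOrientation ellipse orientation in radians.
#' @param pbDefocusSigma Gaussian point-spread std in pixels (0 = in focus);
#'   blurs the rendered polar body only, never the mask.
#' @param deformation an [elasticParams()] list applied jointly to image and
#'   mask, or NULL for no deformation.
#' @param pipettePresent logical: draw holding/injection pipette bars?
#' @param brightness global illumination level in \[0.3, 1\].
#' @param noiseSigma additive Gaussian sensor-noise std (intensity units).
#' @param seed integer seed; rendering is deterministic given the seed.
#' @return validated parameter list.
#' @export
sceneParams <- function(cellCenter, cellRadius, zonaThickness = 10,
                        polarBodyPresent = TRUE, pbCenterAngle = 0,
                        pbSemiAxes = c(8, 6), pbOrientation = 0,
                        pbDefocusSigma = 0, deformation = NULL,
                        pipettePresent = FALSE, brightness = 0.85,
                        noiseSigma = 0.02, seed = 1L) {
  if (length(cellCenter) != 2L || !is.numeric(cellCenter))
    stop("cellCenter must be numeric (row, col)", call. = FALSE)
  if (cellRadius <= 0) stop("cellRadius must be positive", call. = FALSE)
  if (zonaThickness < 2 || zonaThickness >= cellRadius)
    stop("zonaThickness must be in [2, cellRadius)", call. = FALSE)
  if (length(pbSemiAxes) != 2L || any(pbSemiAxes < 2))
    stop("pbSemiAxes must each be >= 2 px", call. = FALSE)
  if (any(pbSemiAxes > cellRadius / 3))
    stop("pbSemiAxes must each be <= cellRadius / 3", call. = FALSE)
  if (pbDefocusSigma < 0) stop("pbDefocusSigma must be >= 0", call. = FALSE)
  if (brightness < 0.3 || brightness > 1)
    stop("brightness must lie in [0.3, 1]", call. = FALSE)
  if (noiseSigma < 0) stop("noiseSigma must be >= 0", call. = FALSE)
  list(cellCenter = as.numeric(cellCenter), cellRadius = cellRadius,
       zonaThickness = zonaThickness, polarBodyPresent = polarBodyPresent,
       pbCenterAngle = pbCenterAngle, pbSemiAxes = as.numeric(pbSemiAxes),
       pbOrientation = pbOrientation, pbDefocusSigma = pbDefocusSigma,
       deformation = deformation, pipettePresent = pipettePresent,
       brightness = brightness, noiseSigma = noiseSigma,
       seed = as.integer(seed))
}

#' Centre of the polar body implied by the scene geometry
#'
#' @param p a [sceneParams()] list.
#' @return numeric (row, col): the ellipse centre at radius
#'   `cellRadius - zonaThickness / 2` along `pbCenterAngle`.
#' @export
pbCenter <- function(p) {
  rho <- p$cellRadius - p$zonaThickness / 2
  c(p$cellCenter[1] + rho * sin(p$pbCenterAngle),
    p$cellCenter[2] + rho * cos(p$pbCenterAngle))
}

# Rasterize the polar-body ellipse: 1 where the pixel centre is inside.
pbIndicator <- function(p, H, W) {
  ctr <- pbCenter(p)
  g <- canvasGrid(H, W)
  dr <- g$r - ctr[1]; dc <- g$c - ctr[2]
  co <- cos(p$pbOrientation); si <- sin(p$pbOrientation)
  u <- co * dc + si * dr   # along semi-axis a
  v <- -si * dc + co * dr  # along semi-axis b
  q <- (u / p$pbSemiAxes[1])^2 + (v / p$pbSemiAxes[2])^2
  fromRowMajor((q <= 1) * 1, H, W)
}

drawPipettes <- function(img, p) {
  H <- nrow(img); W <- ncol(img)
  cr <- round(p$cellCenter[1]); R <- p$cellRadius
  bar <- function(img, rows, cols, halfWidth, darkEdge) {
    rows <- rows[rows >= 1 & rows <= H]
    cols <- cols[cols >= 1 & cols <= W]
    if (length(rows) == 0 || length(cols) == 0) return(img)
    img[rows, cols] <- img[rows, cols] * 0.8
    edges <- unique(c(utils::head(rows, darkEdge), utils::tail(rows, darkEdge)))
    img[edges, cols] <- img[edges, cols] * 0.35
    img
  }
  wHold <- max(4L, round(R * 0.22))
  wInj <- max(2L, round(R * 0.10))
  leftEnd <- floor(p$cellCenter[2] - R)        # touching the cell edge
  rightStart <- ceiling(p$cellCenter[2] + R)
  img <- bar(img, (cr - wHold):(cr + wHold), seq_len(max(leftEnd, 0)),
             wHold, 2L)
  img <- bar(img, (cr - wInj):(cr + wInj),
             if (rightStart <= W) rightStart:W else integer(0), wInj, 1L)
  img
}

#' Render a synthetic oocyte micrograph and its label mask
#'
#' Deterministic for a fixed `p$seed`. The mask marks exactly the rasterized
#' polar-body ellipse (after deformation, if any); defocus convolves the
#' rendered polar body with a Gaussian PSF before compositing and does not
#' change the mask. Pipettes are straight bars touching the cell edge.
#'
#' @param p a [sceneParams()] list.
#' @param size integer (height, width), each divisible by 16.
#' @return list with `image` (a [Micrograph-class]) and `mask`
#'   (a [LabelMask-class]).
#' @export
renderScene <- function(p, size = c(256, 256)) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H %% 16L != 0L || W %% 16L != 0L)
    stop("size must be divisible by 16", call. = FALSE)
  b <- p$brightness
  draws <- withSeed(p$seed, {
    list(texLow = matrix(stats::runif(H * W, -1, 1), H, W),
         texFine = matrix(stats::runif(H * W, -1, 1), H, W),
         pbTex = matrix(stats::runif(H * W, -1, 1), H, W),
         gradDir = stats::runif(1, 0, 2 * pi),
         gradAmp = stats::runif(1, 0, 0.04),
         noise = matrix(stats::rnorm(H * W), H, W))
  })
  g <- canvasGrid(H, W)
  d <- fromRowMajor(sqrt((g$r - p$cellCenter[1])^2 +
                         (g$c - p$cellCenter[2])^2), H, W)
  R <- p$cellRadius; zt <- p$zonaThickness
  sIn <- stats::plogis((R - d) / 1.2)        # 1 inside the whole cell
  sCyt <- stats::plogis((R - zt - d) / 1.2)  # 1 inside the cytoplasm
  # Low-frequency multiplicative texture keeps plain thresholding non-trivial.
  texLow <- gaussBlur2d(draws$texLow, min(H, W) / 18)
  texLow <- texLow / max(stats::sd(texLow), 1e-8) * 0.10
  texFine <- gaussBlur2d(draws$texFine, 1.2)
  texFine <- texFine / max(stats::sd(texFine), 1e-8) * 0.04
  img <- b * (0.95 * (1 - sIn) + 0.80 * (sIn - sCyt) + 0.55 * sCyt)
  img <- img * (1 + sCyt * (texLow + texFine))
  # Dark rims at the zona boundaries, as in brightfield images.
  img <- img - b * 0.22 * exp(-(d - R)^2 / (2 * 1.3^2))
  img <- img - b * 0.16 * exp(-(d - (R - zt))^2 / (2 * 1.3^2))

  mask <- matrix(0, H, W)
  if (p$polarBodyPresent) {
    ind <- pbIndicator(p, H, W)
    mask <- ind
    ctr <- pbCenter(p)
    co <- cos(p$pbOrientation); si <- sin(p$pbOrientation)
    dr <- fromRowMajor(g$r - ctr[1], H, W)
    dc <- fromRowMajor(g$c - ctr[2], H, W)
    u <- co * dc + si * dr; v <- -si * dc + co * dr
    en <- sqrt((u / p$pbSemiAxes[1])^2 + (v / p$pbSemiAxes[2])^2)
    pbNoise <- gaussBlur2d(draws$pbTex, 1.0)
    pbNoise <- pbNoise / max(stats::sd(pbNoise), 1e-8) * 0.05
    # Dark body with a bright rim just inside the boundary.
    pbLayer <- b * (0.40 + 0.30 * exp(-(en - 0.88)^2 / (2 * 0.08^2))) *
      (1 + pbNoise)
    sigmaPSF <- max(0.6, p$pbDefocusSigma)  # 0.6 px acts as anti-aliasing
    A <- gaussBlur2d(ind, sigmaPSF)
    P <- gaussBlur2d(pbLayer * ind, sigmaPSF)
    img <- img * (1 - A) + P
  }

  if (!is.null(p$deformation)) {
    def <- elasticPair(img, mask, params = p$deformation)
    img <- def$image; mask <- def$mask
  }
  if (p$pipettePresent) img <- drawPipettes(img, p)
  # Mild illumination gradient across the field of view.
  gr <- fromRowMajor((g$r - (H + 1) / 2) / H, H, W)
  gc <- fromRowMajor((g$c - (W + 1) / 2) / W, H, W)
  img <- img * (1 + draws$gradAmp *
                  (sin(draws$gradDir) * gr + cos(draws$gradDir) * gc))
  img <- img + p$noiseSigma * draws$noise
  list(image = Micrograph(pmin(pmax(img, 0), 1)),
       mask = LabelMask(mask))
}

#' Sample random scene parameters at a given difficulty
#'
#' Difficulty levels mirror the three failure axes of rotation-stage
#' micrographs: `"clear"` (in focus, no deformation), `"defocused"`
#' (PSF std drawn from \[2, 6\] px), `"deformed"` (elastic deformation with
#' alpha in \[4, 10\] px), and `"mixed"` (each hazard applied independently
#' with probability 1/2). Polar-body semi-axes are drawn from \[4, 16\] px in
#' all modes (clamped to the cellRadius/3 geometric bound).
#'
#' @param difficulty one of "clear", "defocused", "deformed", "mixed".
#' @param seed integer seed; draws are deterministic given the seed.
#' @param size canvas (height, width) the scene is destined for.
#' @param polarBodyPresent logical: whether this scene has a polar body.
#' @return a [sceneParams()] list.
#' @export
sampleSceneParams <- function(difficulty = c("clear", "defocused", "deformed",
                                             "mixed"),
                              seed = 1L, size = c(256, 256),
                              polarBodyPresent = TRUE) {
  if (is.character(difficulty) && length(difficulty) == 1L &&
      !(difficulty %in% c("clear", "defocused", "deformed", "mixed")))
    stop("unknown difficulty label '", difficulty, "'", call. = FALSE)
  difficulty <- match.arg(difficulty)
  s <- min(size)
  withSeed(seed, {
    R <- stats::runif(1, 0.30, 0.38) * s
    zt <- max(2, stats::runif(1, 0.09, 0.13) * R)
    center <- c(size[1] / 2 + stats::runif(1, -0.03, 0.03) * s,
                size[2] / 2 + stats::runif(1, -0.03, 0.03) * s)
    axes <- pmin(pmax(stats::runif(2, 4, 16), 2), R / 3)
    defocus <- 0
    deform <- NULL
    wantDefocus <- difficulty == "defocused" ||
      (difficulty == "mixed" && stats::runif(1) < 0.5)
    wantDeform <- difficulty == "deformed" ||
      (difficulty == "mixed" && stats::runif(1) < 0.5)
    if (wantDefocus) defocus <- stats::runif(1, 2, 6)
    if (wantDeform)
      deform <- elasticParams(alpha = stats::runif(1, 4, 10),
                              sigma = stats::runif(1, 8, 12),
                              seed = sample.int(.Machine$integer.max - 1L, 1))
    sceneParams(
      cellCenter = center, cellRadius = R, zonaThickness = zt,
      polarBodyPresent = polarBodyPresent,
      pbCenterAngle = stats::runif(1, 0, 2 * pi),
      pbSemiAxes = axes,
      pbOrientation = stats::runif(1, 0, pi),
      pbDefocusSigma = defocus, deformation = deform,
      pipettePresent = stats::runif(1) < 0.7,
      brightness = stats::runif(1, 0.6, 1.0),
      noiseSigma = stats::runif(1, 0.01, 0.03),
      seed = sample.int(.Machine$integer.max - 1L, 1))
  })
}

#' Generate a synthetic image/mask dataset with a manifest
#'
#' Writes `nPositive` scenes containing a polar body (nonempty masks) and
#' `nNegative` scenes without one (all-zero masks) as paired PNGs under
#' `outDir`, plus a `manifest.csv` pairing them. Fully deterministic under
#' `seed`: rerunning with the same arguments reproduces identical files.
#'
#' @param nPositive number of positive scenes (>= 0).
#' @param nNegative number of negative scenes (>= 0).
#' @param difficulty difficulty label passed to [sampleSceneParams()].
#' @param outDir output directory (created if needed).
#' @param seed master seed for the whole dataset.
#' @param size canvas (height, width), divisible by 16.
#' @return the manifest data.frame (columns image, mask, label) with
#'   absolute paths; a relative-path copy is written to
#'   `outDir/manifest.csv`.
#' @export
generateDataset <- function(nPositive, nNegative,
                            difficulty = "mixed", outDir, seed = 1L,
                            size = c(256, 256)) {
  if (nPositive < 0 || nNegative < 0)
    stop("counts must be nonnegative", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir))
    stop("cannot create output directory: ", outDir, call. = FALSE)
  n <- nPositive + nNegative
  seeds <- deriveSeeds(seed, max(n, 1L))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    positive <- i <= nPositive
    p <- sampleSceneParams(difficulty, seed = seeds[i], size = size,
                           polarBodyPresent = positive)
    sc <- renderScene(p, size = size)
    if (positive && sum(asPixels(sc$mask)) == 0)
      stop("positive scene ", i, " rendered an empty mask", call. = FALSE)
    ip <- file.path(outDir, sprintf("img_%05d.png", i))
    mp <- file.path(outDir, sprintf("mask_%05d.png", i))
    writeMicrograph(sc$image, ip)
    writeLabelMask(sc$mask, mp)
    rows[[i]] <- data.frame(image = ip, mask = mp,
                            label = if (positive) "positive" else "negative",
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0) do.call(rbind, rows) else
    data.frame(image = character(0), mask = character(0),
               label = character(0))
  writeManifest(manifest, file.path(outDir, "manifest.csv"),
                relativeTo = outDir)
  manifest
}
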