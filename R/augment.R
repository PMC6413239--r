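# Paired image/mask geometric augmentation: random rotation, axis flipping
# and elastic deformation. The elastic transform draws per-pixel displacement
# fields uniform on (-1, 1), smooths them with a unit-sum Gaussian of std
# sigma (truncated at 4 sigma) and scales by alpha, then resamples the source
# at the displaced coordinates. Every transform is applied identically to the
# image (bilinear) and its mask (nearest neighbour, so the mask stays binary).

#' Elastic-deformation parameters
#'
#' @param alpha displacement magnitude in pixels (>= 0); the smoothed field
#'   is scaled by alpha, so |displacement| <= alpha everywhere.
#' @param sigma Gaussian smoothing std in pixels (> 0); larger values give
#'   smoother, more rigid-looking deformations.
#' @param seed integer seed for the random displacement draw.
#' @return validated list of class parameters.
#' @export
elasticParams <- function(alpha, sigma, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a nonnegative scalar", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar", call. = FALSE)
  list(alpha = alpha, sigma = sigma, seed = as.integer(seed))
}

#' Generate a smoothed random displacement field
#'
#' Draws per-pixel displacements i.i.d. uniform on (-1, 1) for the row and
#' column directions, convolves each with a unit-sum 2-D Gaussian of std
#' `sigma`, and scales by `alpha`. Because the kernel sums to one and the
#' raw draws lie in (-1, 1), the result is bounded by `alpha` in absolute
#' value. Deterministic for a fixed seed.
#'
#' @param shape integer (height, width).
#' @param params an [elasticParams()] list.
#' @return list with matrices `drow`, `dcol` of the given shape.
#' @export
makeDisplacement <- function(shape, params) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  raw <- withSeed(params$seed, {
    list(dr = matrix(stats::runif(H * W, -1, 1), H, W),
         dc = matrix(stats::runif(H * W, -1, 1), H, W))
  })
  list(drow = params$alpha * gaussBlur2d(raw$dr, params$sigma),
       dcol = params$alpha * gaussBlur2d(raw$dc, params$sigma))
}

#' Rotate an image/mask pair about the canvas centre
#'
#' The image is resampled bilinearly; regions rotated in from outside the
#' canvas are filled with the median intensity of the image border. The mask
#' uses nearest-neighbour sampling with fill 0 and is re-binarized, so its
#' values stay in \{0, 1\}. `angle = 0` is an exact identity.
#'
#' @param img a [Micrograph-class] or numeric matrix.
#' @param mask a [LabelMask-class] or 0/1 matrix (same shape), or NULL.
#' @param angle rotation angle in degrees, in \[-90, 90\].
#' @return list with elements `image` and `mask` (matrices; NULL mask stays
#'   NULL).
#' @export
rotatePair <- function(img, mask, angle) {
  if (!is.numeric(angle) || length(angle) != 1L || angle < -90 || angle > 90)
    stop("angle must be a scalar in [-90, 90] degrees", call. = FALSE)
  img <- asPixels(img)
  if (!is.null(mask)) {
    mask <- asPixels(mask)
    if (!all(dim(mask) == dim(img)))
      stop("mask shape must match image shape", call. = FALSE)
  }
  if (angle == 0) return(list(image = img, mask = mask))
  H <- nrow(img); W <- ncol(img)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  th <- angle * pi / 180
  g <- canvasGrid(H, W)
  # Source coordinate = inverse rotation of destination about the centre.
  dr <- g$r - cr; dc <- g$c - cc
  sr <- cr + cos(th) * dr - sin(th) * dc
  sc <- cc + sin(th) * dr + cos(th) * dc
  borderVals <- c(img[1, ], img[H, ], img[, 1], img[, W])
  fill <- stats::median(borderVals)
  out <- fromRowMajor(
    bilinearSample(img, sr, sc, border = "constant", fill = fill), H, W)
  mout <- NULL
  if (!is.null(mask)) {
    mv <- nearestSample(mask, sr, sc, border = "constant", fill = 0)
    mout <- fromRowMajor((mv > 0.5) * 1, H, W)
  }
  list(image = out, mask = mout)
}

#' Flip an image/mask pair along an axis
#'
#' Exact index reversal: "horizontal" mirrors left-right (column c maps to
#' W + 1 - c), "vertical" mirrors top-bottom. Applying the same flip twice
#' is the identity.
#'
#' @inheritParams rotatePair
#' @param axis "horizontal" or "vertical".
#' @return list with elements `image` and `mask`.
#' @export
flipPair <- function(img, mask, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  img <- asPixels(img)
  flip <- function(m) {
    if (axis == "horizontal") m[, rev(seq_len(ncol(m))), drop = FALSE]
    else m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  mout <- NULL
  if (!is.null(mask)) {
    mask <- asPixels(mask)
    if (!all(dim(mask) == dim(img)))
      stop("mask shape must match image shape", call. = FALSE)
    mout <- flip(mask)
  }
  list(image = flip(img), mask = mout)
}

#' Elastically deform an image/mask pair
#'
#' Each output pixel (r, c) is sampled from the source at
#' (r + drow(r, c), c + dcol(r, c)); coordinates outside the canvas are
#' mirrored back in (reflect padding). The image is sampled bilinearly, the
#' mask by nearest neighbour, with the same field for both. `alpha = 0` is
#' an exact identity.
#'
#' @inheritParams rotatePair
#' @param params an [elasticParams()] list, or NULL when `field` is given.
#' @param field optionally a precomputed displacement field from
#'   [makeDisplacement()] (overrides `params`).
#' @return list with elements `image` and `mask`.
#' @export
elasticPair <- function(img, mask, params = NULL, field = NULL) {
  img <- asPixels(img)
  H <- nrow(img); W <- ncol(img)
  if (is.null(field)) {
    if (is.null(params)) stop("provide params or field", call. = FALSE)
    field <- makeDisplacement(c(H, W), params)
  }
  if (!all(dim(field$drow) == c(H, W)) || !all(dim(field$dcol) == c(H, W)))
    stop("displacement field shape must match image shape", call. = FALSE)
  g <- canvasGrid(H, W)
  # Row-major field lookup to match the output grid ordering.
  idx <- cbind(g$r, g$c)
  sr <- g$r + field$drow[idx]
  sc <- g$c + field$dcol[idx]
  out <- fromRowMajor(bilinearSample(img, sr, sc, border = "reflect"), H, W)
  mout <- NULL
  if (!is.null(mask)) {
    mask <- asPixels(mask)
    if (!all(dim(mask) == dim(img)))
      stop("mask shape must match image shape", call. = FALSE)
    mv <- nearestSample(mask, sr, sc, border = "reflect")
    mout <- fromRowMajor((mv > 0.5) * 1, H, W)
  }
  list(image = pmin(pmax(out, 0), 1), mask = mout)
}

#' Expand a dataset fourfold by paired augmentation
#'
#' For every manifest entry, emits the original pair plus exactly one rotated
#' copy (angle uniform on \[-90, 90\]), one flipped copy (axis chosen at
#' random) and one elastically deformed copy (alpha uniform on `alphaRange`,
#' sigma uniform on `sigmaRange`), so the output has 4x the input entries.
#' Augmented images and masks are written to `outDir` as PNGs; entries with
#' no mask file are treated as all-zero (negative) masks and keep their
#' label.
#'
#' @param manifest data.frame from [readManifest()] (columns image, mask,
#'   label).
#' @param outDir directory for augmented images and the new manifest.
#' @param seed integer seed driving all random transform draws.
#' @param alphaRange elastic displacement magnitude range in px.
#' @param sigmaRange elastic smoothing std range in px.
#' @return the expanded manifest (data.frame), also written to
#'   `outDir/manifest.csv`.
#' @export
augmentManifest <- function(manifest, outDir, seed = 1L,
                            alphaRange = c(6, 12), sigmaRange = c(8, 12)) {
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(manifest)
  draws <- withSeed(seed, {
    list(angle = stats::runif(n, -90, 90),
         axis = sample(c("horizontal", "vertical"), n, replace = TRUE),
         alpha = stats::runif(n, alphaRange[1], alphaRange[2]),
         sigma = stats::runif(n, sigmaRange[1], sigmaRange[2]),
         eseed = sample.int(.Machine$integer.max - 1L, n))
  })
  rows <- vector("list", 4L * n)
  for (i in seq_len(n)) {
    img <- asPixels(readMicrograph(manifest$image[i]))
    hasMask <- !is.na(manifest$mask[i]) && nzchar(manifest$mask[i])
    mask <- if (hasMask) asPixels(readLabelMask(manifest$mask[i]))
            else matrix(0, nrow(img), ncol(img))
    lab <- manifest$label[i]
    variants <- list(
      orig = list(image = img, mask = mask),
      rot = rotatePair(img, mask, draws$angle[i]),
      flip = flipPair(img, mask, draws$axis[i]),
      elas = elasticPair(img, mask,
                         elasticParams(draws$alpha[i], draws$sigma[i],
                                       draws$eseed[i]))
    )
    for (k in seq_along(variants)) {
      tag <- names(variants)[k]
      ip <- file.path(outDir, sprintf("img_%05d_%s.png", i, tag))
      mp <- file.path(outDir, sprintf("mask_%05d_%s.png", i, tag))
      writeMicrograph(variants[[k]]$image, ip)
      writeLabelMask(variants[[k]]$mask, mp)
      rows[[(i - 1L) * 4L + k]] <-
        data.frame(image = ip, mask = mp, label = lab,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  writeManifest(out, file.path(outDir, "manifest.csv"), relativeTo = outDir)
  out
}
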