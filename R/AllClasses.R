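#' @import methods
NULL

#' Micrograph: a grayscale oocyte image
#'
#' A single-channel intensity image with values in \[0, 1\], the input of the
#' segmentation network and the output of the synthetic scene generator.
#' Coordinates throughout the package are (row, col) with row 1 at the top.
#' Height and width must each be divisible by 16 because the encoder halves
#' the spatial size four times.
#'
#' @slot .Data numeric matrix of intensities in \[0, 1\].
#' @slot pixelsPer10um physical scale: how many pixels span 10 micrometres
#'   (default 16, the nominal calibration of the target imaging setup).
#' @export
setClass("Micrograph",
  contains = "matrix",
  slots = c(pixelsPer10um = "numeric"),
  prototype = prototype(pixelsPer10um = 16)
)

setValidity("Micrograph", function(object) {
  m <- object@.Data
  if (!is.numeric(m)) return("pixel data must be numeric")
  if (anyNA(m) || any(!is.finite(m))) return("intensities must be finite")
  if (any(m < 0) || any(m > 1)) return("intensities must lie in [0, 1]")
  h <- nrow(m); w <- ncol(m)
  if (h < 16L) return(sprintf("height %d is below the minimum of 16", h))
  if (w < 16L) return(sprintf("width %d is below the minimum of 16", w))
  if (h %% 16L != 0L)
    return(sprintf("height %d is not divisible by 16", h))
  if (w %% 16L != 0L)
    return(sprintf("width %d is not divisible by 16", w))
  if (length(object@pixelsPer10um) != 1L || object@pixelsPer10um <= 0)
    return("pixelsPer10um must be a positive scalar")
  TRUE
})

#' @describeIn Micrograph-class Construct a Micrograph from a numeric matrix.
#' @param pixels numeric matrix in \[0, 1\].
#' @param pixelsPer10um physical scale in pixels per 10 um.
#' @export
Micrograph <- function(pixels, pixelsPer10um = 16) {
  new("Micrograph", as.matrix(pixels), pixelsPer10um = pixelsPer10um)
}

#' LabelMask: a binary polar-body annotation
#'
#' Per-pixel annotation paired with a [Micrograph-class]: 1 marks the
#' polar-body region (stored white on disk), 0 the background (black).
#'
#' @slot .Data numeric matrix with values in \{0, 1\}.
#' @export
setClass("LabelMask", contains = "matrix")

setValidity("LabelMask", function(object) {
  m <- object@.Data
  if (!is.numeric(m)) return("mask data must be numeric")
  if (anyNA(m)) return("mask must not contain NA")
  if (!all(m %in% c(0, 1))) return("mask values must be exactly 0 or 1")
  TRUE
})

#' @describeIn LabelMask-class Construct a LabelMask from a 0/1 matrix.
#' @param pixels numeric matrix of 0s and 1s.
#' @export
LabelMask <- function(pixels) new("LabelMask", as.matrix(pixels))

#' ProbabilityMap: per-pixel polar-body probability
#'
#' The network output: each pixel holds the probability that it belongs to
#' the polar-body region. Same spatial shape as the input micrograph.
#'
#' @slot .Data numeric matrix in \[0, 1\].
#' @export
setClass("ProbabilityMap", contains = "matrix")

setValidity("ProbabilityMap", function(object) {
  m <- object@.Data
  if (anyNA(m) || any(!is.finite(m))) return("probabilities must be finite")
  if (any(m < 0) || any(m > 1)) return("probabilities must lie in [0, 1]")
  TRUE
})

#' @describeIn ProbabilityMap-class Construct a ProbabilityMap.
#' @param pixels numeric matrix in \[0, 1\].
#' @export
ProbabilityMap <- function(pixels) new("ProbabilityMap", as.matrix(pixels))

#' DetectionResult: presence decision and centroid of the polar body
#'
#' End product of the prediction stage: whether a polar body was found, and
#' if so the (row, col) centroid of the winning region, the region's maximum
#' probability (confidence) and its area in pixels. When `present` is FALSE
#' the centroid is absent (`NA`), confidence and area are 0.
#'
#' @slot present logical flag.
#' @slot centroid numeric (row, col), or c(NA, NA) when absent.
#' @slot confidence maximum probability of the winning region, or 0.
#' @slot area pixel count of the winning region, or 0.
#' @export
setClass("DetectionResult",
  slots = c(present = "logical", centroid = "numeric",
            confidence = "numeric", area = "numeric")
)

setValidity("DetectionResult", function(object) {
  if (length(object@present) != 1L) return("present must be a single flag")
  if (length(object@centroid) != 2L) return("centroid must be length 2")
  if (object@present && anyNA(object@centroid))
    return("a present detection must carry a centroid")
  if (!object@present && !all(is.na(object@centroid)))
    return("an absent detection must have an NA centroid")
  TRUE
})

#' @describeIn DetectionResult-class Construct a DetectionResult.
#' @param present logical flag.
#' @param centroid numeric (row, col) or NULL when absent.
#' @param confidence winning region's max probability.
#' @param area winning region's pixel count.
#' @export
DetectionResult <- function(present, centroid = NULL, confidence = 0,
                            area = 0) {
  if (is.null(centroid)) centroid <- c(NA_real_, NA_real_)
  new("DetectionResult", present = present,
      centroid = unname(as.numeric(centroid)),
      confidence = as.numeric(confidence), area = as.numeric(area))
}

setMethod("show", "DetectionResult", function(object) {
  if (object@present) {
    cat(sprintf(
      "DetectionResult: polar body present at (%.2f, %.2f), confidence %.3f, area %d px\n",
      object@centroid[1], object@centroid[2], object@confidence,
      as.integer(object@area)))
  } else {
    cat("DetectionResult: no polar body\n")
  }
})

#' SegmentationNetwork: the inception U-net
#'
#' Holds the trainable parameters (flat named list of weight matrices),
#' non-trainable state (batch-normalization running moments) and the
#' architecture configuration of the nine-module contraction-expansion
#' segmentation network.
#'
#' @slot params named list of numeric arrays (trainable weights).
#' @slot state named list of numeric vectors (running moments).
#' @slot config named list, see [networkConfig()].
#' @export
setClass("SegmentationNetwork",
  slots = c(params = "list", state = "list", config = "list")
)

setMethod("show", "SegmentationNetwork", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "SegmentationNetwork: 9 inception modules, base %d channels, %s decoder\n",
    object@config$baseChannels, object@config$upsample))
  cat(sprintf("  %d trainable parameters in %d arrays\n",
              np, length(object@params)))
})

#' EvalReport: accuracy accounting over a test set
#'
#' Per-sample correctness records plus the per-class tally (positive images,
#' negative images, summary) in the style of a detection-accuracy table.
#'
#' @slot summary data.frame with columns class, n, correct, accuracy.
#' @slot records data.frame with one row per sample: truth_present,
#'   pred_present, distance (px, NA when either centroid is absent), correct.
#' @export
setClass("EvalReport",
  slots = c(summary = "data.frame", records = "data.frame")
)

setMethod("show", "EvalReport", function(object) {
  cat("Polar-body detection accuracy\n")
  s <- object@summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %5d samples  %5d correct  %6.1f%%\n",
                s$class[i], s$n[i], s$correct[i], 100 * s$accuracy[i]))
  }
})

#' @describeIn EvalReport-class Overall accuracy (fraction correct).
#' @param report an EvalReport.
#' @export
overallAccuracy <- function(report) {
  s <- report@summary
  s$accuracy[s$class == "Summary"]
}

# Accept either the S4 class or a plain matrix where convenient.
asPixels <- function(x) {
  if (is(x, "Micrograph") || is(x, "LabelMask") || is(x, "ProbabilityMap"))
    x@.Data
  else as.matrix(x)
}
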