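# Evaluation: the 10-pixel correctness criterion and accuracy accounting
# over positive (polar body visible) and negative samples. A prediction is
# correct when (i) neither truth nor prediction has a polar body, or
# (ii) both do and the centroid distance is strictly below the tolerance.
# A missed detection, a spurious detection, or a centroid at or beyond the
# tolerance is incorrect.

#' Ground truth derived from a label mask
#'
#' Present iff the mask is nonempty; the centroid is the mean of the
#' foreground pixel locations (the same rule the detector applies to its
#' predicted region).
#'
#' @param mask a [LabelMask-class] or 0/1 matrix.
#' @return list with `present` (logical) and `centroid` ((row, col) or NULL).
#' @export
maskGroundTruth <- function(mask) {
  m <- asPixels(mask)
  idx <- which(m == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(present = FALSE, centroid = NULL))
  list(present = TRUE, centroid = unname(colMeans(idx)))
}

centroidDistance <- function(a, b, norm = c("euclidean", "chebyshev")) {
  norm <- match.arg(norm)
  d <- a - b
  if (norm == "euclidean") sqrt(sum(d^2)) else max(abs(d))
}

#' Is a detection correct under the centroid-distance criterion?
#'
#' Truth absent and prediction absent: correct. Truth absent but a
#' detection reported, or truth present but nothing detected: incorrect.
#' Both present: correct iff the centroid distance is strictly less than
#' `tol` pixels (default 10).
#'
#' @param pred a [DetectionResult-class] (or list with `present`,
#'   `centroid`).
#' @param truth list from [maskGroundTruth()].
#' @param tol distance tolerance in pixels (default 10).
#' @param norm "euclidean" (default) or "chebyshev" (per-axis maximum).
#' @return logical flag.
#' @export
isCorrect <- function(pred, truth, tol = 10, norm = "euclidean") {
  predPresent <- if (is(pred, "DetectionResult")) pred@present
    else pred$present
  predCentroid <- if (is(pred, "DetectionResult")) pred@centroid
    else pred$centroid
  if (!truth$present && !predPresent) return(TRUE)
  if (!truth$present || !predPresent) return(FALSE)
  centroidDistance(predCentroid, truth$centroid, norm) < tol
}

#' Tally detection accuracy over a test set
#'
#' @param predictions list of [DetectionResult-class] objects (or lists
#'   with `present`/`centroid`), aligned with `truths`.
#' @param truths list of ground truths from [maskGroundTruth()].
#' @param tol centroid tolerance in pixels.
#' @param norm distance norm, see [isCorrect()].
#' @return an [EvalReport-class] with per-class (Positive, Negative,
#'   Summary) tallies and per-sample records.
#' @export
evaluateDetections <- function(predictions, truths, tol = 10,
                               norm = "euclidean") {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length", call. = FALSE)
  if (length(predictions) == 0)
    stop("nothing to evaluate", call. = FALSE)
  n <- length(predictions)
  rec <- data.frame(truth_present = logical(n), pred_present = logical(n),
                    distance = rep(NA_real_, n), correct = logical(n))
  for (i in seq_len(n)) {
    p <- predictions[[i]]; t <- truths[[i]]
    pp <- if (is(p, "DetectionResult")) p@present else p$present
    pc <- if (is(p, "DetectionResult")) p@centroid else p$centroid
    rec$truth_present[i] <- t$present
    rec$pred_present[i] <- pp
    if (t$present && pp)
      rec$distance[i] <- centroidDistance(pc, t$centroid, norm)
    rec$correct[i] <- isCorrect(p, t, tol, norm)
  }
  tallyRow <- function(name, sel) {
    data.frame(class = name, n = sum(sel),
               correct = sum(rec$correct[sel]),
               accuracy = if (sum(sel) > 0) sum(rec$correct[sel]) / sum(sel)
                          else NA_real_)
  }
  summary <- rbind(tallyRow("Positive", rec$truth_present),
                   tallyRow("Negative", !rec$truth_present),
                   tallyRow("Summary", rep(TRUE, n)))
  new("EvalReport", summary = summary, records = rec)
}
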