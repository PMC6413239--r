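# Training losses: a soft Dice loss measuring global mask overlap, a
# pixel-wise binary cross-entropy measuring per-pixel correctness, and
# their weighted combination (weights 1 and beta, beta defaulting to 0.5).
# The Dice intersection/union are relaxed to products and sums so the loss
# is differentiable in the predicted probabilities; epsilon smoothing makes
# the empty-vs-empty case (correct rejection of a negative image) a loss
# of zero rather than 0/0.

checkSameShape <- function(pred, target) {
  if (!all(dim(pred) == dim(target)))
    stop("prediction and target shapes differ: ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(target), collapse = "x"), call. = FALSE)
}

#' Soft Dice loss
#'
#' `1 - (intersection + eps) / (union + eps)` with
#' `intersection = sum(pred * target)` and
#' `union = sum(pred) + sum(target) - intersection`. Equal nonempty binary
#' masks give 0; disjoint nonempty masks give 1; two empty masks give 0.
#'
#' @param pred a [ProbabilityMap-class] or numeric matrix in \[0, 1\].
#' @param target a [LabelMask-class] or 0/1 matrix of the same shape.
#' @param eps smoothing constant (default 1e-6).
#' @return scalar loss in \[0, 1\].
#' @export
diceLoss <- function(pred, target, eps = 1e-6) {
  p <- asPixels(pred); t <- asPixels(target)
  checkSameShape(p, t)
  i <- sum(p * t)
  u <- sum(p) + sum(t) - i
  1 - (i + eps) / (u + eps)
}

#' Pixel-wise binary cross-entropy loss
#'
#' Mean over all N pixels of `-[y log(p) + (1 - y) log(1 - p)]` with
#' predictions clipped to `[eps, 1 - eps]`. Natural logarithm; a uniform
#' 0.5 prediction scores `log(2)` for any binary target.
#'
#' @inheritParams diceLoss
#' @param eps clipping constant (default 1e-7).
#' @return nonnegative scalar.
#' @export
cateLoss <- function(pred, target, eps = 1e-7) {
  p <- asPixels(pred); t <- asPixels(target)
  checkSameShape(p, t)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Combined training loss
#'
#' `diceLoss + beta * cateLoss`, the weighted combination used to train the
#' segmentation network (beta defaults to 0.5).
#'
#' @inheritParams diceLoss
#' @param beta nonnegative weight of the cross-entropy term.
#' @return list with `value`, `dice` and `cate` components.
#' @export
totalLoss <- function(pred, target, beta = 0.5) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("beta must be a nonnegative scalar", call. = FALSE)
  d <- diceLoss(pred, target)
  ce <- cateLoss(pred, target)
  list(value = d + beta * ce, dice = d, cate = ce)
}

# Gradient of the soft Dice loss with respect to the predictions.
diceGrad <- function(p, t, eps = 1e-6) {
  i <- sum(p * t)
  u <- sum(p) + sum(t) - i
  -(t * (u + eps) - (i + eps) * (1 - t)) / (u + eps)^2
}

# Gradient of the combined loss with respect to pre-sigmoid logits, given
# probabilities p = sigmoid(z). The cross-entropy part reduces to
# (p - t) / N, which never saturates.
lossGradLogits <- function(p, t, beta) {
  diceGrad(p, t) * p * (1 - p) + beta * (p - t) / length(p)
}
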