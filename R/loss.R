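# The volumetric training loss and its differentiable surrogate.

asBinaryArray <- function(x) {
  if (is(x, "TruthMask")) return(x@values)
  if (is(x, "PocketPrediction")) return(x@psiHat)
  x
}

#' Volumetric matching loss
#'
#' The loss to be maximized:
#' \deqn{L = \frac{|pred \wedge truth| + k |(1-pred) \wedge (1-truth)|}
#'            {|truth| + k |1 - truth|}}
#' with |.| counting voxels over the whole grid. \code{k = 0} reduces L to
#' the recall of the true pocket; \code{k = 1} to plain voxel accuracy.
#' Intermediate values mitigate the class imbalance between pocket and
#' non-pocket voxels.
#'
#' @param pred Binary prediction (logical array, or a
#'   \linkS4class{PocketPrediction}).
#' @param truth Binary ground truth (logical array or
#'   \linkS4class{TruthMask}).
#' @param k Background weight in [0, 1] (default 0.02).
#' @return Loss value in [0, 1].
#' @export
volumetricLoss <- function(pred, truth, k = 0.02) {
  if (k < 0 || k > 1) geneoStop("geneo_bad_argument", "k must lie in [0, 1]")
  p <- asBinaryArray(pred); t <- asBinaryArray(truth)
  if (!identical(dim(p), dim(t)))
    geneoStop("geneo_bad_argument", "prediction and truth grids differ")
  tv <- sum(t)
  n <- length(t)
  denom <- tv + k * (n - tv)
  if (denom == 0)
    geneoStop("geneo_degenerate_denominator",
              "empty ground truth with k = 0 gives an undefined loss")
  (sum(p & t) + k * sum(!p & !t)) / denom
}

#' Soft (differentiable) binarization
#'
#' Logistic relaxation of the hard threshold,
#' \code{plogis((psi - theta) / temperature)}; converges pointwise to the
#' hard threshold as the temperature goes to 0 (except exactly at theta).
#'
#' @param psi Likelihood field.
#' @param theta Threshold.
#' @param temperature Positive softness scale.
#' @return Field with values in (0, 1).
#' @export
softBinarize <- function(psi, theta, temperature) {
  if (temperature <= 0)
    geneoStop("geneo_bad_argument", "temperature must be > 0")
  out <- plogis((psi - theta) / temperature)
  dim(out) <- dim(psi)
  out
}

# Soft loss on a masked soft prediction s (0 off-mask), plus its gradient
# with respect to s. Internal, used by the trainer.
softLossParts <- function(s, tau, k) {
  tv <- sum(tau)
  n <- length(tau)
  denom <- tv + k * (n - tv)
  val <- (sum(s * tau) + k * sum((1 - s) * (1 - tau))) / denom
  list(value = val, dL_ds = (tau - k * (1 - tau)) / denom)
}
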