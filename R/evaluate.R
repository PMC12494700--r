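# Evaluation against ground truth: overlap, match rank, H/T ranking
# coefficients, centre-distance metrics and success curves.

#' Volumetric overlap with the true pocket
#'
#' @param pocket Voxel set: logical array, or integer voxel indices.
#' @param truth \linkS4class{TruthMask} or logical array.
#' @return |pocket intersect truth| / |truth|, in [0, 1].
#' @export
overlapFraction <- function(pocket, truth) {
  t <- asBinaryArray(truth)
  tv <- sum(t)
  if (tv == 0)
    geneoStop("geneo_degenerate_truth", "empty ground truth")
  inter <- if (is.logical(pocket)) sum(pocket & t) else sum(t[pocket])
  inter / tv
}

#' Rank of the pocket matching the ground truth
#'
#' The matching pocket is the one with the largest overlap (ties: the best,
#' i.e. lowest, rank). When no pocket intersects the truth at all the
#' method failed on this protein and NA is returned.
#'
#' @param prediction A \linkS4class{PocketPrediction}, or a list of voxel
#'   index vectors ordered by rank.
#' @param truth \linkS4class{TruthMask} or logical array.
#' @return Integer rank, or NA on failure.
#' @export
matchRank <- function(prediction, truth) {
  sets <- if (is(prediction, "PocketPrediction")) {
    lapply(prediction@pockets$rank, function(r) pocketVoxels(prediction, r))
  } else prediction
  if (length(sets) == 0L) return(NA_integer_)
  ov <- vapply(sets, overlapFraction, numeric(1), truth = truth)
  if (all(ov == 0)) return(NA_integer_)
  which.max(ov)   # first maximum = lowest rank on ties
}

#' Top-n identification coefficients
#'
#' With n the per-protein number of true pockets, H at j = 0 is the
#' fraction of proteins matched within the first n predicted pockets and H
#' at j >= 1 the fraction matched exactly by the (n+j)-th one; T is the
#' cumulative sum. Failures (no intersecting pocket) enter no bucket and
#' are reported separately, so the buckets plus the failure fraction
#' partition the dataset.
#'
#' @param ranks Integer match ranks, NA for failures.
#' @param n Number of true pockets per protein (scalar or vector).
#' @param maxJ Largest offset j to report (default the largest observed).
#' @return list(H, T, failureFraction, maxJ); H and T are indexed j = 0..maxJ.
#' @export
hTCoefficients <- function(ranks, n = 1, maxJ = NULL) {
  n <- rep_len(n, length(ranks))
  if (any(n < 1)) geneoStop("geneo_bad_argument", "n must be >= 1")
  fail <- is.na(ranks)
  j <- ifelse(fail, NA_integer_, pmax(0L, ranks - n))
  if (is.null(maxJ)) maxJ <- max(0L, j, na.rm = TRUE)
  H <- vapply(0:maxJ, function(jj) mean(!fail & j == jj), numeric(1))
  list(H = H, T = cumsum(H), failureFraction = mean(fail), maxJ = maxJ)
}

#' Distance from the prediction centroid to the ligand (DCA)
#'
#' @param centroid Length-3 pocket centroid.
#' @param ligandCoords Matrix of ligand heavy-atom coordinates.
#' @return Minimal Euclidean distance in Angstrom.
#' @export
dca <- function(centroid, ligandCoords) {
  if (is.null(dim(ligandCoords))) ligandCoords <- rbind(ligandCoords)
  if (nrow(ligandCoords) == 0L)
    geneoStop("geneo_bad_argument", "ligand coordinates are empty")
  min(sqrt(colSums((t(ligandCoords) - as.numeric(centroid))^2)))
}

#' Distance between truth and prediction centroids (DCC)
#'
#' @param truthCentroid,centroid Length-3 centroids.
#' @return Euclidean distance in Angstrom.
#' @export
dcc <- function(truthCentroid, centroid) {
  sqrt(sum((as.numeric(truthCentroid) - as.numeric(centroid))^2))
}

#' Centroid of a truth mask
#'
#' @param truth A \linkS4class{TruthMask}.
#' @return Mean of the occupied voxel centers.
#' @export
truthCentroid <- function(truth) {
  colMeans(voxelCenters(truth@grid)[which(truth@values), , drop = FALSE])
}

#' Success-rate curve over distance thresholds
#'
#' @param values Per-protein distances (DCA or DCC); NA or Inf marks a
#'   failure and never counts as a success.
#' @param thresholds Increasing thresholds in Angstrom (default 4..20).
#' @return Fractions with value strictly below each threshold.
#' @export
successCurve <- function(values, thresholds = 4:20) {
  if (is.unsorted(thresholds))
    geneoStop("geneo_bad_argument", "thresholds must be increasing")
  v <- ifelse(is.na(values), Inf, values)
  vapply(thresholds, function(t) mean(v < t), numeric(1))
}

#' Evaluate a model on labelled examples
#'
#' Runs the detector on each example and assembles the metric suite. The
#' per-protein overlap, DCA and DCC are the best values among the top
#' (n + extraRanks) ranked pockets, mirroring the reporting convention of
#' the ranking analysis.
#'
#' @param model A \linkS4class{GENEOModel}.
#' @param examples List of \code{\link{trainingExample}}s; an example may
#'   carry a \code{ligandCoords} matrix for DCA.
#' @param n True-pocket count per example (scalar or vector, default 1).
#' @param extraRanks How far beyond rank n the reporting looks (default 2).
#' @param thresholds Success-curve thresholds.
#' @return list(perProtein = data.frame, H, T, failureFraction,
#'   dcaCurve, dccCurve).
#' @export
evaluateModel <- function(model, examples, n = 1, extraRanks = 2,
                          thresholds = 4:20) {
  n <- rep_len(n, length(examples))
  rows <- lapply(seq_along(examples), function(q) {
    ex <- examples[[q]]
    pred <- detectPockets(ex$stack, model)
    mr <- matchRank(pred, ex$truth)
    top <- pred@pockets[pred@pockets$rank <= n[q] + extraRanks, ,
                        drop = FALSE]
    ov <- if (nrow(top)) max(vapply(top$rank, function(r)
      overlapFraction(pocketVoxels(pred, r), ex$truth), numeric(1))) else 0
    tc <- truthCentroid(ex$truth)
    lc <- ex$ligandCoords %||% rbind(tc)
    dcaV <- if (nrow(top)) min(vapply(seq_len(nrow(top)), function(i)
      dca(c(top$cx[i], top$cy[i], top$cz[i]), lc), numeric(1))) else NA_real_
    dccV <- if (nrow(top)) min(vapply(seq_len(nrow(top)), function(i)
      dcc(tc, c(top$cx[i], top$cy[i], top$cz[i])), numeric(1))) else NA_real_
    data.frame(id = ex$id %||% as.character(q), n = n[q],
               matchRank = if (is.na(mr)) NA_integer_ else mr,
               overlap = ov, dca = dcaV, dcc = dccV)
  })
  per <- do.call(rbind, rows)
  ht <- hTCoefficients(per$matchRank, n)
  list(perProtein = per, H = ht$H, T = ht$T,
       failureFraction = ht$failureFraction,
       dcaCurve = successCurve(per$dca, thresholds),
       dccCurve = successCurve(per$dcc, thresholds),
       thresholds = thresholds)
}
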