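# The operator pipeline: per-channel convolution, convex combination,
# output normalization, thresholding, labeling, scoring and ranking.

#' Construct a GENEOModel
#'
#' Defaults give the full equivariant, non-expansive variant ("E-NE"): a
#' signed difference-of-Gaussians kernel on the distance channel (so the
#' operator responds to cavity-scale structure), Gaussian kernels elsewhere,
#' uniform convex weights and threshold 0.5.
#'
#' @param sigma Kernel widths in Angstrom (default 2 for every channel).
#' @param alpha Convex weights (default uniform).
#' @param theta Threshold in [0, 1] (default 0.5).
#' @param families Kernel family per channel.
#' @param variant "E-NE" (default), "NE-NE" or "NE-E".
#' @param taps Free kernel taps for the NE variants (list of 8 odd-sized
#'   arrays).
#' @param connectivity Labeling connectivity (default 26).
#' @param volumeRef Score volume scale in voxels (default 30).
#' @param smallVolume "Small pocket" volume threshold in Angstrom^3
#'   (default 100).
#' @return A \linkS4class{GENEOModel}.
#' @examples
#' m <- geneoModel()
#' nParameters(m)  # 17
#' @export
geneoModel <- function(sigma = rep(2, 8), alpha = rep(1, 8) / 8, theta = 0.5,
                       families = c("difference_of_gaussians",
                                    rep("gaussian", 7)),
                       variant = "E-NE", taps = list(),
                       connectivity = 26L, volumeRef = 30,
                       smallVolume = 100) {
  new("GENEOModel", variant = variant, sigma = as.numeric(sigma),
      alpha = as.numeric(alpha), theta = as.numeric(theta),
      families = families, taps = taps,
      connectivity = as.integer(connectivity), volumeRef = volumeRef,
      smallVolume = smallVolume)
}

# Discrete kernels of a model at a given grid spacing. For NE variants the
# stored taps are used; "NE-NE" re-normalizes them to unit L1 norm here.
modelKernels <- function(model, spacing, truncation = 3, radius = NULL) {
  if (model@variant == "E-NE") {
    lapply(seq_len(8), function(i)
      buildKernel(model@families[i], model@sigma[i], spacing, truncation,
                  radius = if (is.null(radius)) NULL else radius[i])$taps)
  } else if (model@variant == "NE-NE") {
    lapply(model@taps, function(t) {
      s <- sum(abs(t))
      if (s == 0) t else t / s
    })
  } else {
    model@taps
  }
}

#' Apply one convolutional operator
#'
#' Same-shape linear convolution with zero padding outside the grid.
#'
#' @param field Numeric 3D array.
#' @param kernel Kernel taps (odd-dimensioned 3D array) or the list returned
#'   by \code{\link{buildKernel}}.
#' @return Filtered array of the same shape.
#' @export
applyGeneo <- function(field, kernel) {
  taps <- if (is.list(kernel)) kernel$taps else kernel
  if (any(dim(taps) > dim(field)))
    geneoStop("geneo_kernel_too_large",
              "kernel (", paste(dim(taps), collapse = "x"),
              ") larger than the grid (",
              paste(dim(field), collapse = "x"), ")")
  out <- cpp_conv3d(field, dim(field), taps, dim(taps))
  dim(out) <- dim(field)
  out
}

#' Convex combination of filtered fields
#'
#' @param fields List of same-shape arrays.
#' @param alpha Convex weights (non-negative, summing to 1 within 1e-9).
#' @return Pointwise weighted sum.
#' @export
convexCombine <- function(fields, alpha) {
  if (any(alpha < -1e-9) || abs(sum(alpha) - 1) > 1e-9)
    geneoStop("geneo_invalid_weights",
              "weights must be non-negative and sum to 1")
  out <- array(0, dim = dim(fields[[1]]))
  for (i in seq_along(fields)) out <- out + alpha[i] * fields[[i]]
  out
}

#' Normalize the combined output to [0, 1]
#'
#' Min-max rescale computed over the empty-space voxels only, then clamped
#' to [0, 1] everywhere; a field constant over the mask maps to 0.5.
#'
#' @param field Combined array.
#' @param mask Logical empty-space mask.
#' @return Array psi with values in [0, 1].
#' @export
normalizeOutput <- function(field, mask) {
  if (!any(mask)) geneoStop("geneo_empty_space", "empty-space mask is empty")
  v <- field[mask]
  lo <- min(v); hi <- max(v)
  out <- if (hi > lo) (field - lo) / (hi - lo)
  else array(0.5, dim = dim(field))
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Threshold the likelihood field
#'
#' @param psi Normalized field.
#' @param theta Threshold in [0, 1].
#' @param mask Logical empty-space mask.
#' @return Logical array: \code{psi > theta} (strictly) and inside the mask.
#' @export
hardThreshold <- function(psi, theta, mask) {
  if (theta < 0 || theta > 1)
    geneoStop("geneo_bad_argument", "theta must lie in [0, 1]")
  out <- (psi > theta) & mask
  dim(out) <- dim(psi)
  out
}

#' Label connected pocket components
#'
#' @param binary Logical array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array; 0 background, components numbered 1..P in scan
#'   order (deterministic).
#' @export
labelPockets <- function(binary, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    geneoStop("geneo_bad_argument", "connectivity must be 6, 18 or 26")
  out <- cpp_label3d(binary, dim(binary), as.integer(connectivity))
  dim(out) <- dim(binary)
  out
}

#' Score and rank pockets
#'
#' Each pocket's score is its mean likelihood adjusted for volume:
#' \code{mean(psi) * (1 - exp(-V / volumeRef))}, which is bounded, increases
#' with volume and preserves mean-psi ordering at equal volume. Ties are
#' broken by larger volume, then lower label.
#'
#' @param psi Normalized likelihood field.
#' @param labels Integer label array.
#' @param volumeRef Volume scale in voxels (default 30).
#' @return data.frame(label, nVoxels, meanPsi, score, rank), ordered by rank.
#' @export
scoreAndRank <- function(psi, labels, volumeRef = 30) {
  labs <- labels[labels > 0]
  if (length(labs) == 0L)
    return(data.frame(label = integer(0), nVoxels = integer(0),
                      meanPsi = numeric(0), score = numeric(0),
                      rank = integer(0)))
  nv <- tabulate(labs)
  ids <- which(nv > 0)
  meanPsi <- vapply(ids, function(l) mean(psi[labels == l]), numeric(1))
  vol <- nv[ids]
  score <- meanPsi * (1 - exp(-vol / volumeRef))
  ord <- order(-score, -vol, ids)
  data.frame(label = ids[ord], nVoxels = vol[ord], meanPsi = meanPsi[ord],
             score = score[ord], rank = seq_along(ord))
}

#' Summarize ranked pockets
#'
#' Adds the webservice-style descriptors: volume in Angstrom^3, centroid
#' (unweighted mean of member voxel centers), equivalent-sphere radius,
#' counts of hydrogen-bond acceptor/donor protein atoms within 4 A of the
#' pocket, mean lipophilicity/hydrophilicity composite, mean polarity and
#' the small-pocket flag.
#'
#' @param ranked data.frame from \code{\link{scoreAndRank}}.
#' @param psi Likelihood field.
#' @param labels Label array.
#' @param stack The normalized \linkS4class{ChannelStack} (for the
#'   lipophilicity/polarity descriptors; may be NULL).
#' @param structure Optional \linkS4class{ParameterizedStructure} for the
#'   HBA/HBD counts.
#' @param smallVolume Threshold in Angstrom^3 (default 100).
#' @param contactDist HBA/HBD contact distance in Angstrom (default 4).
#' @return The ranked table with descriptor columns added.
#' @export
summarizePockets <- function(ranked, psi, labels, stack = NULL,
                             structure = NULL, smallVolume = 100,
                             contactDist = 4) {
  grid <- if (!is.null(stack)) stack@grid else NULL
  s <- if (!is.null(grid)) grid@spacing else 1
  centers <- if (!is.null(grid)) voxelCenters(grid) else NULL
  n <- nrow(ranked)
  out <- ranked
  out$volume <- ranked$nVoxels * s^3
  out$cx <- out$cy <- out$cz <- out$radius <- rep(NA_real_, n)
  out$hba <- out$hbd <- rep(NA_integer_, n)
  out$lipophilicity <- out$polarity <- rep(NA_real_, n)
  out$small <- out$volume < smallVolume
  if (n == 0L) return(out)
  prot <- if (!is.null(structure)) structure@proteinAtoms else NULL
  for (q in seq_len(n)) {
    vox <- which(labels == ranked$label[q])
    if (!is.null(centers)) {
      ctr <- colMeans(centers[vox, , drop = FALSE])
      out$cx[q] <- ctr[1]; out$cy[q] <- ctr[2]; out$cz[q] <- ctr[3]
      out$radius[q] <- (3 * out$volume[q] / (4 * pi))^(1 / 3)
      if (!is.null(prot) && nrow(prot)) {
        pc <- as.matrix(prot[, c("x", "y", "z")])
        d <- cpp_min_dist_each(pc, centers[vox, , drop = FALSE])
        near <- d <= contactDist
        out$hba[q] <- sum(near & prot$hbRole %in% c("acceptor", "both"))
        out$hbd[q] <- sum(near & prot$hbRole %in% c("donor", "both"))
      }
    }
    if (!is.null(stack)) {
      ch <- stack@channels
      out$lipophilicity[q] <- mean((ch$lipophilic[vox] + ch$hydrophilic[vox]) / 2)
      out$polarity[q] <- mean(ch$polar[vox])
    }
  }
  out
}

#' @describeIn detectPockets pipeline on a channel stack
setMethod("detectPockets", signature(stack = "ChannelStack",
                                     model = "GENEOModel"),
          function(stack, model, structure = NULL, truncation = 3, ...) {
  if (!isTRUE(stack@normalized)) stack <- normalizeChannels(stack)
  # cap the stencil so kernels always fit the grid
  cap <- as.integer((min(stack@grid@dims) - 1L) %/% 2L)
  radii <- if (model@variant == "E-NE")
    pmin(vapply(seq_len(8), function(i)
      kernelRadius(model@families[i], model@sigma[i], stack@grid@spacing,
                   truncation), integer(1)), cap)
  else NULL
  kernels <- modelKernels(model, stack@grid@spacing, truncation,
                          radius = radii)
  psiI <- lapply(seq_len(8),
                 function(i) applyGeneo(stack@channels[[i]], kernels[[i]]))
  combined <- convexCombine(psiI, model@alpha)
  psi <- normalizeOutput(combined, stack@emptyMask)
  psiHat <- hardThreshold(psi, model@theta, stack@emptyMask)
  labels <- labelPockets(psiHat, model@connectivity)
  ranked <- scoreAndRank(psi, labels, model@volumeRef)
  pockets <- summarizePockets(ranked, psi, labels, stack, structure,
                              model@smallVolume)
  new("PocketPrediction", grid = stack@grid, psi = psi, psiHat = psiHat,
      labels = labels, pockets = pockets,
      intermediate = list(psiChannels = psiI, combined = combined))
})

#' Predict pockets from a PDB file
#'
#' Convenience wrapper: prepare the structure, compute and normalize the
#' channels, run the model.
#'
#' @param input PDB path or text.
#' @param model A \linkS4class{GENEOModel} (default \code{geneoModel()}).
#' @param ligand Ligand selector passed to \code{\link{prepareStructure}};
#'   use NA for apo structures (no split, no chain filter).
#' @param spacing,padding,cutoff Channel computation parameters.
#' @param ... Passed to \code{\link{computeChannels}}.
#' @return A list with \code{prediction} (\linkS4class{PocketPrediction}),
#'   \code{stack}, and \code{structure}.
#' @export
predictPockets <- function(input, model = geneoModel(), ligand = "AUTO",
                           spacing = 1, padding = 5, cutoff = 10, ...) {
  structure <- if (is.na(ligand)[1]) {
    atoms <- assignParameters(readPDB(input))
    new("ParameterizedStructure", proteinAtoms = atoms,
        ligandAtoms = atoms[0, , drop = FALSE], provenance = list())
  } else prepareStructure(input, ligand)
  stack <- computeChannels(structure, spacing = spacing, padding = padding,
                           cutoff = cutoff, ...)
  pred <- detectPockets(stack, model, structure)
  list(prediction = pred, stack = stack, structure = structure)
}
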