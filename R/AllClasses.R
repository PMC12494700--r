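#' @import methods
#' @importFrom stats plogis qlogis optimize runif rnorm setNames ave
#' @importFrom utils head read.delim read.csv write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib geneopocket, .registration = TRUE
NULL

.CHANNELS <- c("distance", "gravitational", "electrostatic", "lipophilic",
               "hydrophilic", "polar", "hb_acceptor", "hb_donor")

#' Channel names
#'
#' The eight potential channels, in canonical order: distance to the
#' molecular surface, gravitational (mass / d), electrostatic (charge / d),
#' lipophilic and hydrophilic (signed lipophilicity split), polar indicator,
#' and the hydrogen-bond acceptor and donor potentials.
#'
#' @return Character vector of length 8.
#' @export
channelNames <- function() .CHANNELS

# ---------------------------------------------------------------- VoxelGrid

#' VoxelGrid: a cubic-voxel discretization of space
#'
#' Axis-aligned grid of cubic voxels. Voxel \code{(i, j, k)} (0-based)
#' occupies the half-open cube \code{[origin + i*s, origin + (i+1)*s)} and
#' its center is \code{origin + (i + 1/2) * s}.
#'
#' @slot origin Numeric length-3, minimum corner in Angstrom.
#' @slot spacing Single positive numeric, voxel edge in Angstrom.
#' @slot dims Integer length-3, number of voxels per axis.
#' @export
setClass("VoxelGrid",
         representation(origin = "numeric", spacing = "numeric",
                        dims = "integer"))

setValidity("VoxelGrid", function(object) {
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    return("origin must be a finite length-3 numeric")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    return("spacing must be a single positive number")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive integers")
  TRUE
})

#' Construct a VoxelGrid
#'
#' @param origin Minimum corner (length-3 numeric, Angstrom).
#' @param spacing Voxel edge length (Angstrom).
#' @param dims Number of voxels per axis (length-3).
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(c(0, 0, 0), 1, c(4, 4, 4))
#' nVoxels(g)
#' @export
VoxelGrid <- function(origin, spacing, dims) {
  new("VoxelGrid", origin = as.numeric(origin), spacing = as.numeric(spacing),
      dims = as.integer(dims))
}

#' @describeIn VoxelGrid-class grid origin (minimum corner)
#' @param x,object A VoxelGrid.
#' @export
gridOrigin <- function(x) x@origin

#' @describeIn VoxelGrid-class voxel edge length in Angstrom
#' @export
gridSpacing <- function(x) x@spacing

#' @describeIn VoxelGrid-class voxel counts per axis
#' @export
gridDims <- function(x) x@dims

#' @describeIn VoxelGrid-class total number of voxels
#' @export
nVoxels <- function(x) prod(as.numeric(x@dims))

#' Voxel center coordinates
#'
#' @param grid A \linkS4class{VoxelGrid}.
#' @return An \code{nVoxels x 3} matrix of centers, rows in column-major
#'   voxel order (first index fastest).
#' @export
voxelCenters <- function(grid) {
  d <- grid@dims; s <- grid@spacing; o <- grid@origin
  cx <- o[1] + (seq_len(d[1]) - 0.5) * s
  cy <- o[2] + (seq_len(d[2]) - 0.5) * s
  cz <- o[3] + (seq_len(d[3]) - 0.5) * s
  cbind(x = rep(cx, times = d[2] * d[3]),
        y = rep(rep(cy, each = d[1]), times = d[3]),
        z = rep(cz, each = d[1] * d[2]))
}

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dims, collapse = " x "),
      sprintf("voxels, spacing %.3g A, origin (%s)\n", object@spacing,
              paste(sprintf("%.2f", object@origin), collapse = ", ")))
})

# ------------------------------------------------------------- ChannelStack

#' ChannelStack: the eight potential fields on a shared grid
#'
#' @slot grid The shared \linkS4class{VoxelGrid}.
#' @slot channels Named list of eight numeric 3D arrays (see
#'   \code{\link{channelNames}}).
#' @slot emptyMask Logical array, TRUE where the distance channel is
#'   non-negative before normalization (empty space around the protein).
#' @slot normalization data.frame with per-channel min/max recorded when the
#'   stack was min-max rescaled; zero rows for a raw stack.
#' @slot normalized Logical flag.
#' @export
setClass("ChannelStack",
         representation(grid = "VoxelGrid", channels = "list",
                        emptyMask = "array", normalization = "data.frame",
                        normalized = "logical"))

setValidity("ChannelStack", function(object) {
  d <- object@grid@dims
  if (length(object@channels) != 8L ||
      !identical(names(object@channels), .CHANNELS))
    return("channels must be the 8 canonical fields, in order")
  for (nm in .CHANNELS) {
    v <- object@channels[[nm]]
    if (!identical(dim(v), d))
      return(sprintf("channel '%s' does not match the grid dims", nm))
  }
  if (!identical(dim(object@emptyMask), d))
    return("emptyMask does not match the grid dims")
  if (isTRUE(object@normalized)) {
    rng <- range(unlist(lapply(object@channels, range)))
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      return("normalized stack has values outside [0, 1]")
  }
  TRUE
})

#' @describeIn ChannelStack-class the shared grid
#' @param x,object A ChannelStack.
#' @export
stackGrid <- function(x) x@grid

#' @describeIn ChannelStack-class named list of channel arrays
#' @export
stackChannels <- function(x) x@channels

#' @describeIn ChannelStack-class logical empty-space mask array
#' @export
emptySpaceMask <- function(x) x@emptyMask

#' @describeIn ChannelStack-class TRUE once min-max normalized
#' @export
isNormalized <- function(x) isTRUE(x@normalized)

setMethod("show", "ChannelStack", function(object) {
  cat("ChannelStack (", if (object@normalized) "normalized" else "raw",
      "): ", paste(object@grid@dims, collapse = " x "),
      " voxels, ", sum(object@emptyMask), " in empty space\n", sep = "")
})

# ---------------------------------------------------------------- TruthMask

#' TruthMask: binary ground-truth pocket occupancy
#'
#' Voxels overlapping the co-crystallized ligand (heavy atoms, van der Waals
#' spheres) are 1, all others 0.
#'
#' @slot grid The \linkS4class{VoxelGrid}.
#' @slot values Logical 3D array.
#' @export
setClass("TruthMask",
         representation(grid = "VoxelGrid", values = "array"))

setValidity("TruthMask", function(object) {
  if (!identical(dim(object@values), object@grid@dims))
    return("values do not match the grid dims")
  if (!is.logical(object@values))
    return("values must be logical")
  TRUE
})

#' @describeIn TruthMask-class logical occupancy array
#' @param x,object A TruthMask.
#' @export
maskValues <- function(x) x@values

setMethod("show", "TruthMask", function(object) {
  cat("TruthMask:", sum(object@values), "of", nVoxels(object@grid),
      "voxels occupied\n")
})

# --------------------------------------------------------------- GENEOModel

#' GENEOModel: the operator layer, convex weights and threshold
#'
#' Holds the 17 learnable parameters of the full equivariant model: one
#' kernel width \code{sigma} per channel, the convex combination weights
#' \code{alpha} (on the simplex) and the pocket threshold \code{theta}.
#' The ablation variants \code{"NE-NE"} and \code{"NE-E"} replace the
#' radially symmetric parametric kernels with free taps (slot \code{taps});
#' \code{"NE-NE"} re-normalizes the taps to unit L1 norm in the forward
#' pass, \code{"NE-E"} uses them as-is.
#'
#' @slot variant One of "E-NE", "NE-NE", "NE-E".
#' @slot sigma Kernel widths in Angstrom (length 8).
#' @slot alpha Convex weights (length 8, non-negative, sums to 1).
#' @slot theta Threshold in [0, 1].
#' @slot families Kernel family per channel ("gaussian",
#'   "difference_of_gaussians" or "spherical_shell"); fixed, not learned.
#' @slot taps Free kernel taps for the NE variants (list of 8 arrays), empty
#'   for "E-NE".
#' @slot connectivity Voxel connectivity for pocket labeling (6, 18 or 26).
#' @slot volumeRef Volume scale (voxels) of the score adjustment.
#' @slot smallVolume Volume (Angstrom^3) below which a pocket is flagged
#'   small.
#' @export
setClass("GENEOModel",
         representation(variant = "character", sigma = "numeric",
                        alpha = "numeric", theta = "numeric",
                        families = "character", taps = "list",
                        connectivity = "integer", volumeRef = "numeric",
                        smallVolume = "numeric"))

setValidity("GENEOModel", function(object) {
  if (!object@variant %in% c("E-NE", "NE-NE", "NE-E"))
    return("variant must be one of E-NE, NE-NE, NE-E")
  if (length(object@sigma) != 8L || any(object@sigma <= 0))
    return("sigma must be 8 positive widths")
  if (length(object@alpha) != 8L || any(object@alpha < -1e-9) ||
      abs(sum(object@alpha) - 1) > 1e-9)
    return("alpha must be 8 non-negative weights summing to 1")
  if (length(object@theta) != 1L || object@theta < 0 || object@theta > 1)
    return("theta must lie in [0, 1]")
  if (length(object@families) != 8L ||
      !all(object@families %in% c("gaussian", "difference_of_gaussians",
                                  "spherical_shell")))
    return("families must be 8 known kernel families")
  if (object@variant != "E-NE" && length(object@taps) != 8L)
    return("NE variants require 8 free kernels in taps")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  TRUE
})

setMethod("show", "GENEOModel", function(object) {
  cat("GENEOModel [", object@variant, "]\n", sep = "")
  cat("  sigma:", paste(sprintf("%.3f", object@sigma), collapse = " "), "\n")
  cat("  alpha:", paste(sprintf("%.3f", object@alpha), collapse = " "), "\n")
  cat(sprintf("  theta: %.3f   connectivity: %d\n", object@theta,
              object@connectivity))
})

# ---------------------------------------------------------- PocketPrediction

#' PocketPrediction: model output on one channel stack
#'
#' @slot grid The \linkS4class{VoxelGrid}.
#' @slot psi Normalized pocket-likelihood field in [0, 1].
#' @slot psiHat Logical array: psi > theta restricted to empty space.
#' @slot labels Integer array, 0 background, 1..P pocket ids (component
#'   labels, not ranks).
#' @slot pockets data.frame of ranked pockets (rank, label, nVoxels, volume,
#'   meanPsi, score, centroid, radius, hba, hbd, lipophilicity, polarity,
#'   small).
#' @slot intermediate List with the per-channel filtered fields (psi_i) and
#'   the pre-normalization combination, kept for diagnostics.
#' @export
setClass("PocketPrediction",
         representation(grid = "VoxelGrid", psi = "array", psiHat = "array",
                        labels = "array", pockets = "data.frame",
                        intermediate = "list"))

#' @describeIn PocketPrediction-class ranked pocket table
#' @param x,object A PocketPrediction.
#' @export
pocketTable <- function(x) x@pockets

#' @describeIn PocketPrediction-class integer label array (0 = background)
#' @export
pocketLabels <- function(x) x@labels

#' @describeIn PocketPrediction-class normalized likelihood field
#' @export
pocketField <- function(x) x@psi

#' Voxel indices of one ranked pocket
#'
#' @param x A \linkS4class{PocketPrediction}.
#' @param rank Pocket rank (1 = top).
#' @return Integer vector of linear voxel indices.
#' @export
pocketVoxels <- function(x, rank) {
  p <- x@pockets[x@pockets$rank == rank, , drop = FALSE]
  if (nrow(p) == 0L) stop("no pocket with rank ", rank)
  which(x@labels == p$label[1])
}

setMethod("show", "PocketPrediction", function(object) {
  cat("PocketPrediction:", nrow(object@pockets), "pocket(s)\n")
  if (nrow(object@pockets) > 0)
    print(head(object@pockets[, c("rank", "score", "volume", "meanPsi")], 5))
})

# ------------------------------------------------------------------ FitResult

#' FitResult: outcome of one training run
#'
#' @slot model The fitted \linkS4class{GENEOModel}.
#' @slot trainLoss Per-epoch mean hard-threshold loss on the training set.
#' @slot heldoutLoss Per-epoch mean hard-threshold loss on held-out examples
#'   (length 0 when none were supplied).
#' @slot seed Integer seed used.
#' @slot config Echo of the training configuration.
#' @export
setClass("FitResult",
         representation(model = "GENEOModel", trainLoss = "numeric",
                        heldoutLoss = "numeric", seed = "integer",
                        config = "list"))

#' @describeIn FitResult-class the fitted model
#' @param x,object A FitResult.
#' @export
fittedModel <- function(x) x@model

#' @describeIn FitResult-class per-epoch training loss history
#' @export
lossHistory <- function(x) x@trainLoss

setMethod("show", "FitResult", function(object) {
  n <- length(object@trainLoss)
  cat(sprintf("FitResult [%s]: %d epochs, final train loss %.4f",
              object@model@variant, n,
              if (n) object@trainLoss[n] else NA_real_))
  if (length(object@heldoutLoss))
    cat(sprintf(", held-out %.4f", object@heldoutLoss[n]))
  cat("\n")
})

# ----------------------------------------------------------------- generics

#' Detect and rank pockets on a channel stack
#'
#' Runs the operator pipeline: per-channel convolution with the model's
#' kernels, convex combination, min-max normalization over empty space,
#' thresholding at theta, connected-component labeling and volume-adjusted
#' scoring.
#'
#' @param stack A \linkS4class{ChannelStack} (normalized; a raw stack is
#'   normalized on the fly).
#' @param model A \linkS4class{GENEOModel}.
#' @param structure Optional parameterized structure used for the HBA/HBD
#'   pocket descriptors.
#' @param ... Unused.
#' @return A \linkS4class{PocketPrediction}.
#' @export
setGeneric("detectPockets",
           function(stack, model, structure = NULL, ...)
             standardGeneric("detectPockets"))

#' Named learnable parameters of a model
#'
#' For the full equivariant model this is the named vector of the 17
#' learnable parameters: \code{sigma1..sigma8}, \code{alpha1..alpha8} and
#' \code{theta}. For the NE ablation variants the free kernel taps replace
#' the sigmas.
#'
#' @param object A \linkS4class{GENEOModel}.
#' @return Named numeric vector.
#' @export
setGeneric("modelParameters",
           function(object) standardGeneric("modelParameters"))

#' @describeIn modelParameters number of learnable parameters
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @describeIn modelParameters number of operators in the layer
#' @export
setGeneric("nOperators", function(object) standardGeneric("nOperators"))

setMethod("modelParameters", "GENEOModel", function(object) {
  if (object@variant == "E-NE") {
    c(setNames(object@sigma, paste0("sigma", 1:8)),
      setNames(object@alpha, paste0("alpha", 1:8)),
      theta = object@theta)
  } else {
    taps <- unlist(lapply(seq_along(object@taps), function(i) {
      t <- as.numeric(object@taps[[i]])
      setNames(t, paste0("K", i, "_", seq_along(t)))
    }))
    c(taps, setNames(object@alpha, paste0("alpha", 1:8)),
      theta = object@theta)
  }
})

setMethod("nParameters", "GENEOModel",
          function(object) length(modelParameters(object)))

setMethod("nOperators", "GENEOModel", function(object) length(object@families))
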