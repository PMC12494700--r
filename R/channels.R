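# The eight potential channels on the voxel grid, their normalization, and
# the ligand ground-truth mask.

#' Per-atom hydrogen-bond radial term
#'
#' The acceptor-style well \code{-eps * (R^6 - 2 R^4)} with reduced distance
#' \code{R = rmin / d + 0.96}; \code{d} is clamped below at \code{dmin} and
#' \code{R} capped at \code{rcap} to bound the steric singularity at voxels
#' inside atoms. The attractive branch is untouched by the cap: the term
#' peaks at \code{32/27 * eps} at \code{R = sqrt(4/3)} and vanishes at
#' \code{R = sqrt(2)}.
#'
#' @param d Distance(s) in Angstrom.
#' @param eps Well depth (default 1).
#' @param rmin Well position parameter in Angstrom (default 1.9).
#' @param dmin Lower distance clamp (default 0).
#' @param rcap Cap on the reduced distance R (default 2).
#' @return Numeric vector of per-atom terms.
#' @export
hbAcceptorTerm <- function(d, eps = 1, rmin = 1.9, dmin = 0, rcap = 2) {
  d <- pmax(d, dmin)
  R <- pmin(rmin / d + 0.96, rcap)
  -eps * (R^6 - 2 * R^4)
}

.coordsOf <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Compute the eight potential channels
#'
#' Evaluates, at every voxel center, the distance-to-surface potential
#' (signed distance to the nearest atom sphere), the inverse-distance sums
#' weighted by mass, partial charge, the negative (lipophilic) and positive
#' (hydrophilic) parts of the lipophilicity coefficient and the polarity
#' indicator, and the hydrogen-bond acceptor and donor potentials. The
#' inverse-distance and hydrogen-bond sums run over atoms within
#' \code{cutoff} of the voxel, with distances clamped below at
#' \code{spacing / 2}. The empty-space mask is the set of voxels whose
#' distance channel is non-negative.
#'
#' @param structure A \linkS4class{ParameterizedStructure}, or a
#'   parameterized protein atom table.
#' @param grid A \linkS4class{VoxelGrid}; built from the protein with
#'   \code{spacing}/\code{padding} when NULL.
#' @param spacing,padding Grid construction parameters (defaults 1 A, 5 A),
#'   used only when \code{grid} is NULL.
#' @param cutoff Neighborhood radius for the sum channels (default 10 A).
#' @param rcap Cap on the hydrogen-bond reduced distance (default 2).
#' @param normalize Min-max normalize the stack (default TRUE).
#' @param cubic Passed to \code{\link{buildGrid}} when the grid is built
#'   here.
#' @return A \linkS4class{ChannelStack}.
#' @export
computeChannels <- function(structure, grid = NULL, spacing = 1, padding = 5,
                            cutoff = 10, rcap = 2, normalize = TRUE,
                            cubic = FALSE) {
  atoms <- if (is(structure, "ParameterizedStructure"))
    structure@proteinAtoms else structure
  if (is.null(atoms) || nrow(atoms) == 0L)
    geneoStop("geneo_empty_structure", "no protein atoms")
  if (is.null(grid)) grid <- buildGrid(atoms, spacing, padding, cubic = cubic)
  if (cutoff <= 0) geneoStop("geneo_bad_argument", "cutoff must be > 0")
  s <- grid@spacing
  dmin <- s / 2
  co <- .coordsOf(atoms)
  org <- grid@origin; dims <- grid@dims

  phi1 <- cpp_distance_field(co, atoms$vdw, org, s, dims)
  mask <- array(phi1 >= 0, dim = dims)
  inv <- function(coef) cpp_invdist_field(co, coef, org, s, dims, cutoff, dmin)
  phi2 <- inv(atoms$mass)
  phi3 <- inv(atoms$charge)
  phi4 <- inv(pmin(atoms$lipo, 0))
  phi5 <- inv(pmax(atoms$lipo, 0))
  phi6 <- inv(as.numeric(atoms$polar))

  acc <- atoms$hbRole %in% c("acceptor", "both")
  phi7 <- if (any(acc))
    cpp_hb_acceptor_field(co[acc, , drop = FALSE], atoms$hbEps[acc],
                          atoms$hbRmin[acc], org, s, dims, cutoff, dmin, rcap)
  else array(0, dim = dims)

  don <- which(atoms$hbRole %in% c("donor", "both") &
                 vapply(atoms$donorH, function(h) !is.null(h) && nrow(h) > 0,
                        logical(1)))
  if (length(don)) {
    hyd <- do.call(rbind, atoms$donorH[don])
    nH <- vapply(atoms$donorH[don], nrow, integer(1))
    hydStart <- c(0L, cumsum(nH))
    hasAnt <- vapply(atoms$antecedent[don], Negate(is.null), logical(1))
    ants <- t(vapply(atoms$antecedent[don],
                     function(a) if (is.null(a)) c(0, 0, 0) else a,
                     numeric(3)))
    phi8 <- cpp_hb_donor_field(co[don, , drop = FALSE], atoms$hbEps[don],
                               atoms$hbRmin[don], ants, hasAnt, hyd,
                               hydStart, org, s, dims, cutoff, dmin, rcap)
  } else phi8 <- array(0, dim = dims)

  chans <- list(phi1, phi2, phi3, phi4, phi5, phi6, phi7, phi8)
  chans <- lapply(chans, function(v) { dim(v) <- dims; v })
  names(chans) <- .CHANNELS
  stack <- new("ChannelStack", grid = grid, channels = chans,
               emptyMask = mask,
               normalization = data.frame(channel = character(0),
                                          min = numeric(0), max = numeric(0)),
               normalized = FALSE)
  if (normalize) normalizeChannels(stack) else stack
}

#' Min-max normalize a channel stack
#'
#' Each channel is rescaled to [0, 1] over the whole grid, independently per
#' structure; a constant channel maps to the constant 0.5. Optional
#' per-channel orientation flips (value -> 1 - value) can be requested for
#' channels whose polarity should be inverted before entering the convex
#' combination.
#'
#' @param stack A raw \linkS4class{ChannelStack}.
#' @param flip Character vector of channel names to flip (default none).
#' @return The normalized stack, with per-channel min/max recorded.
#' @export
normalizeChannels <- function(stack, flip = character(0)) {
  bad <- names(which(!vapply(stack@channels,
                             function(v) all(is.finite(v)), logical(1))))
  if (length(bad))
    geneoStop("geneo_invalid_field",
              "non-finite values in channel(s): ", paste(bad, collapse = ", "))
  rec <- data.frame(channel = .CHANNELS, min = NA_real_, max = NA_real_,
                    flipped = .CHANNELS %in% flip)
  chans <- stack@channels
  for (i in seq_along(chans)) {
    v <- chans[[i]]
    lo <- min(v); hi <- max(v)
    rec$min[i] <- lo; rec$max[i] <- hi
    v <- if (hi > lo) (v - lo) / (hi - lo) else array(0.5, dim = dim(v))
    if (rec$flipped[i]) v <- 1 - v
    chans[[i]] <- v
  }
  initialize(stack, channels = chans, normalization = rec, normalized = TRUE)
}

#' Ground-truth mask from the ligand
#'
#' A voxel is marked 1 exactly when the van der Waals sphere of some ligand
#' heavy atom overlaps the voxel's cube (exact sphere-box intersection;
#' tangency does not count, and a zero-radius atom marks only the half-open
#' cube that owns it).
#'
#' @param ligand Parameterized ligand atom table, or a
#'   \linkS4class{ParameterizedStructure}.
#' @param grid The \linkS4class{VoxelGrid}.
#' @return A \linkS4class{TruthMask}.
#' @export
ligandTruthMask <- function(ligand, grid) {
  if (is(ligand, "ParameterizedStructure")) ligand <- ligand@ligandAtoms
  lig <- ligand[toupper(ligand$element) != "H", , drop = FALSE]
  if (nrow(lig) == 0L)
    geneoStop("geneo_empty_truth", "ligand has no heavy atoms")
  v <- cpp_truth_mask(.coordsOf(lig), lig$vdw, grid@origin, grid@spacing,
                      grid@dims)
  dim(v) <- grid@dims
  if (!any(v))
    geneoStop("geneo_empty_truth", "ligand lies entirely outside the grid")
  new("TruthMask", grid = grid, values = v)
}
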