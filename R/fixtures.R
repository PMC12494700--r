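# Deterministic synthetic inputs: shell "proteins" enclosing a cavity with
# a small ligand inside (valid PDB), phantom channel stacks with a known
# pocket, and model-generated training sets for parameter recovery.

#' Specification of a synthetic shell complex
#'
#' A quasi-uniform spherical shell of atoms with an opening cap (the pocket
#' mouth) and a small ligand cluster at the center. Elements are drawn as
#' roughly 70/15/15 C/N/O so that all eight channels are non-degenerate;
#' part of the N/O shell atoms carry an inward-pointing bonded hydrogen to
#' populate the donor channel.
#'
#' @param seed Integer seed; the fixture is byte-deterministic per seed.
#' @param shellRadius Shell radius in Angstrom (default 8).
#' @param openingHalfAngle Half-angle of the opening cap in degrees
#'   (default 35).
#' @param atomSpacing Approximate atom spacing on the shell in Angstrom
#'   (default 1.8).
#' @param ligandAtoms Number of ligand heavy atoms (default 5).
#' @param randomOrientation Apply a seeded random rigid rotation
#'   (default FALSE).
#' @param hydrogenFraction Fraction of N/O shell atoms given a bonded
#'   hydrogen (default 0.5).
#' @return list of settings.
#' @export
shellComplexSpec <- function(seed = 1L, shellRadius = 8,
                             openingHalfAngle = 35, atomSpacing = 1.8,
                             ligandAtoms = 5, randomOrientation = FALSE,
                             hydrogenFraction = 0.5) {
  list(seed = as.integer(seed), shellRadius = shellRadius,
       openingHalfAngle = openingHalfAngle, atomSpacing = atomSpacing,
       ligandAtoms = ligandAtoms, randomOrientation = randomOrientation,
       hydrogenFraction = hydrogenFraction)
}

.LIGAND_DIRS <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
                      c(1, 1, -1), c(-1, -1, -1), c(1, -1, 1),
                      c(-1, 1, 1)) / sqrt(3)

#' Generate a shell protein-ligand complex as PDB text
#'
#' @param spec A \code{\link{shellComplexSpec}}.
#' @param file Optional path to write the PDB to.
#' @return Character vector of PDB lines (invisibly when written to file).
#' @export
makeShellComplex <- function(spec = shellComplexSpec(), file = NULL) {
  R <- spec$shellRadius
  ligExtent <- 1.4 + 1.7   # bond length + vdW of the outermost ligand atom
  if (R <= ligExtent + 2)
    geneoStop("geneo_bad_spec",
              "shellRadius must exceed the ligand extent + 2 A")
  if (spec$ligandAtoms < 1 || spec$ligandAtoms > nrow(.LIGAND_DIRS) + 1)
    geneoStop("geneo_bad_spec", "ligandAtoms must be between 1 and ",
              nrow(.LIGAND_DIRS) + 1)
  n <- max(50L, as.integer(round(4 * pi * R^2 / spec$atomSpacing^2)))
  atoms <- withSeed(spec$seed, {
    # Fibonacci sphere, cap removed
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    rho <- sqrt(pmax(0, 1 - z^2))
    ga <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
    u <- cbind(rho * cos(ga), rho * sin(ga), z)
    keep <- z < cos(spec$openingHalfAngle * pi / 180)
    u <- u[keep, , drop = FALSE]
    if (nrow(u) < 50L)
      geneoStop("geneo_bad_spec", "opening too wide: fewer than 50 atoms")
    rad <- R + runif(nrow(u), -0.15, 0.15)
    shell <- u * rad
    el <- sample(c("C", "N", "O"), nrow(u), replace = TRUE,
                 prob = c(0.70, 0.15, 0.15))
    # inward-pointing hydrogens on a fraction of the N/O atoms
    hooks <- which(el %in% c("N", "O") &
                     runif(nrow(u)) < spec$hydrogenFraction)
    hcoords <- shell[hooks, , drop = FALSE] -
      u[hooks, , drop = FALSE] * 1.0
    lig <- rbind(c(0, 0, 0),
                 .LIGAND_DIRS[seq_len(spec$ligandAtoms - 1), , drop = FALSE] * 1.4)
    ligEl <- rep_len(c("C", "N", "O", "C", "C", "O", "N", "C", "C"),
                     spec$ligandAtoms)
    ligName <- paste0(ligEl, ave(seq_along(ligEl), ligEl, FUN = seq_along))
    co <- rbind(shell, hcoords, lig)
    if (spec$randomOrientation) {
      M <- matrix(rnorm(9), 3, 3)
      qr_ <- qr(M)
      Q <- qr.Q(qr_)
      if (det(Q) < 0) Q[, 1] <- -Q[, 1]
      co <- co %*% t(Q)
    }
    ns <- nrow(shell); nh <- nrow(hcoords)
    data.frame(
      record = c(rep("ATOM", ns + nh), rep("HETATM", spec$ligandAtoms)),
      serial = seq_len(ns + nh + spec$ligandAtoms),
      name = c(el, rep("H", nh), ligName),
      resid = c(rep("GLY", ns + nh), rep("LIG", spec$ligandAtoms)),
      chain = "A",
      resno = c(seq_len(ns), hooks, rep(ns + 1L, spec$ligandAtoms)),
      x = co[, 1], y = co[, 2], z = co[, 3],
      occ = 1,
      element = c(el, rep("H", nh), ligEl),
      stringsAsFactors = FALSE)
  })
  # hydrogens must sit in the residue of their heavy atom for bonding to be
  # chemically sensible; order rows by residue number, then re-serial
  atoms <- atoms[order(atoms$record == "HETATM", atoms$resno,
                       atoms$name == "H"), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  writePDB(atoms, file)
}

#' Specification of a phantom channel stack
#'
#' Each channel is \code{signal * indicator(pocket ball) + Gaussian noise},
#' then min-max normalized; the truth mask is a concentric ball.
#'
#' @param seed Integer seed.
#' @param dims Grid dims (default 12^3).
#' @param spacing Voxel edge (default 1 A).
#' @param center Ball center in voxel units (default grid center).
#' @param radius Ball radius in voxels (default 3).
#' @param signal Per-channel signal level (length 8, recycled).
#' @param noise Gaussian noise standard deviation (default 0.1).
#' @param truthRadius Truth ball radius in voxels (default = radius).
#' @param channelCenters Optional 8 x 3 matrix of per-channel ball centers
#'   in voxel units; when given, channel i's signal sits on its own ball,
#'   making the convex weights identifiable from data. Default: all
#'   channels share \code{center}.
#' @return list of settings.
#' @export
phantomSpec <- function(seed = 1L, dims = c(12L, 12L, 12L), spacing = 1,
                        center = NULL, radius = 3, signal = 1, noise = 0.1,
                        truthRadius = radius, channelCenters = NULL) {
  if (noise < 0) geneoStop("geneo_bad_spec", "noise must be >= 0")
  dims <- as.integer(dims)
  if (is.null(center)) center <- dims / 2
  ctrs <- if (is.null(channelCenters))
    matrix(center, 8, 3, byrow = TRUE) else channelCenters
  for (i in seq_len(nrow(ctrs)))
    if (any(ctrs[i, ] - radius < 0) || any(ctrs[i, ] + radius > dims))
      geneoStop("geneo_bad_spec",
                "pocket ball must lie strictly inside the grid")
  list(seed = as.integer(seed), dims = dims, spacing = spacing,
       center = center, radius = radius,
       signal = rep_len(signal, 8), noise = noise,
       truthRadius = truthRadius, channelCenters = ctrs)
}

ballIndicator <- function(grid, centerVox, radiusVox) {
  ctr <- grid@origin + centerVox * grid@spacing
  cc <- voxelCenters(grid)
  ind <- sqrt(colSums((t(cc) - ctr)^2)) <= radiusVox * grid@spacing
  array(ind, dim = grid@dims)
}

#' Generate a phantom channel stack with known truth
#'
#' @param spec A \code{\link{phantomSpec}}.
#' @return list(stack = \linkS4class{ChannelStack},
#'   truth = \linkS4class{TruthMask}).
#' @export
makePhantomChannels <- function(spec = phantomSpec()) {
  grid <- VoxelGrid(c(0, 0, 0), spec$spacing, spec$dims)
  chans <- withSeed(spec$seed, {
    lapply(seq_len(8), function(i) {
      ind <- ballIndicator(grid, spec$channelCenters[i, ], spec$radius)
      v <- spec$signal[i] * ind
      if (spec$noise > 0) v <- v + rnorm(length(ind), sd = spec$noise)
      array(v, dim = spec$dims)
    })
  })
  names(chans) <- .CHANNELS
  stack <- new("ChannelStack", grid = grid, channels = chans,
               emptyMask = array(TRUE, dim = spec$dims),
               normalization = data.frame(channel = character(0),
                                          min = numeric(0),
                                          max = numeric(0)),
               normalized = FALSE)
  truth <- new("TruthMask", grid = grid,
               values = ballIndicator(grid, spec$center, spec$truthRadius))
  list(stack = normalizeChannels(stack), truth = truth)
}

#' Generate training examples from a known model
#'
#' Draws random phantom stacks, runs the full equivariant pipeline with the
#' given parameters and takes the top-scoring pocket's voxel set as the
#' ground truth, which makes the generating model a strong (usually near-
#' optimal, but recorded rather than assumed) reference for recovery
#' experiments.
#'
#' @param model The generating \linkS4class{GENEOModel}.
#' @param nExamples Number of examples.
#' @param seed Integer seed.
#' @param dims,spacing,noise Phantom geometry and noise.
#' @param signalRange Per-channel signal levels drawn uniformly from this
#'   range.
#' @param radiusRange Pocket ball radius range in voxels.
#' @return List of \code{\link{trainingExample}}s; the generating model's
#'   per-example hard-threshold loss is recorded in
#'   \code{attr(, "generatorLoss")}.
#' @export
generateFromModel <- function(model, nExamples, seed = 1L,
                              dims = c(12L, 12L, 12L), spacing = 1,
                              noise = 0.1, signalRange = c(0.6, 1.4),
                              radiusRange = c(2.2, 3.2)) {
  if (nExamples < 1)
    geneoStop("geneo_bad_argument", "nExamples must be >= 1")
  dims <- as.integer(dims)
  out <- vector("list", nExamples)
  losses <- numeric(nExamples)
  fails <- 0L
  withSeed(seed, {
    q <- 1L
    attempts <- 0L
    while (q <= nExamples) {
      attempts <- attempts + 1L
      if (fails > max(nExamples, attempts / 2))
        geneoStop("geneo_degenerate_generator",
                  "model produced no pockets on more than half of the draws")
      margin <- max(radiusRange) + 1
      ctrs <- matrix(runif(24, margin, rep(dims, each = 8) - margin), 8, 3)
      sp <- phantomSpec(seed = sample.int(2^30, 1),
                        dims = dims, spacing = spacing, center = ctrs[1, ],
                        radius = runif(1, radiusRange[1], radiusRange[2]),
                        signal = runif(8, signalRange[1], signalRange[2]),
                        noise = noise, channelCenters = ctrs)
      ph <- makePhantomChannels(sp)
      pred <- detectPockets(ph$stack, model)
      if (nrow(pred@pockets) == 0L) { fails <- fails + 1L; next }
      truth <- new("TruthMask", grid = ph$stack@grid,
                   values = array(pred@labels == pred@pockets$label[1],
                                  dim = dims))
      losses[q] <- volumetricLoss(pred@psiHat, truth@values, k = 0.02)
      out[[q]] <- trainingExample(ph$stack, truth,
                                  id = sprintf("model-gen-%03d", q))
      q <- q + 1L
    }
  })
  attr(out, "generatorLoss") <- losses
  out
}
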