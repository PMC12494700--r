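# Grid construction around a structure.

#' Build a voxel grid covering a structure
#'
#' The grid covers the axis-aligned bounding box of the atoms (centers
#' expanded by their van der Waals radii) plus \code{padding} on every side;
#' the voxel count per axis is \code{ceiling(extent / spacing)}.
#'
#' @param atoms A parameterized atom data.frame (needs columns x, y, z and
#'   vdw), or any data.frame with x, y, z (radius then taken as 0).
#' @param spacing Voxel edge length in Angstrom (default 1).
#' @param padding Extra margin in Angstrom on all sides (default 5).
#' @param maxVoxels Guard against runaway grids (default 2e7 voxels).
#' @param cubic If TRUE, pad dims up to a cube (equal voxel counts per
#'   axis, extra voxels split symmetrically); useful for the 90-degree
#'   rotation group, which maps a cubic grid onto itself.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' atoms <- data.frame(x = 0, y = 0, z = 0, vdw = 1.5)
#' buildGrid(atoms, spacing = 1, padding = 2.5)  # 8 x 8 x 8
#' @export
buildGrid <- function(atoms, spacing = 1, padding = 5, maxVoxels = 2e7,
                      cubic = FALSE) {
  if (spacing <= 0) geneoStop("geneo_bad_argument", "spacing must be > 0")
  if (padding < 0) geneoStop("geneo_bad_argument", "padding must be >= 0")
  if (is.null(atoms) || nrow(atoms) == 0L)
    geneoStop("geneo_empty_structure", "cannot build a grid with no atoms")
  r <- if ("vdw" %in% names(atoms)) atoms$vdw else rep(0, nrow(atoms))
  lo <- c(min(atoms$x - r), min(atoms$y - r), min(atoms$z - r)) - padding
  hi <- c(max(atoms$x + r), max(atoms$y + r), max(atoms$z + r)) + padding
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing - 1e-9)))
  origin <- lo
  if (cubic) {
    n <- max(dims)
    extra <- n - dims
    origin <- origin - (extra * spacing) / 2
    dims <- rep(n, 3L)
  }
  if (prod(as.numeric(dims)) > maxVoxels)
    geneoStop("geneo_grid_too_large",
              "grid of ", paste(dims, collapse = "x"),
              " voxels exceeds the cap of ", format(maxVoxels), " voxels")
  VoxelGrid(origin, spacing, dims)
}
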