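# The proper 90-degree rotation group of the cubic grid (24 elements),
# used to verify equivariance: radially symmetric kernels commute with
# these rotations exactly on the lattice.

#' The 24 proper axis-aligned rotations
#'
#' @return List of 24 integer 3x3 matrices with determinant +1 (signed
#'   permutation matrices).
#' @export
gridRotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    P <- diag(3)[p, , drop = FALSE]
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      R <- diag(c(s1, s2, s3)) %*% P
      if (round(det(R)) == 1) out[[length(out) + 1L]] <- R
    }
  }
  out
}

#' Rotate a cubic field about the grid center
#'
#' Applies \code{B[R (v - c) + c] = A[v]} on 0-based voxel indices with
#' \code{c = (n - 1) / 2}; the signed-permutation rotations map voxel
#' centers to voxel centers exactly, so the operation is a pure relabeling.
#'
#' @param arr Cubic 3D array (equal dims).
#' @param R A rotation matrix from \code{\link{gridRotations}}.
#' @return The rotated array.
#' @export
rotateField <- function(arr, R) {
  d <- dim(arr)
  if (length(unique(d)) != 1L)
    geneoStop("geneo_bad_argument", "rotateField requires a cubic array")
  m <- d[1]
  ax <- 0:(m - 1)
  idx <- cbind(rep(ax, times = m * m),
               rep(rep(ax, each = m), times = m),
               rep(ax, each = m * m))
  ctr <- (m - 1) / 2
  dest <- sweep(sweep(idx, 2, ctr) %*% t(R), 2, ctr, "+")
  lin <- round(dest[, 1]) + m * (round(dest[, 2]) + m * round(dest[, 3])) + 1
  out <- arr
  out[lin] <- as.vector(arr)
  out
}

#' Rotate coordinates about the center of a grid
#'
#' @param coords n x 3 matrix.
#' @param R Rotation matrix.
#' @param grid A \linkS4class{VoxelGrid}.
#' @return Rotated coordinates.
#' @export
rotateCoords <- function(coords, R, grid) {
  ctr <- grid@origin + grid@dims * grid@spacing / 2
  sweep(sweep(coords, 2, ctr) %*% t(R), 2, ctr, "+")
}
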