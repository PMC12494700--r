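# Radially symmetric L1-normalized convolution kernels. Each family is a
# radial profile sampled at voxel-center offsets, truncated and normalized
# to unit L1 norm, so every kernel is centrally symmetric by construction
# and the induced convolution operator is non-expansive in sup norm.

kernelRadius <- function(family, sigma, spacing, truncation = 3) {
  eff <- if (family == "difference_of_gaussians") 2 * sigma else sigma
  max(1L, as.integer(ceiling(truncation * eff / spacing)))
}

# Radial profile and its derivative with respect to sigma, at radii r (A).
kernelProfile <- function(family, r, sigma) {
  switch(family,
    gaussian = {
      w <- exp(-r^2 / (2 * sigma^2))
      list(w = w, dw = w * r^2 / sigma^3)
    },
    difference_of_gaussians = {
      # signed: narrow excitatory Gaussian minus a broad (2*sigma) one,
      # each mass-normalized before subtraction
      g1 <- exp(-r^2 / (2 * sigma^2))
      g2 <- exp(-r^2 / (8 * sigma^2))
      d1 <- g1 * r^2 / sigma^3
      d2 <- g2 * r^2 / (4 * sigma^3)
      s1 <- sum(g1); s2 <- sum(g2)
      w <- g1 / s1 - g2 / s2
      dw <- (d1 * s1 - g1 * sum(d1)) / s1^2 - (d2 * s2 - g2 * sum(d2)) / s2^2
      list(w = w, dw = dw)
    },
    spherical_shell = {
      # Gaussian shell at radius sigma, width sigma / 2
      w <- exp(-2 * (r - sigma)^2 / sigma^2)
      dw <- w * (4 * (r - sigma) / sigma^2 + 4 * (r - sigma)^2 / sigma^3)
      list(w = w, dw = dw)
    },
    geneoStop("geneo_bad_argument", "unknown kernel family '", family, "'"))
}

#' Build a discrete convolution kernel
#'
#' Samples the chosen radial profile at voxel-center offsets inside the
#' truncation radius and normalizes the taps to unit L1 norm. The result is
#' exactly centrally symmetric (K(v) = K(-v)) because the profile depends
#' only on |v|.
#'
#' @param family "gaussian", "difference_of_gaussians" (signed) or
#'   "spherical_shell".
#' @param sigma Width parameter in Angstrom; must be at least
#'   \code{0.25 * spacing}.
#' @param spacing Grid spacing in Angstrom.
#' @param truncation Truncation radius in units of sigma (default 3; the
#'   difference-of-Gaussians family truncates at \code{truncation} times its
#'   broad width \code{2 * sigma}).
#' @param radius Optional fixed tap radius in voxels, overriding the
#'   truncation rule (used during training to keep the stencil fixed while
#'   sigma varies).
#' @param grad If TRUE, also return the derivative of the taps with respect
#'   to sigma.
#' @return A list with \code{taps} (odd-dimensioned 3D array summing to 1 in
#'   absolute value), \code{radius}, \code{family}, \code{sigma} and, when
#'   requested, \code{dtaps}.
#' @examples
#' k <- buildKernel("gaussian", sigma = 1, spacing = 1)
#' sum(abs(k$taps))
#' @export
buildKernel <- function(family, sigma, spacing, truncation = 3,
                        radius = NULL, grad = FALSE) {
  if (sigma < 0.25 * spacing - 1e-12)
    geneoStop("geneo_parameter_floor",
              "sigma = ", sigma, " is below the floor of 0.25 * spacing = ",
              0.25 * spacing)
  if (is.null(radius)) radius <- kernelRadius(family, sigma, spacing, truncation)
  ax <- (-radius):radius
  n <- length(ax)
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+")) * spacing
  dim(r) <- c(n, n, n)
  prof <- kernelProfile(family, as.numeric(r), sigma)
  s <- sum(abs(prof$w))
  if (s == 0) geneoStop("geneo_bad_argument", "degenerate kernel (all-zero taps)")
  taps <- array(prof$w / s, dim = c(n, n, n))
  out <- list(taps = taps, radius = radius, family = family, sigma = sigma)
  if (grad) {
    ds <- sum(sign(prof$w) * prof$dw)
    out$dtaps <- array((prof$dw * s - prof$w * ds) / s^2, dim = c(n, n, n))
  }
  out
}
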