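## Closed-form dispersion analytics for the damped tissue-wave equation
##   d/dt (laplacian phi) = -div( Sigma grad phi ),
## plus the textbook electromagnetic reference numbers used to show why the
## observed slow brain rhythms cannot be EM propagation effects.

SPEED_OF_LIGHT <- 3e8  # m/s, as conventionally rounded in the EM estimates

#' Plane-wave dispersion of the tissue wave equation
#'
#' For a plane wave phi ~ exp(-i (k.r - Omega t)) in a medium with local
#' scaled conductivity tensor Sigma and gradient dSigma, the complex
#' frequency is
#' \deqn{\gamma = \frac{\Sigma_{ij} k_i k_j}{k^2}, \qquad
#'       \omega = -\frac{(\partial_i \Sigma_{ij}) k_j}{k^2},}
#' with Omega = omega + i gamma. The decay rate gamma is set by the tensor
#' itself; the oscillation frequency omega is driven entirely by its spatial
#' gradient, and scales as 1/k (long waves oscillate fastest).
#'
#' @param Sigma symmetric 3x3 scaled conductivity tensor (1/s).
#' @param gradSigma 3x3x3 array with \code{gradSigma[l, i, j]} = the
#'   derivative of Sigma_ij along axis l (1/s per unit length). The
#'   contraction uses the divergence \code{sum_i gradSigma[i, i, j]}.
#' @param k nonzero 3-vector wavevector.
#' @param kUnits units tag stored with the result ("1/m" or "1/voxel").
#' @return a \linkS4class{DispersionResult}
#' @examples
#' ## homogeneous isotropic gray matter: pure decay at sigma/eps
#' r <- wetcowDispersion(diag(76.31, 3), array(0, c(3, 3, 3)), c(1, 0, 0))
#' r@gamma
#' @export
wetcowDispersion <- function(Sigma, gradSigma, k, kUnits = "1/m") {
  k <- as.numeric(k)
  if (length(k) != 3L || sum(k^2) == 0)
    stop("wavevector k must be a nonzero 3-vector")
  stopifnot(all(dim(Sigma) == c(3, 3)), all(dim(gradSigma) == c(3, 3, 3)))
  k2 <- sum(k^2)
  gamma <- as.numeric(t(k) %*% Sigma %*% k) / k2
  divSigma <- vapply(1:3, function(j)
    gradSigma[1, 1, j] + gradSigma[2, 2, j] + gradSigma[3, 3, j], numeric(1))
  omega <- -sum(divSigma * k) / k2
  new("DispersionResult", Omega = complex(real = omega, imaginary = gamma),
      omega = omega, gamma = gamma, k = k, kUnits = kUnits)
}

#' Decay rate of a homogeneous isotropic medium
#'
#' In a homogeneous isotropic medium the dispersion relation reduces to a
#' k-independent pure decay at rate sigma/eps. With the standard
#' low-frequency gray/white-matter constants this lands in the 75-115 1/s
#' range, i.e. strong damping: without anisotropy and inhomogeneity no
#' persistent waves would be observed.
#'
#' @param sigma conductivity (S/m)
#' @param eps absolute permittivity (F/m), > 0
#' @return decay rate in 1/s
#' @examples
#' homogeneousDecayRate(2.75e-2, 4.07e7 * 8.854187817e-12)  # gray matter
#' @export
homogeneousDecayRate <- function(sigma, eps) {
  if (!is.numeric(eps) || any(eps <= 0))
    stop("permittivity must be positive")
  sigma / eps
}

#' Electromagnetic phase velocity in a dielectric
#'
#' v = c / sqrt(epsRel) with c = 3e8 m/s.
#'
#' @param epsRel relative permittivity, > 0
#' @return velocity in m/s
#' @export
emVelocity <- function(epsRel) {
  if (!is.numeric(epsRel) || any(epsRel <= 0))
    stop("relative permittivity must be positive")
  SPEED_OF_LIGHT / sqrt(epsRel)
}

#' Electromagnetic wavelength at a given frequency
#'
#' lambda = v / f, following the conventional back-of-envelope usage in
#' which the frequency in Hz divides the velocity directly (at
#' epsRel = 100 and f = 10 Hz this gives 3e6 m = 3000 km, the standard
#' argument that EM phase differences across the head are negligible).
#' Set \code{angular = TRUE} to treat \code{freq} as an angular frequency
#' (rad/s), i.e. lambda = 2 pi v / omega.
#'
#' @param epsRel relative permittivity, > 0
#' @param freq frequency in Hz (or rad/s when \code{angular})
#' @param angular interpret \code{freq} as angular frequency
#' @return wavelength in m
#' @export
emWavelength <- function(epsRel, freq, angular = FALSE) {
  if (!is.numeric(freq) || any(freq <= 0))
    stop("frequency must be positive")
  v <- emVelocity(epsRel)
  if (angular) 2 * pi * v / freq else v / freq
}

#' Persistence ratio of a dispersive mode
#'
#' The magnitude of decay rate over frequency, |gamma/omega|: small values
#' mean the mode rings for many cycles before it damps out. Undefined for a
#' homogeneous medium (omega = 0).
#'
#' @param result a \linkS4class{DispersionResult}
#' @return dimensionless |gamma/omega|
#' @export
persistenceRatio <- function(result) {
  stopifnot(is(result, "DispersionResult"))
  if (result@omega == 0)
    stop("persistence ratio undefined: mode has zero oscillation frequency")
  abs(result@gamma / result@omega)
}
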