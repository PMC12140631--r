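#' @import methods
#' @importFrom stats rnorm fft mvfft cor sd coef lm
NULL

## Vacuum permittivity (F/m), used wherever relative permittivities are scaled.
EPS0 <- 8.854187817e-12

#' TissueGrid: a labeled voxel volume with geometry
#'
#' Holds the sampling lattice on which all volumetric computations are done:
#' integer tissue labels (0 = background, 1 = CSF, 2 = GM, 3 = WM by default),
#' the voxel size in mm, and a NIfTI-style 4x4 voxel-to-world affine
#' (0-based voxel indices, RAS world axes).
#'
#' @slot dims integer(3), volume dimensions in voxels (all >= 1).
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot affine 4x4 voxel-to-world matrix (invertible).
#' @slot labels integer array of dimension \code{dims}.
#' @slot meta list of free-form metadata (e.g. the resolution tag of a
#'   template grid).
#' @export
setClass("TissueGrid",
  representation(
    dims = "integer",
    voxelSize = "numeric",
    affine = "matrix",
    labels = "array",
    meta = "list"
  )
)

setValidity("TissueGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three integers >= 1")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (abs(det(object@affine)) < .Machine$double.eps)
    msg <- c(msg, "affine must be invertible")
  if (!identical(dim(object@labels), as.integer(object@dims)))
    msg <- c(msg, "labels array shape must equal dims")
  if (length(msg)) msg else TRUE
})

#' TissueTable: per-label electrical properties
#'
#' One row per tissue label: conductivity sigma (S/m) and relative
#' permittivity epsRel (multiples of the vacuum permittivity
#' eps0 = 8.854187817e-12 F/m).
#'
#' @slot table data.frame with columns \code{label}, \code{name},
#'   \code{sigma}, \code{epsRel}.
#' @export
setClass("TissueTable", representation(table = "data.frame"))

setValidity("TissueTable", function(object) {
  tb <- object@table
  need <- c("label", "name", "sigma", "epsRel")
  if (!all(need %in% names(tb)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$label)) return("duplicate tissue labels")
  if (any(tb$sigma < 0)) return("conductivity sigma must be >= 0")
  if (any(tb$epsRel <= 0)) return("relative permittivity epsRel must be > 0")
  TRUE
})

#' TensorField: per-voxel scaled conductivity tensor and permittivity
#'
#' The scaled conductivity tensor Sigma = sigma_ij / eps (units 1/s) drives
#' both the damping and the oscillation of the tissue waves; eps (F/m) is the
#' absolute permittivity. Sigma is stored as a 4D array with the 6 unique
#' components of the symmetric tensor in the order xx, yy, zz, xy, xz, yz.
#'
#' @slot dims integer(3) grid dimensions.
#' @slot voxelSize numeric(3) voxel size in mm.
#' @slot sigma numeric 4D array \code{c(dims, 6)}, components in 1/s.
#' @slot eps numeric 3D array, permittivity in F/m.
#' @export
setClass("TensorField",
  representation(
    dims = "integer",
    voxelSize = "numeric",
    sigma = "array",
    eps = "array"
  )
)

setValidity("TensorField", function(object) {
  msg <- character()
  if (!identical(dim(object@sigma), as.integer(c(object@dims, 6L))))
    msg <- c(msg, "sigma must be a (dims, 6) array")
  if (!identical(dim(object@eps), as.integer(object@dims)))
    msg <- c(msg, "eps must match dims")
  else if (any(object@eps <= 0))
    msg <- c(msg, "permittivity must be positive everywhere")
  if (length(msg) == 0L) {
    diagc <- object@sigma[, , , 1:3, drop = FALSE]
    if (any(diagc < 0)) msg <- c(msg, "diagonal Sigma components must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' BoundaryLayerModel: idealized anisotropic boundary layer
#'
#' Fibers aligned with z fill a half space and thin out across a narrow layer
#' along x. Cross-fiber conduction is suppressed by the small parameter
#' \code{epsilon}; the along-fiber scaled conductivity follows the profile
#' \code{profile(x)} (units 1/s). The constants \code{a} = profile(x0) and
#' \code{b} = d(profile)/dx at x0 are frozen at the boundary location, which
#' is what makes the thin-layer reduction valid.
#'
#' @slot epsilon small dimensionless cross-fiber coupling (0 <= epsilon << 1).
#' @slot profile function of position x returning the along-fiber scaled
#'   conductivity (1/s).
#' @slot x0 boundary location.
#' @slot a profile value at x0 (1/s).
#' @slot b profile slope at x0 (1/s per unit length).
#' @export
setClass("BoundaryLayerModel",
  representation(
    epsilon = "numeric",
    profile = "function",
    x0 = "numeric",
    a = "numeric",
    b = "numeric"
  )
)

setValidity("BoundaryLayerModel", function(object) {
  msg <- character()
  if (object@epsilon < 0 || object@epsilon >= 1)
    msg <- c(msg, "epsilon must satisfy 0 <= epsilon < 1")
  a0 <- object@profile(object@x0)
  if (!isTRUE(all.equal(a0, object@a, tolerance = 1e-6)))
    msg <- c(msg, "stored a is inconsistent with profile(x0)")
  if (length(msg)) msg else TRUE
})

#' DispersionResult: complex frequency of a plane-wave mode
#'
#' @slot Omega complex frequency (1/s), \code{Omega = omega + 1i*gamma}.
#' @slot omega real (oscillatory) part (1/s).
#' @slot gamma imaginary (decay) part (1/s).
#' @slot k the wavevector the result was evaluated at.
#' @slot kUnits character, units of k ("1/m" or "1/voxel").
#' @export
setClass("DispersionResult",
  representation(Omega = "complex", omega = "numeric", gamma = "numeric",
                 k = "numeric", kUnits = "character")
)

#' SensorArray: electrode montage mapped onto the grid
#'
#' Positions are stored as 0-based, possibly fractional, voxel coordinates;
#' world coordinates (mm) are kept when the montage was given in world space.
#'
#' @slot names unique channel labels.
#' @slot voxels n x 3 numeric matrix of 0-based voxel coordinates.
#' @slot world n x 3 numeric matrix of world coordinates (mm) or a 0-row
#'   matrix when unknown.
#' @slot dims integer(3), dimensions of the grid the array is mapped to.
#' @export
setClass("SensorArray",
  representation(names = "character", voxels = "matrix", world = "matrix",
                 dims = "integer")
)

setValidity("SensorArray", function(object) {
  msg <- character()
  if (anyDuplicated(object@names)) msg <- c(msg, "channel names must be unique")
  if (nrow(object@voxels) != length(object@names))
    msg <- c(msg, "one voxel position per channel required")
  if (ncol(object@voxels) != 3L) msg <- c(msg, "voxels must be n x 3")
  inb <- object@voxels >= 0 &
    sweep(object@voxels, 2, object@dims - 1L, `<=`)
  if (!all(inb)) msg <- c(msg, "all sensor voxels must lie inside the grid")
  if (length(msg)) msg else TRUE
})

#' EEGRecording: multichannel surface recording
#'
#' @slot data channels x samples numeric matrix; rownames are channel names.
#' @slot fs sampling rate in Hz.
#' @slot t0 start time in seconds.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric", t0 = "numeric")
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive sampling rate (Hz)")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "recording must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' SpectralPotential: reconstructed band-limited potential
#'
#' Per-frequency-bin complex potential volumes and, after Hermitian assembly
#' and inverse transform, the real time-domain 4D potential.
#'
#' @slot freqs frequencies (Hz) of the retained bins.
#' @slot volumes list of complex 3D arrays, one per bin.
#' @slot phiT real 4D array (dims x time) or a 0-length array if the time
#'   domain was not assembled.
#' @slot fs sampling rate (Hz) of the time axis.
#' @slot nTime number of time samples of the originating window.
#' @slot diagnostics list of per-bin solver diagnostics (iterations,
#'   relative changes, rescale factors).
#' @export
setClass("SpectralPotential",
  representation(freqs = "numeric", volumes = "list", phiT = "array",
                 fs = "numeric", nTime = "integer", diagnostics = "list")
)

#' CouplingMatrix: nonnegative space-time coupling between voxels
#'
#' @slot Q symmetric nonnegative sparse matrix (class dsCMatrix or dense).
#' @slot voxelIndex linear (1-based) indices into the originating volume of
#'   the retained voxels.
#' @slot dims integer(3) of the originating volume.
#' @export
setClass("CouplingMatrix",
  representation(Q = "ANY", voxelIndex = "integer", dims = "integer")
)

#' ModeSet: ranked spatiotemporal modes
#'
#' Modes are ranked by amplitude (eigenvalue of the coupling matrix). Spatial
#' maps are nonnegative and unit L2-normalized over the retained voxels;
#' \code{muStar} is the equilibrium voxel distribution (squared leading
#' eigenvector, normalized to sum to 1).
#'
#' @slot maps nvox x nmodes matrix of spatial maps.
#' @slot timecourses ntime x nmodes matrix of mode time courses.
#' @slot amplitudes numeric, non-increasing mode amplitudes.
#' @slot muStar numeric nvox vector, >= 0, sums to 1.
#' @slot voxelIndex linear indices of the retained voxels.
#' @slot dims integer(3) of the originating volume.
#' @export
setClass("ModeSet",
  representation(maps = "matrix", timecourses = "matrix",
                 amplitudes = "numeric", muStar = "numeric",
                 voxelIndex = "integer", dims = "integer")
)

setValidity("ModeSet", function(object) {
  msg <- character()
  n <- length(object@amplitudes)
  if (ncol(object@maps) != n || ncol(object@timecourses) != n)
    msg <- c(msg, "maps/timecourses must have one column per mode")
  if (is.unsorted(rev(object@amplitudes)))
    msg <- c(msg, "amplitudes must be non-increasing with rank")
  if (length(object@muStar)) {
    if (any(object@muStar < -1e-12)) msg <- c(msg, "muStar must be >= 0")
    if (abs(sum(object@muStar) - 1) > 1e-8)
      msg <- c(msg, "muStar must sum to 1")
  }
  if (length(msg)) msg else TRUE
})
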