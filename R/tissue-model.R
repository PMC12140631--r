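## Tissue geometry and electrical-property fields.
##
## Everything downstream (dispersion analytics, forward integration, the
## frequency-domain inverse solve) is driven by the scaled conductivity
## tensor Sigma = sigma_ij/eps (1/s) and the permittivity eps (F/m) defined
## on a voxel grid.

MNI_GRIDS <- list(
  "2mm"   = list(dims = c(91L, 109L, 91L),   vox = c(2, 2, 2)),
  "1mm"   = list(dims = c(182L, 218L, 182L), vox = c(1, 1, 1)),
  "0.7mm" = list(dims = c(207L, 256L, 215L), vox = c(0.7, 0.7, 0.7))
)

## Default tissue labels used throughout.
LABEL_BACKGROUND <- 0L
LABEL_CSF <- 1L
LABEL_GM <- 2L
LABEL_WM <- 3L

centeredAffine <- function(dims, voxelSize) {
  ## RAS affine with the world origin at the volume center, 0-based indices.
  A <- diag(4)
  A[1:3, 1:3] <- diag(voxelSize, 3, 3)
  A[1:3, 4] <- -voxelSize * (dims - 1) / 2
  A
}

newTissueGrid <- function(dims, voxelSize, labels = NULL, affine = NULL,
                          meta = list()) {
  dims <- as.integer(dims)
  if (is.null(labels)) labels <- array(0L, dims)
  storage.mode(labels) <- "integer"
  if (is.null(affine)) affine <- centeredAffine(dims, voxelSize)
  new("TissueGrid", dims = dims, voxelSize = as.numeric(voxelSize),
      affine = affine, labels = labels, meta = meta)
}

#' Standard template sampling grids
#'
#' Returns an empty (all-background) grid with the voxel dimensions of the
#' standard brain-template lattices: 91 x 109 x 91 at 2 mm,
#' 182 x 218 x 182 at 1 mm, and 207 x 256 x 215 at the ~0.7 mm
#' resolution. The millimetre tag is stored as metadata; the voxel
#' dimensions are authoritative.
#'
#' @param resolution one of \code{"2mm"}, \code{"1mm"}, \code{"0.7mm"}.
#' @return a \linkS4class{TissueGrid} with labels initialized to background.
#' @examples
#' g <- makeMniGrid("2mm")
#' prod(gridDims(g))  # 902629 voxels
#' @export
makeMniGrid <- function(resolution = c("2mm", "1mm", "0.7mm")) {
  if (!is.character(resolution) || !resolution[1] %in% names(MNI_GRIDS))
    stop("unknown resolution label: ", resolution[1],
         " (supported: ", paste(names(MNI_GRIDS), collapse = ", "), ")")
  spec <- MNI_GRIDS[[resolution[1]]]
  newTissueGrid(spec$dims, spec$vox, meta = list(resolution = resolution[1]))
}

#' Concentric-shell phantom grid
#'
#' Builds a layered-sphere tissue grid centered in the volume: voxels within
#' the first radius get the first label, voxels between consecutive radii get
#' the following labels, and voxels beyond the outermost radius remain
#' background (0). Radii are in voxel units.
#'
#' @param dims integer(3) grid dimensions.
#' @param radii strictly increasing shell radii (voxels).
#' @param labels one integer label per shell.
#' @param voxelSize voxel size in mm (default 1 mm isotropic).
#' @return a \linkS4class{TissueGrid}
#' @examples
#' g <- sphericalPhantom(c(32, 32, 32), radii = c(8, 12, 14),
#'                       labels = c(3, 2, 1))
#' @export
sphericalPhantom <- function(dims, radii, labels, voxelSize = c(1, 1, 1)) {
  dims <- as.integer(dims)
  if (length(radii) != length(labels))
    stop("need one label per shell")
  if (is.unsorted(radii, strictly = TRUE))
    stop("shell radii must be strictly increasing")
  if (max(radii) > min(dims) / 2)
    stop("shell radii exceed half the grid extent")
  ctr <- (dims - 1) / 2
  ax <- lapply(1:3, function(d) (seq_len(dims[d]) - 1) - ctr[d])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  lab <- array(LABEL_BACKGROUND, dims)
  for (s in rev(seq_along(radii)))  # innermost shell wins
    lab[r2 <= radii[s]^2] <- as.integer(labels[s])
  newTissueGrid(dims, voxelSize, labels = lab)
}

#' Tissue property table
#'
#' Constructs a per-label table of conductivity (S/m) and relative
#' permittivity. \code{defaultTissueTable()} carries the standard
#' low-frequency gray/white-matter constants
#' (sigma_GM = 2.75e-2 S/m, eps_GM = 4.07e7 eps0;
#' sigma_WM = 2.77e-2 S/m, eps_WM = 2.76e7 eps0). The CSF entry
#' (sigma = 1.79 S/m, eps_rel = 109) is a conventional literature default,
#' not part of the core wave model, and is freely configurable. Background
#' defaults to sigma = 1e-6 * sigma_GM with eps = eps_GM so that the exterior
#' of the head is electrically inert on the periodic computational domain.
#'
#' @param label integer labels.
#' @param name tissue names.
#' @param sigma conductivities in S/m.
#' @param epsRel relative permittivities (multiples of eps0).
#' @return a \linkS4class{TissueTable}
#' @export
TissueTable <- function(label, name, sigma, epsRel) {
  new("TissueTable", table = data.frame(
    label = as.integer(label), name = as.character(name),
    sigma = as.numeric(sigma), epsRel = as.numeric(epsRel)))
}

#' @rdname TissueTable
#' @export
defaultTissueTable <- function() {
  TissueTable(
    label  = c(LABEL_BACKGROUND, LABEL_CSF, LABEL_GM, LABEL_WM),
    name   = c("background", "CSF", "GM", "WM"),
    sigma  = c(1e-6 * 2.75e-2, 1.79, 2.75e-2, 2.77e-2),
    epsRel = c(4.07e7, 109, 4.07e7, 2.76e7))
}

#' Build the scaled conductivity-tensor / permittivity field
#'
#' At every voxel, eps = epsRel * eps0 and the scaled conductivity tensor is
#' isotropic, Sigma = (sigma/eps) * I, looked up from the voxel's tissue
#' label. Every label present in the grid must have a table entry.
#'
#' Label-to-property mapping is optionally followed by partial-volume
#' smoothing (an isotropic Gaussian of standard deviation \code{smoothing}
#' voxels applied to the conductivity and permittivity volumes): tissue
#' interfaces in real heads are thin but resolved layers, and the
#' pseudo-spectral derivative operators need the resulting gradients to be
#' representable on the grid.
#'
#' @param grid a \linkS4class{TissueGrid}
#' @param table a \linkS4class{TissueTable} (default \code{defaultTissueTable()})
#' @param smoothing partial-volume Gaussian sd in voxels (0 = hard labels)
#' @return a \linkS4class{TensorField}
#' @examples
#' g <- sphericalPhantom(c(16, 16, 16), c(5, 7), c(3, 2))
#' f <- buildTensorField(g)
#' range(isotropicPart(f))
#' @export
buildTensorField <- function(grid, table = defaultTissueTable(),
                             smoothing = 0) {
  stopifnot(is(grid, "TissueGrid"), is(table, "TissueTable"))
  tb <- table@table
  present <- sort(unique(as.vector(grid@labels)))
  missing <- setdiff(present, tb$label)
  if (length(missing))
    stop("labels present in grid but absent from tissue table: ",
         paste(missing, collapse = ", "))
  idx <- match(grid@labels, tb$label)
  eps <- array(tb$epsRel[idx] * EPS0, grid@dims)
  cond <- array(tb$sigma[idx], grid@dims)
  if (smoothing > 0) {
    cond <- pmax(smoothVolume(cond, smoothing), 0)
    eps <- pmax(smoothVolume(eps, smoothing), min(eps))
  }
  rate <- cond / eps
  sig <- array(0, c(grid@dims, 6L))
  sig[, , , 1] <- rate
  sig[, , , 2] <- rate
  sig[, , , 3] <- rate
  new("TensorField", dims = grid@dims, voxelSize = grid@voxelSize,
      sigma = sig, eps = eps)
}

#' Isotropic part of the scaled conductivity tensor
#'
#' Per-voxel sigma = Tr(Sigma)/3 = (Sigma_xx + Sigma_yy + Sigma_zz)/3, the
#' isotropic local conductivity (1/s) entering the inverse-solver operator.
#'
#' @param field a \linkS4class{TensorField}
#' @return numeric 3D array (1/s)
#' @export
isotropicPart <- function(field) {
  stopifnot(is(field, "TensorField"))
  (field@sigma[, , , 1] + field@sigma[, , , 2] + field@sigma[, , , 3]) / 3
}

#' Idealized anisotropic boundary-layer model
#'
#' Fibers aligned with z thin out across a narrow layer along x. The default
#' along-fiber profile is a hyperbolic-tangent ramp from \code{low} to
#' \code{high} (1/s) of half-width \code{width} centered at \code{x0};
#' \code{a = profile(x0)} and \code{b = d(profile)/dx |_(x0)} are evaluated
#' from the stored profile.
#'
#' @param epsilon small dimensionless cross-fiber coupling.
#' @param x0 boundary location.
#' @param width ramp half-width (same length units as x).
#' @param low,high asymptotic along-fiber scaled conductivities (1/s).
#' @param profile optional custom profile function of x (overrides the ramp).
#' @return a \linkS4class{BoundaryLayerModel}
#' @export
boundaryLayerModel <- function(epsilon = 0.01, x0 = 0, width = 1,
                               low = 0, high = 100, profile = NULL) {
  if (is.null(profile)) {
    force(x0); force(width); force(low); force(high)
    profile <- function(x) low + (high - low) * (1 + tanh((x - x0) / width)) / 2
  }
  h <- 1e-6 * max(1, abs(x0), width)
  a <- profile(x0)
  b <- (profile(x0 + h) - profile(x0 - h)) / (2 * h)
  new("BoundaryLayerModel", epsilon = epsilon, profile = profile,
      x0 = x0, a = a, b = b)
}

#' Boundary-layer conductivity tensor at a position
#'
#' Evaluates the idealized layered tensor
#' \deqn{\Sigma = \pmatrix{\epsilon u & \epsilon u & \epsilon u \cr
#'   \epsilon u & \epsilon u & 0 \cr \epsilon u & 0 & u}}
#' with u = profile(x): cross-fiber conduction suppressed by epsilon, full
#' conduction only along the fiber (z) axis. At epsilon = 0 the tensor
#' reduces to pure along-fiber conduction.
#'
#' @param model a \linkS4class{BoundaryLayerModel}
#' @param x position at which to evaluate the profile
#' @return symmetric 3x3 matrix (1/s)
#' @export
boundaryLayerTensor <- function(model, x) {
  stopifnot(is(model, "BoundaryLayerModel"))
  u <- model@profile(x)
  e <- model@epsilon
  matrix(c(e * u, e * u, e * u,
           e * u, e * u, 0,
           e * u, 0,     u), 3, 3, byrow = TRUE)
}
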