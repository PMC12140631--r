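## Fourier-collocation operators on the periodic voxel grid.
##
## All spatial derivatives in the forward and inverse solvers are spectral:
## multiply by i*k in Fourier space. First-derivative operators zero the
## Nyquist wavenumber (its ik image has no conjugate-symmetric partner for
## real fields); the Laplacian and its inverse keep the full |k|^2.

fftn <- function(x) stats::fft(x)
ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## Angular wavenumbers of an n-point periodic axis with spacing h.
axisWavenumbers <- function(n, h = 1) {
  if (n == 1L) return(0)
  idx <- c(0:(n - n %/% 2 - 1), -(n %/% 2):-1)
  if (n %% 2 == 0) idx[n %/% 2 + 1] <- -n %/% 2  # Nyquist, negative by convention
  2 * pi * idx / (n * h)
}

## Precomputed wavenumber arrays for a grid; reused across many operator
## applications. kd1..kd3 have the Nyquist plane zeroed (first derivatives);
## k2 is the full squared magnitude; invLap = -1/k^2 with the k=0 (gauge)
## coefficient set to 0.
makeSpectralOps <- function(dims, spacing = c(1, 1, 1)) {
  dims <- as.integer(dims)
  kv <- lapply(1:3, function(d) axisWavenumbers(dims[d], spacing[d]))
  kvd <- lapply(1:3, function(d) {
    k <- kv[[d]]
    if (dims[d] %% 2 == 0) k[dims[d] %/% 2 + 1] <- 0
    k
  })
  expand <- function(v, d) {
    each <- prod(dims[seq_len(d - 1)])
    array(rep(v, each = each), dims)  # recycled over the trailing axes
  }
  kx <- expand(kvd[[1]], 1); ky <- expand(kvd[[2]], 2); kz <- expand(kvd[[3]], 3)
  k2 <- expand(kv[[1]], 1)^2 + expand(kv[[2]], 2)^2 + expand(kv[[3]], 3)^2
  invLap <- -1 / k2
  invLap[1, 1, 1] <- 0
  list(dims = dims, spacing = spacing, kx = kx, ky = ky, kz = kz,
       k2 = k2, invLap = invLap)
}

## Gradient components of a volume given its Fourier transform.
specGradFromHat <- function(xhat, ops) {
  list(ifftn(1i * ops$kx * xhat),
       ifftn(1i * ops$ky * xhat),
       ifftn(1i * ops$kz * xhat))
}

specDiv <- function(F1, F2, F3, ops) {
  ifftn(1i * (ops$kx * fftn(F1) + ops$ky * fftn(F2) + ops$kz * fftn(F3)))
}

specLaplacian <- function(x, ops) ifftn(-ops$k2 * fftn(x))

#' Invert the Laplacian on the periodic grid
#'
#' Solves laplacian(phi) = vol spectrally in the zero-mean gauge: the k = 0
#' Fourier coefficient of the result is set to 0 (the potential is defined
#' only up to a constant), so the input's mean is implicitly projected out.
#'
#' @param vol numeric or complex 3D array.
#' @param voxelSize grid spacing (mm or voxel units); enters as 1/length^2.
#' @return array of the same shape; real when the input is real.
#' @examples
#' x <- array(rnorm(8^3), c(8, 8, 8))
#' lap <- invertLaplacian(x)
#' @export
invertLaplacian <- function(vol, voxelSize = c(1, 1, 1)) {
  ops <- makeSpectralOps(dim(vol), voxelSize)
  invertLaplacianOps(vol, ops)
}

invertLaplacianOps <- function(vol, ops) {
  out <- ifftn(ops$invLap * fftn(vol))
  if (is.complex(vol)) out else Re(out)
}

## Gaussian low-pass filter (sd in voxels) via the spectral transfer
## function exp(-k^2 sd^2 / 2); used for partial-volume smoothing of
## label-derived property fields.
smoothVolume <- function(vol, sd) {
  if (sd <= 0) return(vol)
  ops <- makeSpectralOps(dim(vol), rep(1, 3))
  Re(ifftn(exp(-ops$k2 * sd^2 / 2) * fftn(vol)))
}

## Contraction Sigma . grad, returning the three flux components.
tensorFlux <- function(sig, g) {
  list(sig[, , , 1] * g[[1]] + sig[, , , 4] * g[[2]] + sig[, , , 5] * g[[3]],
       sig[, , , 4] * g[[1]] + sig[, , , 2] * g[[2]] + sig[, , , 6] * g[[3]],
       sig[, , , 5] * g[[1]] + sig[, , , 6] * g[[2]] + sig[, , , 3] * g[[3]])
}
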