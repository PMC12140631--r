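## Frequency-domain iterative inverse solver.
##
## In the temporal Fourier domain the potential obeys
##   (Sigma_ij - I w eps delta_ij) d_i d_j phi_w
##     = [I w (d_i eps) delta_ij - (d_i Sigma_ij)] d_j phi_w  (+ sources),
## rearranged as L phi = R phi with L the plain Laplacian and
##   R = (sigma + I w eps) / (sigma^2 + w^2 eps^2) *
##       [ I w (d_i eps) d_i  -  (d_i Sigma_ij) d_j  -  (Sigma_ij - sigma
##         delta_ij) d_i d_j ],
## sigma = Tr(Sigma)/3. The three bracketed terms pick up permittivity
## gradients, conductivity gradients, and anisotropy respectively. Each
## frequency bin is solved independently by the fixed-point iteration
## L phi^(k) = R phi^(k-1), accumulated as phiTilde = alpha_K sum_k phi^(k),
## then rescaled to best match the measured electrode coefficients.

#' Inverse-solver configuration
#'
#' @param band frequency band [w1, w2] in Hz (0 <= w1 < w2 <= Nyquist).
#' @param K maximum number of fixed-point iterations.
#' @param tol stopping tolerance on the relative L2 change of the
#'   accumulated sum.
#' @param method sensor-data embedding used for phi^(0): \code{"minnorm"}
#'   (depth-weighted standardized minimum-norm interior source estimate,
#'   the default) or \code{"sensor"} (measured coefficients placed as point
#'   sources at the sensor voxels).
#' @param lambda Tikhonov regularization of the embedding gain matrix,
#'   relative to its mean diagonal.
#' @param commonAverage re-reference the measured coefficients to the
#'   common average across channels before embedding.
#' @param divergenceFactor iterate-norm growth factor that triggers a
#'   convergence error.
#' @return a list of class \code{InverseConfig}
#' @export
inverseConfig <- function(band = c(8, 12), K = 20L, tol = 1e-6,
                          method = c("minnorm", "sensor"), lambda = 1e-8,
                          commonAverage = TRUE, divergenceFactor = 1e6) {
  stopifnot(length(band) == 2L, band[1] >= 0, band[1] < band[2],
            K >= 1L, tol > 0)
  structure(list(band = as.numeric(band), K = as.integer(K), tol = tol,
                 method = match.arg(method), lambda = lambda,
                 commonAverage = commonAverage,
                 divergenceFactor = divergenceFactor),
            class = "InverseConfig")
}

#' Band-restricted Fourier coefficients of a recording
#'
#' Discrete Fourier coefficients of each channel, restricted to the bins
#' whose frequency lies in [band1, band2] (inclusive). Bin frequencies are
#' j * fs / N for j = 0..N-1; only bins at or below Nyquist are eligible.
#'
#' @param rec an \linkS4class{EEGRecording}
#' @param band numeric(2) frequency band in Hz
#' @return list with \code{freqs} (Hz) and \code{coeffs}
#'   (channels x bins complex matrix)
#' @export
sensorSpectrum <- function(rec, band) {
  stopifnot(is(rec, "EEGRecording"), length(band) == 2L)
  if (band[2] > rec@fs / 2)
    stop("band extends beyond the Nyquist frequency ", rec@fs / 2, " Hz")
  if (band[1] < 0 || band[1] >= band[2]) stop("need 0 <= w1 < w2")
  N <- ncol(rec@data)
  X <- stats::mvfft(t(rec@data))           # bins x channels
  freqs <- (seq_len(N) - 1) * rec@fs / N
  sel <- which(freqs >= band[1] & freqs <= band[2] & freqs <= rec@fs / 2)
  list(freqs = freqs[sel],
       coeffs = t(X[sel, , drop = FALSE]))
}

## Precompute everything applyRhat needs repeatedly for one field.
##
## The frequency-domain operator acts on the RAW conductivity tensor
## sigma_ij (S/m) and absolute permittivity eps (F/m): at EEG frequencies
## sigma and omega*eps are comparable (that is the displacement-current
## point), so the prefactor 1/(sigma - I omega eps) is well scaled. The
## stored field carries the scaled tensor Sigma = sigma_ij/eps (1/s), so
## the raw tensor is recovered as Sigma * eps per voxel.
makeRhatContext <- function(field) {
  ops <- makeSpectralOps(field@dims, rep(1, 3))
  sig <- field@sigma * as.vector(field@eps)   # raw sigma_ij, S/m
  sigmaIso <- (sig[, , , 1] + sig[, , , 2] + sig[, , , 3]) / 3
  epshat <- fftn(field@eps)
  gradEps <- lapply(specGradFromHat(epshat, ops), Re)
  dS <- function(comp, axis) {
    khat <- switch(axis, ops$kx, ops$ky, ops$kz)
    Re(ifftn(1i * khat * fftn(sig[, , , comp])))
  }
  ## divSigma_j = sum_i d_i Sigma_ij ; components (xx,yy,zz,xy,xz,yz)
  divSigma <- list(
    dS(1, 1) + dS(4, 2) + dS(5, 3),
    dS(4, 1) + dS(2, 2) + dS(6, 3),
    dS(5, 1) + dS(6, 2) + dS(3, 3))
  aniso <- sig
  aniso[, , , 1] <- sig[, , , 1] - sigmaIso
  aniso[, , , 2] <- sig[, , , 2] - sigmaIso
  aniso[, , , 3] <- sig[, , , 3] - sigmaIso
  hasAniso <- max(abs(aniso)) > 1e-12 * max(abs(sig), 1e-300)
  list(ops = ops, sigmaIso = sigmaIso, eps = field@eps, gradEps = gradEps,
       divSigma = divSigma, aniso = aniso, hasAniso = hasAniso,
       dims = field@dims)
}

#' Apply the frequency-domain scattering operator
#'
#' Computes R phi_w: the permittivity-gradient, conductivity-gradient and
#' anisotropy terms with the prefactor
#' (sigma + I w eps) / (sigma^2 + w^2 eps^2), all derivatives spectral.
#' For a homogeneous isotropic field the result is identically zero.
#'
#' @param field a \linkS4class{TensorField}
#' @param omega bin frequency in Hz (converted internally to angular
#'   frequency, the time-derivative convention d/dt -> -I w).
#' @param phi complex (or real) 3D array
#' @return complex 3D array
#' @export
applyRhat <- function(field, omega, phi) {
  stopifnot(is(field, "TensorField"), identical(dim(phi), as.integer(field@dims)))
  if (!all(is.finite(Re(phi))) || (is.complex(phi) && !all(is.finite(Im(phi)))))
    stop("non-finite potential passed to the scattering operator")
  applyRhatCtx(makeRhatContext(field), omega, phi)
}

applyRhatCtx <- function(ctx, omega, phi) {
  w <- 2 * pi * omega
  ops <- ctx$ops
  phihat <- fftn(phi)
  g <- specGradFromHat(phihat, ops)
  acc <- (1i * w * ctx$gradEps[[1]] - ctx$divSigma[[1]]) * g[[1]] +
         (1i * w * ctx$gradEps[[2]] - ctx$divSigma[[2]]) * g[[2]] +
         (1i * w * ctx$gradEps[[3]] - ctx$divSigma[[3]]) * g[[3]]
  if (ctx$hasAniso) {
    hess <- function(ka, kb) ifftn(-(ka * kb) * phihat)
    acc <- acc -
      (ctx$aniso[, , , 1] * hess(ops$kx, ops$kx) +
       ctx$aniso[, , , 2] * hess(ops$ky, ops$ky) +
       ctx$aniso[, , , 3] * hess(ops$kz, ops$kz) +
       2 * ctx$aniso[, , , 4] * hess(ops$kx, ops$ky) +
       2 * ctx$aniso[, , , 5] * hess(ops$kx, ops$kz) +
       2 * ctx$aniso[, , , 6] * hess(ops$ky, ops$kz))
  }
  pref <- (ctx$sigmaIso + 1i * w * ctx$eps) /
    (ctx$sigmaIso^2 + w^2 * ctx$eps^2)
  pref * acc
}

#' Embed measured electrode coefficients as an initial volume
#'
#' Builds the initial iterate phi^(0) of the fixed-point solve from the
#' per-channel Fourier coefficients at one bin. Two embeddings:
#' \describe{
#'  \item{minnorm (default)}{a depth-weighted minimum-norm estimate of an
#'   interior source distribution consistent with the measurements, computed
#'   against the Green's functions of the tissue-aware frequency-domain
#'   operator (one fixed-point forward solve per sensor voxel; the operator
#'   is complex-symmetric so sensor-centered solves give full gain rows) and
#'   standardized by its per-voxel resolution variance (so single compact
#'   sources are located without the superficial bias of plain minimum
#'   norm); phi^(0) is the spectral Poisson solve of that source volume.}
#'  \item{sensor}{the measured coefficients placed as point sources at the
#'   sensor voxels, phi^(0) = invertLaplacian(source). Simple and fully
#'   local, but its |phi| maxima sit at the sensor voxels themselves.}
#' }
#' Both are deterministic and linear in the coefficients.
#'
#' @param field a \linkS4class{TensorField}
#' @param sensors a \linkS4class{SensorArray}
#' @param coeffs complex vector, one coefficient per channel
#' @param omega bin frequency in Hz (kept for interface symmetry; the
#'   embedding itself is frequency-independent)
#' @param method "minnorm" or "sensor"
#' @param lambda relative Tikhonov regularization (minnorm)
#' @param support optional logical array restricting candidate source
#'   voxels (minnorm); defaults to voxels whose isotropic conductivity
#'   exceeds 1000x the grid minimum (i.e. tissue, not background), or all
#'   voxels when the field is homogeneous.
#' @param focussPasses number of iteratively-reweighted sharpening passes
#'   applied to the minimum-norm estimate (0 disables; default 1). The
#'   reweighting concentrates a diffuse estimate onto its dominant compact
#'   component before the Poisson embedding.
#' @return complex 3D array phi^(0)
#' @export
initializePhi0 <- function(field, sensors, coeffs, omega,
                           method = c("minnorm", "sensor"),
                           lambda = 1e-8, support = NULL, focussPasses = 1L) {
  method <- match.arg(method)
  stopifnot(is(field, "TensorField"), is(sensors, "SensorArray"),
            length(coeffs) == length(sensors@names))
  ctx <- makeRhatContext(field)
  initializePhi0Ctx(ctx, sensors, coeffs, omega, method = method,
                    lambda = lambda, support = support,
                    focussPasses = focussPasses)
}

## Solve the frequency-domain equation L phi = R phi + src by direct
## fixed-point iteration phi <- phi_src + invLap(R phi); geometric
## convergence whenever the scattering gain is < 1.
solveForwardBin <- function(ctx, omega, srcVol, K = 40L, tol = 1e-8) {
  phiSrc <- invertLaplacianOps(srcVol - mean(srcVol), ctx$ops)
  phi <- phiSrc
  n0 <- sqrt(sum(Mod(phiSrc)^2))
  if (n0 == 0) return(phiSrc)
  for (k in seq_len(K)) {
    phiNew <- phiSrc + invertLaplacianOps(applyRhatCtx(ctx, omega, phi),
                                          ctx$ops)
    dn <- sqrt(sum(Mod(phiNew - phi)^2))
    phi <- phiNew
    if (dn < tol * n0) break
  }
  phi
}

sensorVoxelIndex <- function(sensors, dims) {
  svox <- round(sensors@voxels) + 1L     # nearest voxel, 1-based
  if (any(svox < 1L) || any(sweep(svox, 2, dims, `>`)))
    stop("sensor voxel outside grid")
  svox[, 1] + (svox[, 2] - 1L) * dims[1] +
    (svox[, 3] - 1L) * dims[1] * dims[2]
}

initializePhi0Ctx <- function(ctx, sensors, coeffs, omega,
                              method = "minnorm", lambda = 1e-8,
                              support = NULL, focussPasses = 1L) {
  if (!all(is.finite(Mod(coeffs)))) stop("non-finite sensor coefficients")
  dims <- ctx$dims
  ops <- ctx$ops
  sidx <- sensorVoxelIndex(sensors, dims)

  if (method == "sensor" || all(Mod(coeffs) == 0)) {
    src <- array(0i, dims)
    src[sidx] <- src[sidx] + coeffs
    return(invertLaplacianOps(src - mean(src), ops))
  }

  if (is.null(support)) {
    s <- ctx$sigmaIso
    keep <- s > 1e3 * min(s)
    if (!any(keep)) keep <- array(TRUE, dims)
    support <- keep
  }
  vidx <- which(support)
  ## Gain matrix against the tissue-aware frequency-domain operator: the
  ## divergence form nabla.((sigma - I w eps) nabla) is complex-symmetric,
  ## so its Green's functions satisfy G(x, y) = G(y, x) and one forward
  ## solve per sensor voxel fills a full row A[c, v] = G(x_c, x_v).
  pref <- (ctx$sigmaIso + 2i * pi * omega * ctx$eps) /
    (ctx$sigmaIso^2 + (2 * pi * omega)^2 * ctx$eps^2)
  ## each sensor's footprint is its trilinear interpolation stencil, so the
  ## gain matches the trilinear sampling used on the measurement side
  Wsens <- trilinearWeights(sensors@voxels, dims)
  A <- matrix(0i, nrow(Wsens), length(vidx))
  for (c in seq_len(nrow(Wsens))) {
    d <- array(Wsens[c, ] * as.vector(pref), dims)  # 1/(sigma - I w eps) scaling
    gc <- solveForwardBin(ctx, omega, d)
    A[c, ] <- gc[vidx]
  }
  ## Depth-weighted minimum-norm source estimate, standardized by its
  ## resolution variance (so a single compact source is located without
  ## the superficial bias of plain minimum norm), then sharpened by a few
  ## iteratively reweighted (FOCUSS-type) passes so the embedded source is
  ## compact rather than diffuse.
  w2 <- colSums(Mod(A)^2)
  w2[w2 == 0] <- min(w2[w2 > 0], 1)
  weighted <- function(Dw, standardize) {
    M <- A %*% (Dw * Conj(t(A)))
    M <- M + diag(lambda * mean(Re(diag(M))), nrow(M))
    Minv <- solve(M)
    est <- Dw * as.vector(Conj(t(A)) %*% (Minv %*% coeffs))
    if (standardize) {
      Svv <- Dw^2 * Re(colSums(Conj(A) * (Minv %*% A)))
      Svv[Svv <= 0] <- min(Svv[Svv > 0], 1)
      est <- est / sqrt(Svv)
    }
    est
  }
  est <- weighted(1 / w2, standardize = TRUE)
  for (p in seq_len(focussPasses)) {
    ## reweight by the standardized estimate under a tempered depth prior:
    ## the standardized map overshoots slightly outward, a full 1/w2 prior
    ## pulls inward; exponent 3/4 balances the two for deep and shallow
    ## sources alike
    Dw <- Mod(est)^2 / w2^0.75
    mx <- max(Dw)
    if (mx == 0) break
    est <- weighted(Dw / mx, standardize = FALSE)
  }
  src <- array(0i, dims)
  src[vidx] <- est
  invertLaplacianOps(src - mean(src), ops)
}

#' Solve one frequency bin of the inverse problem
#'
#' Runs the fixed-point iteration phi^(k) = invertLaplacian(R phi^(k-1))
#' from the embedded phi^(0), accumulates the Cesaro average
#' phiTilde = alpha_K sum_k phi^(k) with alpha_K = 1/(K+1), stops at K
#' iterations or when the relative L2 change of the accumulated sum drops
#' below tol, and finally rescales phiTilde by the complex least-squares
#' factor that best matches the sampled values at the sensor voxels to the
#' measured coefficients.
#'
#' @param field a \linkS4class{TensorField}
#' @param sensors a \linkS4class{SensorArray}
#' @param coeffs complex vector of per-channel coefficients at this bin
#' @param omega bin frequency (Hz)
#' @param config an \code{\link{inverseConfig}}
#' @return complex 3D array phiTilde_w, with attribute \code{diagnostics}
#'   (iterations, relative changes, rescale factor)
#' @export
iterateInverse <- function(field, sensors, coeffs, omega,
                           config = inverseConfig()) {
  stopifnot(inherits(config, "InverseConfig"))
  coeffs <- as.complex(coeffs)
  if (config$commonAverage) coeffs <- coeffs - mean(coeffs)
  ctx <- makeRhatContext(field)
  iterateInverseCtx(ctx, field, sensors, coeffs, omega, config)
}

iterateInverseCtx <- function(ctx, field, sensors, coeffs, omega, config) {
  phik <- initializePhi0Ctx(ctx, sensors, coeffs, omega,
                            method = config$method, lambda = config$lambda)
  acc <- phik
  n0 <- sqrt(sum(Mod(phik)^2))
  relChanges <- numeric(0)
  iters <- 0L
  if (n0 > 0) {
    for (k in seq_len(config$K)) {
      phik <- invertLaplacianOps(applyRhatCtx(ctx, omega, phik), ctx$ops)
      nk <- sqrt(sum(Mod(phik)^2))
      if (!is.finite(nk) || nk > config$divergenceFactor * n0)
        stop(sprintf("inverse iteration diverged at iterate %d (norm %.3g x phi0)",
                     k, nk / n0))
      acc <- acc + phik
      iters <- k
      rc <- nk / sqrt(sum(Mod(acc)^2))
      relChanges <- c(relChanges, rc)
      if (rc < config$tol) break
    }
  }
  phiTilde <- acc / (iters + 1)
  ## Least-squares complex rescale against the measured coefficients.
  W <- trilinearWeights(sensors@voxels, ctx$dims)
  s <- as.vector(W %*% matrix(phiTilde, ncol = 1))
  den <- sum(Mod(s)^2)
  cfit <- if (den > 0) sum(Conj(s) * coeffs) / den else 1 + 0i
  out <- phiTilde * cfit
  attr(out, "diagnostics") <- list(omega = omega, iterations = iters,
                                   relChange = relChanges, rescale = cfit)
  out
}

#' Reconstruct a band-limited volumetric potential from a recording
#'
#' Fourier-transforms the recording, solves every bin in the band
#' independently, assembles the Hermitian-symmetric volumetric spectrum and
#' inverse-transforms it to the real time-domain 4D potential phiTilde(t,x).
#'
#' @param rec an \linkS4class{EEGRecording}
#' @param field a \linkS4class{TensorField}
#' @param sensors a \linkS4class{SensorArray}
#' @param config an \code{\link{inverseConfig}} (its \code{band} selects
#'   the bins)
#' @return a \linkS4class{SpectralPotential}
#' @examples
#' \donttest{
#' sc <- phantomScenario(seed = 1, dims = c(16, 16, 16), duration = 0.12)
#' rec <- sc$recording
#' out <- reconstructBand(rec, sc$field, sc$sensors,
#'                        inverseConfig(band = c(8, 12), K = 5))
#' }
#' @export
reconstructBand <- function(rec, field, sensors, config = inverseConfig()) {
  stopifnot(is(rec, "EEGRecording"), inherits(config, "InverseConfig"))
  sp <- sensorSpectrum(rec, config$band)
  nBins <- length(sp$freqs)
  if (nBins == 0L)
    stop(sprintf(
      "no Fourier bins fall inside [%g, %g] Hz (resolution %g Hz over %d samples)",
      config$band[1], config$band[2], rec@fs / ncol(rec@data), ncol(rec@data)))
  N <- ncol(rec@data)
  dims <- field@dims
  ctx <- makeRhatContext(field)
  vols <- vector("list", nBins)
  diags <- vector("list", nBins)
  for (b in seq_len(nBins)) {
    coeffs <- sp$coeffs[, b]
    if (config$commonAverage) coeffs <- coeffs - mean(coeffs)
    v <- iterateInverseCtx(ctx, field, sensors, coeffs, sp$freqs[b], config)
    diags[[b]] <- attr(v, "diagnostics")
    attr(v, "diagnostics") <- NULL
    vols[[b]] <- v
  }
  ## Hermitian-symmetric assembly and inverse transform of the time axis:
  ## each retained positive-frequency bin j0 contributes
  ## 2/N * Re(vol * exp(2 pi i f t)).
  phiT <- array(0, c(dims, N))
  nvox <- prod(dims)
  tIdx <- 0:(N - 1)
  for (b in seq_len(nBins)) {
    j0 <- round(sp$freqs[b] * N / rec@fs)
    phase <- exp(2i * pi * j0 * tIdx / N)
    herm <- if (j0 == 0 || (N %% 2 == 0 && j0 == N %/% 2)) 1 else 2
    contrib <- Re(matrix(vols[[b]], nvox, 1) %*% matrix(phase, 1, N)) * herm / N
    phiT <- phiT + array(contrib, c(dims, N))
  }
  new("SpectralPotential", freqs = sp$freqs, volumes = vols, phiT = phiT,
      fs = rec@fs, nTime = as.integer(N), diagnostics = diags)
}
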