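## Time-domain pseudo-spectral integration of the damped tissue-wave
## equation d/dt(laplacian phi) = -div(Sigma . grad phi) (+ sources).
##
## The integrated variable is u = laplacian(phi); phi is recovered through
## the spectral inverse Laplacian in the zero-mean gauge at every stage.
## Classical RK4 with dt = 0.1 / max|Sigma| by default.

#' Oscillatory point source specification
#'
#' An additive term on the right-hand side of the wave equation, localized
#' to a single voxel, with a sinusoidal time course inside an on/off window.
#' Sources are synthetic-ground-truth fixtures: the model's internal
#' nonlinear source term is deliberately not modeled.
#'
#' @param position integer(3), 0-based voxel index.
#' @param frequency oscillation frequency in Hz (>= 0).
#' @param amplitude source strength (potential units / s).
#' @param onset,offset window (s) during which the source is active.
#' @return an object of class \code{SourceSpec}
#' @export
sourceSpec <- function(position, frequency, amplitude = 1,
                       onset = 0, offset = Inf) {
  stopifnot(length(position) == 3L, frequency >= 0, offset >= onset)
  structure(list(position = as.integer(position), frequency = frequency,
                 amplitude = amplitude, onset = onset, offset = offset),
            class = "SourceSpec")
}

#' Right-hand side of the tissue wave equation
#'
#' Returns -div(Sigma . grad phi) with all spatial derivatives computed by
#' Fourier collocation on the periodic grid. This is the operator whose
#' plane-wave symbol gives the dispersion relation (decay from Sigma itself,
#' oscillation from its gradient).
#'
#' @param field a \linkS4class{TensorField}
#' @param phi real or complex 3D array matching the field's grid
#' @return array of the same shape as \code{phi}
#' @export
applyWetcowRhs <- function(field, phi) {
  stopifnot(is(field, "TensorField"), identical(dim(phi), as.integer(field@dims)))
  if (!all(is.finite(Re(phi))))
    stop("non-finite potential passed to the wave operator")
  ops <- makeSpectralOps(field@dims, rep(1, 3))
  applyWetcowRhsOps(field@sigma, fftn(phi), ops, realOutput = !is.complex(phi))
}

## Core operator working from the Fourier transform of phi (1 fwd, 3 inv,
## 3 fwd, 1 inv FFTs per call).
applyWetcowRhsOps <- function(sig, phihat, ops, realOutput = TRUE) {
  g <- specGradFromHat(phihat, ops)
  if (realOutput) g <- lapply(g, Re)
  f <- tensorFlux(sig, g)
  out <- -specDiv(f[[1]], f[[2]], f[[3]], ops)
  if (realOutput) Re(out) else out
}

## Default explicit time step: 0.1 / max|Sigma|.
defaultTimeStep <- function(field) {
  smax <- max(abs(field@sigma))
  if (smax == 0) stop("cannot choose a time step for an all-zero field; give dt")
  0.1 / smax
}

#' Integrate the wave equation forward in time
#'
#' RK4 integration of u = laplacian(phi) with phi recovered spectrally at
#' every stage, starting from \code{phi0} at t = 0. Optional point sources
#' inject a sinusoidal term into du/dt at their voxel. States are recorded
#' every \code{outputEvery} steps (the initial state included). In
#' source-free runs, growth of the L2 norm of phi beyond
#' \code{growthLimit} times its running minimum aborts with an integration
#' error, since the continuous dynamics are non-expansive whenever Sigma is
#' positive semidefinite.
#'
#' @param phi0 real 3D array, initial potential (mean is projected out:
#'   zero-mean gauge).
#' @param field a \linkS4class{TensorField}.
#' @param duration total integration time (s).
#' @param sources list of \code{\link{sourceSpec}} objects.
#' @param dt time step (s); default 0.1 / max|Sigma|.
#' @param outputEvery record every this many steps.
#' @param growthLimit source-free instability threshold (amplitude factor).
#' @return a list of class \code{WaveTrajectory}: \code{times} (s),
#'   \code{phis} (4D array dims x frames), \code{dt}, \code{dims}.
#' @examples
#' g <- sphericalPhantom(c(16, 16, 16), c(5, 7), c(3, 2))
#' f <- buildTensorField(g)
#' phi0 <- array(0, gridDims(g))
#' src <- sourceSpec(c(8, 8, 8), frequency = 10, amplitude = 1)
#' tr <- evolveWetcow(phi0, f, duration = 0.02, sources = list(src))
#' @export
evolveWetcow <- function(phi0, field, duration, sources = list(),
                         dt = NULL, outputEvery = 1L, growthLimit = 1.5) {
  stopifnot(is(field, "TensorField"),
            identical(dim(phi0), as.integer(field@dims)))
  if (is.null(dt)) dt <- defaultTimeStep(field)
  if (dt <= 0) stop("dt must be positive")
  nSteps <- max(1L, ceiling(duration / dt))
  ops <- makeSpectralOps(field@dims, rep(1, 3))
  sig <- field@sigma

  srcVol <- NULL
  if (length(sources)) {
    srcVol <- lapply(sources, function(s) {
      pos <- s$position + 1L
      if (any(pos < 1L) || any(pos > field@dims))
        stop("source position outside grid")
      v <- array(0, field@dims)
      v[pos[1], pos[2], pos[3]] <- s$amplitude
      v
    })
  }
  sourceTerm <- function(t) {
    out <- NULL
    for (i in seq_along(sources)) {
      s <- sources[[i]]
      if (t < s$onset || t > s$offset) next
      w <- srcVol[[i]] * sin(2 * pi * s$frequency * t)
      out <- if (is.null(out)) w else out + w
    }
    out
  }

  rhs <- function(u, t) {
    phihat <- ops$invLap * fftn(u)
    r <- applyWetcowRhsOpsHat(sig, phihat, ops)
    st <- if (length(sources)) sourceTerm(t) else NULL
    if (!is.null(st)) r <- r + st
    r
  }

  u <- Re(specLaplacian(phi0 - mean(phi0), ops))
  nFrames <- nSteps %/% outputEvery + 1L
  phis <- array(0, c(field@dims, nFrames))
  times <- numeric(nFrames)
  phis[, , , 1] <- invertLaplacianOps(u, ops)
  frame <- 1L
  minNorm <- sqrt(sum(phis[, , , 1]^2))
  t <- 0
  for (step in seq_len(nSteps)) {
    k1 <- rhs(u, t)
    k2 <- rhs(u + dt / 2 * k1, t + dt / 2)
    k3 <- rhs(u + dt / 2 * k2, t + dt / 2)
    k4 <- rhs(u + dt * k3, t + dt)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- step * dt
    if (!all(is.finite(u)))
      stop(sprintf("integration diverged (non-finite state at step %d)", step))
    if (step %% outputEvery == 0L) {
      frame <- frame + 1L
      phi <- invertLaplacianOps(u, ops)
      phis[, , , frame] <- phi
      times[frame] <- t
      if (!length(sources)) {
        nrm <- sqrt(sum(phi^2))
        if (nrm > growthLimit * minNorm && minNorm > 0)
          stop(sprintf(
            "integration unstable: source-free amplitude grew by %.3g at t=%.4g",
            nrm / minNorm, t))
        minNorm <- min(minNorm, nrm)
      }
    }
  }
  structure(list(times = times[seq_len(frame)],
                 phis = phis[, , , seq_len(frame), drop = FALSE],
                 dt = dt, dims = field@dims),
            class = "WaveTrajectory")
}

## rhs core given phihat directly (real fields).
applyWetcowRhsOpsHat <- function(sig, phihat, ops) {
  g <- lapply(specGradFromHat(phihat, ops), Re)
  f <- tensorFlux(sig, g)
  Re(-specDiv(f[[1]], f[[2]], f[[3]], ops))
}

#' Reduced boundary-layer wave equations on a 1D periodic domain
#'
#' Integrates the two thin-layer branches obtained from the idealized
#' fiber-boundary tensor with profile constants a = profile(x0) and
#' b = profile'(x0):
#' \itemize{
#'  \item \code{parallel}: ((d/dt + a) d^2/dz^2 + b d/dz) phi = 0 -- a damped
#'    oscillator; a single mode k decays at rate a while oscillating at b/k.
#'  \item \code{transverse}: (d/dt d^2/dy^2 + b d/dy) phi = 0 -- no damping
#'    term; a single mode oscillates at b/k with conserved amplitude
#'    (frequency ~ 1/k, phase speed ~ 1/k^2).
#' }
#' The initial condition is the single complex mode exp(i k y); k must be a
#' harmonic of the domain (k = 2 pi m / (n h), integer m != 0).
#'
#' @param model a \linkS4class{BoundaryLayerModel}
#' @param branch "parallel" or "transverse"
#' @param k wavenumber of the initial mode (1/length)
#' @param duration integration time (s)
#' @param n number of grid points
#' @param h grid spacing
#' @param dt time step; default resolves the stiffest retained mode
#' @param outputEvery record cadence in steps
#' @return list: \code{times}, \code{phis} (complex n x frames matrix),
#'   \code{k}, \code{modeIndex}, \code{branch}, \code{a}, \code{b}
#' @export
simulateBoundaryLayer <- function(model, branch = c("parallel", "transverse"),
                                  k, duration, n = 64L, h = 1,
                                  dt = NULL, outputEvery = 1L) {
  branch <- match.arg(branch)
  stopifnot(is(model, "BoundaryLayerModel"))
  if (k == 0) stop("wavenumber k must be nonzero")
  m <- k * n * h / (2 * pi)
  if (abs(m - round(m)) > 1e-8)
    stop("k must be a harmonic of the periodic domain (k = 2 pi m / (n h))")
  a <- model@a; b <- model@b
  kv <- axisWavenumbers(n, h)
  if (n %% 2 == 0) kv[n %/% 2 + 1] <- 0   # drop Nyquist derivative
  k2 <- kv^2
  invLap <- ifelse(k2 > 0, -1 / k2, 0)

  ## Per-mode complex rates: parallel A' = (-a + i b/k) A; transverse
  ## A' = (i b/k) A. Integrated as a spectral PDE so truncation and
  ## stability behave as in the 3D solver.
  kmin <- 2 * pi / (n * h)
  lamMax <- abs(b) / kmin + (if (branch == "parallel") a else 0)
  if (is.null(dt)) dt <- 0.1 / lamMax
  nSteps <- max(1L, ceiling(duration / dt))

  z <- (0:(n - 1)) * h
  phi <- exp(1i * k * z)
  u <- stats::fft(phi) * (-k2)          # u = d2/dz2 phi, spectral
  rhsHat <- function(uhat) {
    phihat <- invLap * uhat
    dphi <- 1i * kv * phihat
    if (branch == "parallel") -a * uhat - b * dphi else -b * dphi
  }
  nFrames <- nSteps %/% outputEvery + 1L
  phis <- matrix(0 + 0i, n, nFrames)
  times <- numeric(nFrames)
  toPhi <- function(uhat) stats::fft(invLap * uhat, inverse = TRUE) / n
  phis[, 1] <- phi
  frame <- 1L
  for (step in seq_len(nSteps)) {
    k1 <- rhsHat(u)
    k2s <- rhsHat(u + dt / 2 * k1)
    k3 <- rhsHat(u + dt / 2 * k2s)
    k4 <- rhsHat(u + dt * k3)
    u <- u + dt / 6 * (k1 + 2 * k2s + 2 * k3 + k4)
    if (step %% outputEvery == 0L) {
      frame <- frame + 1L
      phis[, frame] <- toPhi(u)
      times[frame] <- step * dt
    }
  }
  list(times = times[seq_len(frame)], phis = phis[, seq_len(frame), drop = FALSE],
       k = k, modeIndex = as.integer(round(m)), branch = branch, a = a, b = b)
}

#' Sample a trajectory at sensor positions
#'
#' Channel time series are the potential at each sensor's (possibly
#' fractional) voxel position, by trilinear interpolation, plus independent
#' Gaussian noise of the given standard deviation.
#'
#' @param trajectory a \code{WaveTrajectory} from \code{\link{evolveWetcow}}
#' @param sensors a \linkS4class{SensorArray} on the same grid
#' @param noiseSd noise standard deviation (same units as phi)
#' @param seed optional integer seed for the noise
#' @return an \linkS4class{EEGRecording} with fs = 1 / frame interval
#' @export
sampleSensors <- function(trajectory, sensors, noiseSd = 0, seed = NULL) {
  stopifnot(inherits(trajectory, "WaveTrajectory"), is(sensors, "SensorArray"))
  if (!identical(as.integer(sensors@dims), as.integer(trajectory$dims)))
    stop("sensor array was mapped to a different grid")
  nt <- length(trajectory$times)
  phisMat <- matrix(trajectory$phis, prod(trajectory$dims), nt)
  W <- trilinearWeights(sensors@voxels, trajectory$dims)
  data <- W %*% phisMat
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    data <- data + matrix(rnorm(length(data), sd = noiseSd), nrow(data))
  }
  if (nt < 2) stop("trajectory has fewer than two frames; cannot set fs")
  fs <- 1 / mean(diff(trajectory$times))
  rownames(data) <- sensors@names
  new("EEGRecording", data = as.matrix(data), fs = fs, t0 = trajectory$times[1])
}

## Sparse-ish trilinear interpolation matrix: rows = sensors, cols = voxels.
## Positions are 0-based fractional voxel coordinates.
trilinearWeights <- function(pos, dims) {
  n <- nrow(pos)
  W <- matrix(0, n, prod(dims))
  for (s in seq_len(n)) {
    p <- pmin(pmax(pos[s, ], 0), dims - 1)
    i0 <- pmin(floor(p), dims - 2); i0 <- pmax(i0, 0)
    f <- p - i0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, f, 1 - f))
      if (w == 0) next
      idx <- (i0[1] + cx + 1) +
        (i0[2] + cy) * dims[1] +
        (i0[3] + cz) * dims[1] * dims[2]
      W[s, idx] <- W[s, idx] + w
    }
  }
  W
}
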