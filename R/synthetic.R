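## Synthetic ground-truth generators: planted spatiotemporal modes for the
## decomposition module, and the layered-sphere closed-loop phantom used to
## validate the full forward -> sensors -> inverse chain.

#' Planted-mode 4D dataset
#'
#' Generates data = sum_m a_m map_m (x) tc_m + noise: compact soft-edged
#' spherical spatial patterns at well-separated centers (effectively
#' disjoint supports), sinusoidal time courses at distinct frequencies
#' (orthogonal over the window), geometrically decreasing amplitudes, and
#' white Gaussian noise. The signal-to-noise ratio is defined as peak mode
#' amplitude over noise standard deviation:
#' noiseSd = max_m (a_m * max(map_m) * rms(tc_m)) / snr. Plateau-like
#' patterns are used deliberately: a correlation-based coupling matrix
#' carries a mode's support, not its graded amplitude profile, so plateaus
#' are the shape an eigen-decomposition can be expected to reproduce.
#'
#' @param dims integer(3) grid (default 10^3).
#' @param nModes number of planted modes.
#' @param nTime number of time points.
#' @param snr peak-signal-to-noise ratio (default 10).
#' @param seed integer seed.
#' @return list: \code{data} (4D array), \code{maps} (nvox x nModes, unit
#'   L2 over the full volume), \code{timecourses}, \code{amplitudes},
#'   \code{noiseSd}
#' @export
makePlantedModes <- function(dims = c(10, 10, 10), nModes = 3, nTime = 200,
                             snr = 10, seed = 1) {
  set.seed(seed)
  dims <- as.integer(dims)
  nvox <- prod(dims)
  ax <- lapply(1:3, function(d) seq_len(dims[d]))
  co <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  ## tetrahedrally staggered centers keep supports strictly disjoint (up
  ## to four modes); further modes fall on the main diagonal
  frac <- rbind(c(0.27, 0.27, 0.27), c(0.73, 0.73, 0.27),
                c(0.73, 0.27, 0.73), c(0.27, 0.73, 0.73))
  if (nModes > 4) {
    fr <- (5:nModes - 0.5) / nModes
    frac <- rbind(frac, cbind(fr, fr, fr))
  }
  centers <- 1 + frac[seq_len(nModes), , drop = FALSE] %*% diag(dims - 1)
  R <- min(dims) / 5.5
  maps <- matrix(0, nvox, nModes)
  for (m in seq_len(nModes)) {
    d <- sqrt(rowSums(sweep(co, 2, centers[m, ])^2))
    g <- 1 / (1 + exp((d - R) / 0.5))           # soft-edged ball
    g[d > R + 1.2] <- 0                         # hard support truncation
    maps[, m] <- g / sqrt(sum(g^2))
  }
  tt <- seq_len(nTime)
  tcs <- sapply(seq_len(nModes), function(m) sin(2 * pi * m * tt / nTime))
  amps <- 1 * 0.8^(seq_len(nModes) - 1)
  clean <- maps %*% (t(tcs) * amps)
  noiseSd <- max(vapply(seq_len(nModes), function(m)
    amps[m] * max(maps[, m]) * sqrt(mean(tcs[, m]^2)), numeric(1))) / snr
  data <- clean + rnorm(length(clean), sd = noiseSd)
  list(data = array(data, c(dims, nTime)), maps = maps, timecourses = tcs,
       amplitudes = amps, noiseSd = noiseSd)
}

#' Fibonacci-lattice surface sensors
#'
#' Places \code{n} sensors quasi-uniformly on a sphere of given radius
#' (voxel units) around the grid center -- a deterministic stand-in for a
#' scalp electrode montage on phantom grids.
#'
#' @param grid a \linkS4class{TissueGrid} (or integer(3) dims)
#' @param n number of sensors
#' @param radius sphere radius in voxels
#' @return a \linkS4class{SensorArray}
#' @export
surfaceSensors <- function(grid, n = 24, radius) {
  dims <- if (is(grid, "TissueGrid")) gridDims(grid) else as.integer(grid)
  ctr <- (dims - 1) / 2
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  pos <- cbind(ctr[1] + radius * sin(phi) * cos(theta),
               ctr[2] + radius * sin(phi) * sin(theta),
               ctr[3] + radius * cos(phi))
  new("SensorArray", names = sprintf("S%02d", seq_len(n)), voxels = pos,
      world = matrix(numeric(0), 0, 3), dims = as.integer(dims))
}

#' Closed-loop phantom scenario with known ground truth
#'
#' Builds a two-shell spherical phantom (white-matter core, gray-matter
#' shell) on a cubic grid, places surface sensors just inside the outer
#' tissue boundary, plants one or two oscillatory point sources at known
#' voxels, integrates the wave equation forward, and samples the sensors.
#' The tissue table is the default gray/white table; CSF is omitted from
#' the wave phantom because its scaled conductivity (sigma/eps ~ 1e9 1/s)
#' equilibrates potentials essentially instantaneously compared to tissue
#' and would only re-impose a boundary value.
#'
#' @param seed integer seed controlling the source position draw.
#' @param dims grid dimensions (default 32^3).
#' @param radii shell radii in voxels (WM core, GM outer; default c(9, 13)).
#' @param nSensors number of surface sensors (default 24).
#' @param sensorRadius sensor sphere radius (default just inside the outer
#'   shell).
#' @param sourceFreqs frequencies (Hz) of the planted sources; one source
#'   per entry.
#' @param sourceMaxDepthRadius a single source is drawn uniformly among
#'   voxels within this distance of the center (default 4: deep sources).
#' @param sourceRadii for multiple sources, the center distance of each
#'   (default: evenly spread from 2 voxels to just inside the core), so
#'   sources sit at distinct depths; directions are seeded random with a
#'   minimum mutual separation of 5 voxels.
#' @param duration total simulated time (s).
#' @param settle initial transient discarded from the recording (s).
#' @param fsOut sensor sampling rate (Hz); must give an integer frame step.
#' @param noiseSd sensor noise standard deviation (default 0).
#' @param smoothing partial-volume smoothing (voxels) passed to
#'   \code{\link{buildTensorField}}; default 2 so label-jump gradients are
#'   resolved on the grid.
#' @return list: \code{grid}, \code{field}, \code{sensors}, \code{sources}
#'   (list of sourceSpec), \code{sourceVoxels} (0-based matrix),
#'   \code{trajectory}, \code{recording} (settled window only)
#' @export
phantomScenario <- function(seed = 1, dims = c(32, 32, 32), radii = c(9, 13),
                            nSensors = 24, sensorRadius = max(radii) - 0.2,
                            sourceFreqs = 10, sourceMaxDepthRadius = 4,
                            duration = 0.36, settle = 0.16, fsOut = 125,
                            noiseSd = 0, smoothing = 2, sourceRadii = NULL) {
  dims <- as.integer(dims)
  grid <- sphericalPhantom(dims, radii, c(LABEL_WM, LABEL_GM))
  field <- buildTensorField(grid, smoothing = smoothing)
  sensors <- surfaceSensors(grid, n = nSensors, radius = sensorRadius)

  set.seed(seed)
  ctr <- (dims - 1) / 2
  nSrc <- length(sourceFreqs)
  srcVox <- matrix(0L, nSrc, 3)
  if (nSrc == 1L) {
    repeat {
      v <- round(ctr + runif(3, -sourceMaxDepthRadius, sourceMaxDepthRadius))
      if (sqrt(sum((v - ctr)^2)) <= sourceMaxDepthRadius) break
    }
    srcVox[1, ] <- as.integer(v)
  } else {
    ## multiple sources sit at distinct depths (the different-depth,
    ## different-frequency discrimination scenario), seeded directions
    if (is.null(sourceRadii))
      sourceRadii <- seq(2, min(radii[1] - 2, 7), length.out = nSrc)
    for (s in seq_len(nSrc)) {
      repeat {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        v <- round(ctr + sourceRadii[s] * u)
        ok <- s == 1 ||
          min(sqrt(rowSums(sweep(srcVox[seq_len(s - 1), , drop = FALSE],
                                 2, v)^2))) >= 5
        if (ok) break
      }
      srcVox[s, ] <- as.integer(v)
    }
  }
  sources <- lapply(seq_len(nSrc), function(s)
    sourceSpec(srcVox[s, ], frequency = sourceFreqs[s], amplitude = 1))

  dt <- defaultTimeStep(field)
  frameStep <- round(1 / (fsOut * dt))
  dt <- 1 / (fsOut * frameStep)          # snap dt so frames land on 1/fsOut
  traj <- evolveWetcow(array(0, dims), field, duration, sources = sources,
                       dt = dt, outputEvery = frameStep)
  rec <- sampleSensors(traj, sensors, noiseSd = noiseSd,
                       seed = if (noiseSd > 0) seed + 1L else NULL)
  keep <- which(traj$times >= settle - 1e-9)
  nWin <- round((duration - settle) * fsOut)   # exact-bin analysis window
  keep <- keep[seq_len(min(length(keep), nWin))]
  recW <- new("EEGRecording", data = rec@data[, keep, drop = FALSE],
              fs = rec@fs, t0 = traj$times[keep[1]])
  list(grid = grid, field = field, sensors = sensors, sources = sources,
       sourceVoxels = srcVox, trajectory = traj, recording = recW)
}
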