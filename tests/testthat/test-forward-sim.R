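test_that("spectral Laplacian inversion has the right eigenvalues", {
  dims <- c(16, 16, 16)
  m <- c(3, 1, 2)
  k2 <- sum((2 * pi * m / dims)^2)
  phi <- planeWave(dims, m)
  ## single mode of amplitude A maps to -A/k^2
  out <- invertLaplacian(phi)
  expect_equal(out, -phi / k2, tolerance = 1e-12)
  ## round trip restores the zero-mean part
  x <- array(rnorm(prod(dims)), dims) + 5
  lap <- spectre:::specLaplacian(x, spectre:::makeSpectralOps(dims))
  expect_equal(invertLaplacian(Re(lap)), x - mean(x), tolerance = 1e-9)
  expect_true(all(invertLaplacian(array(0, dims)) == 0))
})

test_that("the wave operator acts like -s k^2 on plane waves", {
  dims <- c(16, 16, 16)
  s <- 40
  f <- homogeneousField(dims, s)
  ## constant potential: zero response
  expect_equal(max(abs(applyWetcowRhs(f, array(3.2, dims)))), 0,
               tolerance = 1e-12)
  ## plane-wave eigenfunction: -div(s grad phi) = +s k^2 phi
  m <- c(2, 0, 3)
  k2 <- sum((2 * pi * m / dims)^2)
  phi <- planeWave(dims, m)
  expect_equal(applyWetcowRhs(f, phi), s * k2 * phi, tolerance = 1e-10)
  ## linearity
  g <- sphericalPhantom(dims, c(5, 7), c(3L, 2L))
  fv <- buildTensorField(g, smoothing = 1)
  p1 <- array(rnorm(prod(dims)), dims)
  p2 <- array(rnorm(prod(dims)), dims)
  expect_equal(applyWetcowRhs(fv, p1 + p2),
               applyWetcowRhs(fv, p1) + applyWetcowRhs(fv, p2),
               tolerance = 1e-10)
  expect_error(applyWetcowRhs(f, array(NaN, dims)), "non-finite")
})

test_that("homogeneous evolution decays at sigma/eps for random media", {
  set.seed(11)
  dims <- c(12, 12, 12)
  for (rep in 1:20) {
    s <- runif(1, 20, 150)
    f <- homogeneousField(dims, s)
    phi0 <- planeWave(dims, sample(0:3, 3, replace = TRUE) +
                        c(1, 0, 0))             # nonzero mode
    tr <- evolveWetcow(phi0, f, duration = 3 / s, outputEvery = 4)
    amp <- apply(tr$phis, 4, function(v) sqrt(mean(v^2)))
    rate <- -stats::coef(stats::lm(log(amp) ~ tr$times))[2]
    expect_rel(rate, s, 0.01)
  }
})

test_that("a zero-conductivity medium freezes the potential", {
  dims <- c(8, 8, 8)
  f <- homogeneousField(dims, 0)
  phi0 <- planeWave(dims, c(1, 2, 0))
  tr <- evolveWetcow(phi0, f, duration = 0.05, dt = 1e-3)
  last <- tr$phis[, , , dim(tr$phis)[4]]
  expect_equal(last, phi0 - mean(phi0), tolerance = 1e-12)
})

test_that("source-free energy never grows in tissue phantoms", {
  g <- sphericalPhantom(c(16, 16, 16), c(5, 7), c(3L, 2L))
  f <- buildTensorField(g, smoothing = 1)
  set.seed(3)
  phi0 <- array(rnorm(prod(gridDims(g))), gridDims(g))
  tr <- evolveWetcow(phi0, f, duration = 0.02, outputEvery = 2)
  en <- apply(tr$phis, 4, function(v) sum(v^2))
  expect_true(all(diff(en) <= 1e-9 * en[1]))
})

test_that("boundary-layer branches: transverse conserves, parallel decays", {
  m <- boundaryLayerModel(epsilon = 0.01, x0 = 0, width = 2, low = 0,
                          high = 20)
  a <- m@a
  T <- 3 / a                                    # a*T = 3
  n <- 64; k <- 2 * pi * 6 / n
  modeAmp <- function(tr) {
    abs(apply(tr$phis, 2, function(p) stats::fft(p)[tr$modeIndex + 1] /
                length(p)))
  }
  tp <- simulateBoundaryLayer(m, "parallel", k, T, n = n, outputEvery = 10)
  ap <- modeAmp(tp)
  rate <- -stats::coef(stats::lm(log(ap) ~ tp$times))[2]
  expect_rel(rate, a, 0.02)
  expect_lt(ap[length(ap)] / ap[1], 0.10)       # < 10% retained
  tt <- simulateBoundaryLayer(m, "transverse", k, T, n = n, outputEvery = 10)
  at <- modeAmp(tt)
  expect_lt(max(abs(at / at[1] - 1)), 0.001)    # conserved to 0.1%
  expect_gt(at[length(at)] / at[1], 0.99)
  expect_error(simulateBoundaryLayer(m, "transverse", 0, 1), "nonzero")
})

test_that("transverse mode frequency scales as b/k (phase speed ~ 1/k^2)", {
  m <- boundaryLayerModel(epsilon = 0.01, x0 = 0, width = 2, low = 0,
                          high = 20)
  n <- 64
  unwrap <- function(ph) {
    d <- diff(ph); d <- d - 2 * pi * round(d / (2 * pi)); cumsum(c(ph[1], d))
  }
  freqOf <- function(mult) {
    k <- 2 * pi * mult / n
    tr <- simulateBoundaryLayer(m, "transverse", k, 1.5, n = n,
                                outputEvery = 10)
    ph <- apply(tr$phis, 2, function(p)
      Arg(stats::fft(p)[tr$modeIndex + 1]))
    stats::coef(stats::lm(unwrap(ph) ~ tr$times))[2]
  }
  w4 <- freqOf(4); w8 <- freqOf(8)
  expect_rel(w4, m@b / (2 * pi * 4 / n), 0.01)
  expect_rel(w8, m@b / (2 * pi * 8 / n), 0.01)
  expect_rel(w4 / w8, 2, 0.01)                  # omega ~ 1/k
})

test_that("sensor sampling interpolates, is deterministic, and adds
           calibrated noise", {
  dims <- c(6L, 6L, 6L)
  nt <- 10000L
  set.seed(5)
  phis <- array(rnorm(prod(dims) * nt), c(dims, nt))
  traj <- structure(list(times = (0:(nt - 1)) * 1e-3, phis = phis,
                         dt = 1e-3, dims = dims), class = "WaveTrajectory")
  sens <- makeSensorArray(c("a", "b"), rbind(c(2, 3, 1), c(1.5, 2.25, 4)),
                          dims)
  rec <- sampleSensors(traj, sens, noiseSd = 0)
  ## voxel-centered sensor reproduces the voxel series exactly
  expect_equal(rec@data[1, ], phis[3, 4, 2, ], tolerance = 1e-12)
  expect_equal(samplingRate(rec), 1000)
  ## determinism with a seed
  r1 <- sampleSensors(traj, sens, noiseSd = 0.5, seed = 9)
  r2 <- sampleSensors(traj, sens, noiseSd = 0.5, seed = 9)
  expect_identical(r1@data, r2@data)
  ## noise sd within 10% at 1e4 samples
  resid <- r1@data[1, ] - rec@data[1, ]
  expect_rel(stats::sd(resid), 0.5, 0.10)
  bad <- makeSensorArray("x", rbind(c(2, 3, 1)), c(50L, 50L, 50L))
  expect_error(sampleSensors(traj, bad, 0), "different grid")
})
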