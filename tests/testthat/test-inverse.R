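test_that("sensor spectra select exactly the requested bins", {
  fs <- 100; N <- 200
  tt <- (0:(N - 1)) / fs
  data <- rbind(sin(2 * pi * 10 * tt), cos(2 * pi * 10 * tt))
  rownames(data) <- c("a", "b")
  rec <- new("EEGRecording", data = data, fs = fs, t0 = 0)
  sp <- sensorSpectrum(rec, c(8, 12))
  expect_true(10 %in% sp$freqs)
  i10 <- which(sp$freqs == 10)
  others <- Mod(sp$coeffs[1, -i10])
  expect_true(all(others < 1e-10 * Mod(sp$coeffs[1, i10])))
  ## zero signal: all-zero coefficients
  rec0 <- new("EEGRecording", data = matrix(0, 2, N), fs = fs, t0 = 0)
  expect_true(all(Mod(sensorSpectrum(rec0, c(8, 12))$coeffs) == 0))
  ## out-of-band tone never leaks into the selection
  data2 <- rbind(sin(2 * pi * 6 * tt) + sin(2 * pi * 10 * tt))
  rec2 <- new("EEGRecording", data = data2, fs = fs, t0 = 0)
  sp2 <- sensorSpectrum(rec2, c(8, 12))
  expect_true(all(sp2$freqs >= 8 & sp2$freqs <= 12))
  expect_false(6 %in% sp2$freqs)
  expect_error(sensorSpectrum(rec, c(8, 60)), "Nyquist")
})

test_that("the scattering operator vanishes on homogeneous media and is
           linear", {
  dims <- c(12, 12, 12)
  f <- homogeneousField(dims, 76.31)
  set.seed(2)
  phi <- array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))),
               dims)
  expect_lt(max(Mod(applyRhat(f, 10, phi))),
            1e-10 * max(Mod(phi)))
  g <- sphericalPhantom(dims, c(4, 5), c(3L, 2L))
  fv <- buildTensorField(g, smoothing = 1)
  p1 <- array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))), dims)
  p2 <- array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))), dims)
  r12 <- applyRhat(fv, 10, p1 + p2)
  expect_equal(r12, applyRhat(fv, 10, p1) + applyRhat(fv, 10, p2),
               tolerance = 1e-12)
})

test_that("with only a conductivity gradient the operator reduces to the
           gradient term (analytic single-mode oracle)", {
  n <- 32L; dims <- c(n, n, n)
  x <- 0:(n - 1)
  q <- 2 * pi * 2 / n
  s0 <- 3e-2; aAmp <- 5e-3
  epsC <- 3.6e-4
  sigmaRaw <- s0 + aAmp * cos(q * x)             # varies along x only
  sig <- array(0, c(dims, 6))
  for (c in 1:3) sig[, , , c] <- sigmaRaw / epsC # stored scaled tensor
  f <- new("TensorField", dims = dims, voxelSize = c(1, 1, 1), sigma = sig,
           eps = array(epsC, dims))
  kx <- 2 * pi * 3 / n
  phi <- array(exp(1i * kx * x), dims)
  out <- applyRhat(f, 10, phi)
  w <- 2 * pi * 10
  pref <- (sigmaRaw + 1i * w * epsC) / (sigmaRaw^2 + w^2 * epsC^2)
  dsig <- -aAmp * q * sin(q * x)                 # d_x sigma
  expected <- array(pref * (-dsig) * (1i * kx) * exp(1i * kx * x), dims)
  expect_equal(out, expected, tolerance = 1e-10)
})

test_that("measurement embedding is linear, deterministic, and localized", {
  dims <- c(16, 16, 16)
  f <- homogeneousField(dims, 76.31)
  sens <- surfaceSensors(dims, n = 16, radius = 6.5)
  zero <- initializePhi0(f, sens, rep(0 + 0i, 16), 10)
  expect_true(all(Mod(zero) == 0))
  set.seed(8)
  cf <- complex(real = rnorm(16), imaginary = rnorm(16))
  a <- initializePhi0(f, sens, cf, 10)
  b <- initializePhi0(f, sens, cf, 10)
  expect_identical(a, b)                          # deterministic
  a2 <- initializePhi0(f, sens, (2 + 0i) * cf, 10)
  expect_equal(a2, (2 + 0i) * a, tolerance = 1e-9)   # linear in coefficients
  ## a single active sensor produces a field concentrated near it
  one <- rep(0 + 0i, 16); one[5] <- 1 + 0i
  for (method in c("minnorm", "sensor")) {
    p <- initializePhi0(f, sens, one, 10, method = method)
    pk <- arrayInd(which.max(Mod(p)), dims) - 1L
    expect_lt(sqrt(sum((pk - sens@voxels[5, ])^2)), 4)
  }
})

test_that("homogeneous media terminate the iteration at the embedding", {
  dims <- c(12, 12, 12)
  f <- homogeneousField(dims, 76.31)
  sens <- surfaceSensors(dims, n = 12, radius = 4.5)
  set.seed(4)
  cf <- complex(real = rnorm(12), imaginary = rnorm(12))
  cfg <- inverseConfig(band = c(8, 12))
  out <- iterateInverse(f, sens, cf, 10, cfg)
  d <- attr(out, "diagnostics")
  expect_lte(d$iterations, 1)                    # R is null: series ends
  ## the result is a complex multiple of phi^(0)
  cfRef <- cf - mean(cf)
  phi0 <- initializePhi0(f, sens, cfRef, 10)
  ratio <- as.vector(out)[Mod(phi0) > 1e-9 * max(Mod(phi0))] /
    as.vector(phi0)[Mod(phi0) > 1e-9 * max(Mod(phi0))]
  expect_lt(stats::sd(Mod(ratio)) / mean(Mod(ratio)), 1e-6)
  ## zero measurements give the zero volume
  z <- iterateInverse(f, sens, rep(0 + 0i, 12), 10, cfg)
  expect_true(all(Mod(z) == 0))
})

test_that("band reconstruction is linear in the recording and bit
           deterministic", {
  sc <- phantomScenario(seed = 21, dims = c(16, 16, 16), radii = c(4, 6),
                        nSensors = 12, sensorRadius = 5.8,
                        sourceMaxDepthRadius = 2)
  cfg <- inverseConfig(band = c(8, 12), K = 5)
  o1 <- reconstructBand(sc$recording, sc$field, sc$sensors, cfg)
  o2 <- reconstructBand(sc$recording, sc$field, sc$sensors, cfg)
  expect_identical(o1@volumes, o2@volumes)
  recScaled <- new("EEGRecording", data = 3 * sc$recording@data,
                   fs = sc$recording@fs, t0 = sc$recording@t0)
  o3 <- reconstructBand(recScaled, sc$field, sc$sensors, cfg)
  expect_equal(o3@phiT, 3 * o1@phiT, tolerance = 1e-8)
  ## zero recording reconstructs to zero
  rec0 <- new("EEGRecording", data = 0 * sc$recording@data,
              fs = sc$recording@fs, t0 = 0)
  o0 <- reconstructBand(rec0, sc$field, sc$sensors, cfg)
  expect_true(all(o0@phiT == 0))
})

test_that("a single-tone phantom reconstructs a single-frequency time
           course at the source (out-of-bin energy < 1%)", {
  sc <- phantomScenario(seed = 22, dims = c(16, 16, 16), radii = c(4, 6),
                        nSensors = 12, sensorRadius = 5.8,
                        sourceMaxDepthRadius = 2)
  out <- reconstructBand(sc$recording, sc$field, sc$sensors,
                         inverseConfig(band = c(8, 12)))
  sv <- sc$sourceVoxels + 1L
  ts <- out@phiT[sv[1], sv[2], sv[3], ]
  pw <- Mod(stats::fft(ts))^2
  N <- length(ts)
  j10 <- round(10 * N / out@fs) + 1
  inBin <- pw[j10] + pw[N - j10 + 2]
  expect_gt(inBin / sum(pw), 0.99)
  expect_gt(pw[j10] / max(pw[-c(j10, N - j10 + 2)], 1e-300), 100)
})
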