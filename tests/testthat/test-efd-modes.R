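test_that("coupling matrix clips correlations and respects the
           neighborhood", {
  dims <- c(4, 4, 1)
  nt <- 50
  tc <- sin(2 * pi * (1:nt) / 25)
  data <- array(0, c(dims, nt))
  data[1, 1, 1, ] <- tc
  data[2, 1, 1, ] <- tc            # identical neighbor
  data[1, 2, 1, ] <- -tc           # anticorrelated neighbor
  data[3, 3, 1, ] <- stats::rnorm(nt)
  Q <- suppressMessages(couplingMatrix(data, radius = 1.5))
  lin <- function(i, j, k) i + (j - 1) * 4 + (k - 1) * 16
  v <- function(i, j) which(Q@voxelIndex == lin(i, j, 1))
  M <- as.matrix(Q@Q)
  expect_equal(M[v(1, 1), v(2, 1)], 1, tolerance = 1e-12)  # identical pair
  expect_equal(M[v(1, 1), v(1, 2)], 0)                     # clipped at 0
  expect_true(Matrix::isSymmetric(Q@Q))
  expect_true(all(M >= 0))
  ## constant voxels are reported and decoupled
  expect_message(couplingMatrix(data, radius = 1.5), "constant")
  ## beyond the radius there is no coupling
  expect_equal(M[v(1, 1), v(4, 4)], 0)
  expect_error(couplingMatrix(data[, , , 1:4, drop = FALSE]), "8 time points")
})

test_that("independent white-noise voxels have near-zero coupling", {
  set.seed(31)
  dims <- c(3, 3, 3)
  nt <- 10000
  data <- array(stats::rnorm(prod(dims) * nt), c(dims, nt))
  Q <- couplingMatrix(data, radius = 2)
  off <- as.matrix(Q@Q)
  expect_lt(max(off), 0.05)
})

test_that("rank-1 and multi-mode planted patterns are recovered", {
  set.seed(32)
  dims <- c(8, 8, 8)
  nt <- 500
  tc <- sin(2 * pi * (1:nt) / 30)
  d <- sqrt(rowSums(sweep(as.matrix(expand.grid(1:8, 1:8, 1:8)), 2,
                          c(4.5, 4.5, 4.5))^2))
  map <- as.numeric(d <= 2.5)                  # compact ball pattern
  map <- map / sqrt(sum(map^2))
  clean <- map %o% tc
  data <- array(clean + 0.01 * max(clean) * stats::rnorm(length(clean)),
                c(dims, nt))
  Q <- couplingMatrix(data, dense = TRUE)
  ms <- espDecompose(Q, data, 1)
  r <- stats::cor(ms@maps[, 1], map)
  expect_gte(abs(r), 0.99)
  ## time course tracks the planted oscillation
  rt <- stats::cor(ms@timecourses[, 1], tc)
  expect_gte(abs(rt), 0.99)
  ## mu* is a distribution
  expect_gte(min(equilibriumDistribution(ms)), 0)
  expect_equal(sum(equilibriumDistribution(ms)), 1, tolerance = 1e-12)
})

test_that("three planted modes at SNR 10 are recovered above r = 0.95", {
  pm <- makePlantedModes(dims = c(10, 10, 10), nModes = 3, nTime = 200,
                         snr = 10, seed = 33)
  Q <- couplingMatrix(pm$data, radius = 2)
  ms <- espDecompose(Q, pm$data, 3)
  ## match recovered modes to planted ones by best |r|
  rs <- vapply(1:3, function(m) {
    max(abs(stats::cor(ms@maps[, m], pm$maps)))
  }, numeric(1))
  expect_gte(mean(rs), 0.95)
  expect_true(all(diff(modeAmplitudes(ms)) <= 0))
  ## decomposition is deterministic
  ms2 <- espDecompose(Q, pm$data, 3)
  expect_identical(ms@maps, ms2@maps)
  ## asking beyond the available rank warns and truncates
  expect_warning(espDecompose(Q, pm$data, 900), "available")
})

test_that("power maps live in [0,1] with max exactly 1 and truncate by
           rank", {
  pm <- makePlantedModes(dims = c(8, 8, 8), nModes = 4, nTime = 100,
                         snr = 10, seed = 34)
  Q <- couplingMatrix(pm$data, radius = 2)
  ms <- espDecompose(Q, pm$data, 4)
  p <- modePowerMap(ms)
  expect_gte(min(p), 0)
  expect_equal(max(p), 1)
  p2 <- modePowerMap(ms, 2)
  expect_equal(max(p2), 1)
  expect_false(isTRUE(all.equal(p, p2)))
  ## scaling all amplitudes leaves the map unchanged
  ms3 <- ms
  ms3@amplitudes <- 2 * ms3@amplitudes
  expect_equal(modePowerMap(ms3), p, tolerance = 1e-12)
  ## single mode: its squared map rescaled
  ms1 <- espDecompose(Q, pm$data, 1)
  p1 <- modePowerMap(ms1)
  m1 <- modeMap(ms1, 1)^2
  expect_equal(p1, m1 / max(m1), tolerance = 1e-12)
})

test_that("thresholding is inclusive at the boundary and sign-preserving", {
  m <- array(0.5, c(3, 3, 1))
  expect_true(all(thresholdMap(m, 0.6) == 0))
  m2 <- array(c(0.2, 0.6, 0.61, 0.9), c(4, 1, 1))
  out <- thresholdMap(m2)
  expect_equal(as.vector(out), c(0, 0.6, 0.61, 0.9))   # 0.6 retained
  signed <- array(c(-0.7, -0.5, 0.3, 0.8), c(4, 1, 1))
  outS <- thresholdMap(signed, 0.6)
  expect_equal(as.vector(outS), c(-0.7, 0, 0, 0.8))    # sign kept
  expect_error(thresholdMap(m, 1.2), "0, 1")
})

test_that("region means aggregate exactly", {
  map <- array(0.25, c(4, 4, 2))
  atlas <- array(0L, c(4, 4, 2))
  atlas[1:2, , ] <- 1L
  atlas[3:4, , ] <- 2L
  rp <- regionPower(map, atlas)
  expect_equal(rp$meanPower, c(0.25, 0.25))
  ## power confined to one region
  map2 <- array(0, c(4, 4, 2)); map2[1, 1, 1] <- 1
  rp2 <- regionPower(map2, atlas)
  expect_equal(rp2$meanPower[rp2$label == 2], 0)
  expect_gt(rp2$meanPower[rp2$label == 1], 0)
  ## checkerboard averages per half
  chk <- array(rep(c(1, 0), 16), c(4, 4, 2))
  rp3 <- regionPower(chk, atlas)
  expect_equal(rp3$meanPower, c(mean(chk[1:2, , ]), mean(chk[3:4, , ])))
  expect_error(regionPower(map, array(0L, c(3, 3, 3))), "match")
})
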