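test_that("template grids have the standard voxel dimensions and counts", {
  cases <- list("2mm" = list(dims = c(91L, 109L, 91L), count = 902629),
                "1mm" = list(dims = c(182L, 218L, 182L), count = 7221032),
                "0.7mm" = list(dims = c(207L, 256L, 215L), count = 11393280))
  for (res in names(cases)) {
    g <- makeMniGrid(res)
    expect_identical(gridDims(g), cases[[res]]$dims)
    expect_equal(prod(gridDims(g)), cases[[res]]$count)
    expect_true(all(labelVolume(g) == 0L))
  }
  expect_error(makeMniGrid("3mm"), "unknown resolution")
})

test_that("tensor field holds sigma/eps on the diagonal, zero off-diagonal", {
  g <- spectre:::newTissueGrid(c(4, 4, 4), c(1, 1, 1))
  lab <- labelVolume(g)
  lab[1:2, , ] <- 2L   # GM
  lab[3:4, , ] <- 3L   # WM
  g@labels <- lab
  f <- buildTensorField(g)
  sig <- sigmaTensor(f)
  gmRate <- GM_SIGMA / (GM_EPSREL * EPS0)
  wmRate <- WM_SIGMA / (WM_EPSREL * EPS0)
  expect_equal(sig[1, 1, 1, 1], gmRate, tolerance = 1e-12)
  expect_equal(sig[4, 1, 1, 3], wmRate, tolerance = 1e-12)
  expect_true(all(sig[, , , 4:6] == 0))
  ## the printed damping range brackets both rates
  expect_true(gmRate > 75 && gmRate < 115)
  expect_true(wmRate > 75 && wmRate < 115)
  expect_equal(epsVolume(f)[1, 1, 1], GM_EPSREL * EPS0)
  ## zero conductivity gives a zero tensor
  tb <- TissueTable(label = c(0L, 2L, 3L), name = c("bg", "GM", "WM"),
                    sigma = c(0, 0, 0), epsRel = c(1, GM_EPSREL, WM_EPSREL))
  f0 <- buildTensorField(g, tb)
  expect_true(all(sigmaTensor(f0) == 0))
})

test_that("missing label entries are a labeled-data error", {
  g <- spectre:::newTissueGrid(c(3, 3, 3), c(1, 1, 1))
  g@labels[2, 2, 2] <- 7L
  expect_error(buildTensorField(g), "absent from tissue table.*7")
})

test_that("boundary-layer tensor matches the idealized layered form", {
  m <- boundaryLayerModel(epsilon = 0.01, x0 = 0, width = 1, low = 0,
                          high = 20)
  ## profile midpoint: u(x0) = 10
  S <- boundaryLayerTensor(m, 0)
  expect_equal(S[1, 1], 0.1)
  expect_equal(S[3, 3], 10)
  expect_equal(S[2, 3], 0)
  expect_equal(S, t(S))
  ## epsilon = 0: pure along-fiber conduction
  m0 <- boundaryLayerModel(epsilon = 0, x0 = 0, width = 1, low = 0, high = 10)
  S0 <- boundaryLayerTensor(m0, 100)       # far side: u -> 10
  expect_equal(S0, diag(c(0, 0, 10)), tolerance = 1e-6)
  ## symmetry holds for arbitrary parameters
  for (e in c(0.001, 0.05, 0.3)) {
    mm <- boundaryLayerModel(epsilon = e, x0 = 0.5, width = 2, low = 1,
                             high = 50)
    SS <- boundaryLayerTensor(mm, runif(1, -3, 3))
    expect_equal(SS, t(SS))
  }
  ## stored a and b agree with the profile
  expect_equal(m@a, m@profile(0))
  h <- 1e-6
  expect_equal(m@b, (m@profile(h) - m@profile(-h)) / (2 * h), tolerance = 1e-4)
})

test_that("isotropic part is the tensor trace over three", {
  f <- homogeneousField(c(3, 3, 3), 76.31)
  expect_equal(isotropicPart(f)[2, 2, 2], 76.31)
  m0 <- boundaryLayerModel(epsilon = 0, x0 = 0, width = 1, low = 9, high = 9)
  S <- boundaryLayerTensor(m0, 0)
  expect_equal(sum(diag(S)) / 3, 3)
  fz <- homogeneousField(c(2, 2, 2), 0)
  expect_true(all(isotropicPart(fz) == 0))
})

test_that("spherical phantom classifies shells like brute-force distance", {
  dims <- c(32, 32, 32)
  radii <- c(8, 12, 14)
  labs <- c(3L, 2L, 1L)
  g <- sphericalPhantom(dims, radii, labs)
  lv <- labelVolume(g)
  ctr <- (dims - 1) / 2 + 1
  expect_equal(lv[ctr[1], ctr[2], ctr[3]], 3L)   # center voxel: innermost
  expect_equal(lv[1, 1, 1], 0L)                  # corner: background
  ## brute-force oracle
  co <- as.matrix(expand.grid(1:32, 1:32, 1:32)) - 1
  d <- sqrt(rowSums(sweep(co, 2, (dims - 1) / 2)^2))
  oracle <- ifelse(d <= 8, 3L, ifelse(d <= 12, 2L, ifelse(d <= 14, 1L, 0L)))
  expect_identical(as.vector(lv), oracle)
  ## shell voxel counts grow with radius
  counts <- cumsum(rev(table(lv[lv > 0])))        # inner to outer cumulative
  expect_true(all(diff(counts) > 0))
  expect_error(sphericalPhantom(c(16, 16, 16), c(4, 10), c(3, 2)),
               "exceed half the grid extent")
  expect_error(sphericalPhantom(dims, c(8, 8), c(3, 2)), "strictly increasing")
})

test_that("partial-volume smoothing preserves the asymptotic plateaus", {
  g <- sphericalPhantom(c(24, 24, 24), c(10), c(2L))
  f <- buildTensorField(g, smoothing = 1.5)
  s <- isotropicPart(f)
  gmRate <- GM_SIGMA / (GM_EPSREL * EPS0)
  expect_equal(s[13, 13, 13], gmRate, tolerance = 1e-3)
  expect_true(all(s >= 0))
})
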