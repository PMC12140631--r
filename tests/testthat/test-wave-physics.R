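test_that("assembled complex frequency zeroes the dispersion polynomial", {
  ## oracle: substitute Omega back into -i Omega k^2 - Sigma_ij ki kj
  ##         - i (d_i Sigma_ij) kj and demand cancellation
  set.seed(42)
  for (rep in 1:120) {
    B <- matrix(rnorm(9), 3)
    S <- crossprod(B)                       # random PSD symmetric tensor
    G <- array(rnorm(27), c(3, 3, 3))
    G <- (G + aperm(G, c(1, 3, 2))) / 2     # symmetric in tensor indices
    k <- rnorm(3)
    while (sum(k^2) < 1e-6) k <- rnorm(3)
    r <- wetcowDispersion(S, G, k)
    k2 <- sum(k^2)
    divS <- vapply(1:3, function(j) G[1, 1, j] + G[2, 2, j] + G[3, 3, j],
                   numeric(1))
    resid <- -1i * r@Omega * k2 -
      as.numeric(t(k) %*% S %*% k) -
      1i * sum(divS * k)
    scale <- max(Mod(r@Omega) * k2, sum(abs(S)) * k2, 1e-12)
    expect_lt(Mod(resid) / scale, 1e-12)
    expect_equal(r@Omega, complex(real = r@omega, imaginary = r@gamma))
    expect_gte(r@gamma, -1e-12)             # PSD tensor: damping, not growth
  }
})

test_that("decay rate is even and frequency odd under k -> -k", {
  set.seed(7)
  for (rep in 1:20) {
    B <- matrix(rnorm(9), 3); S <- crossprod(B)
    G <- array(rnorm(27), c(3, 3, 3))
    k <- rnorm(3)
    a <- wetcowDispersion(S, G, k)
    b <- wetcowDispersion(S, G, -k)
    expect_equal(a@gamma, b@gamma)
    expect_equal(a@omega, -b@omega)
  }
})

test_that("homogeneous media decay without oscillating", {
  r <- wetcowDispersion(diag(76.31, 3), array(0, c(3, 3, 3)), c(0.3, -1, 2))
  expect_equal(r@omega, 0)
  expect_equal(r@gamma, 76.31, tolerance = 1e-12)
  expect_error(wetcowDispersion(diag(3), array(0, c(3, 3, 3)), c(0, 0, 0)),
               "nonzero")
})

test_that("gray and white matter decay rates fall in the printed range", {
  gm <- homogeneousDecayRate(GM_SIGMA, GM_EPSREL * EPS0)
  wm <- homogeneousDecayRate(WM_SIGMA, WM_EPSREL * EPS0)
  expect_equal(gm, 76.31, tolerance = 1e-3)
  expect_equal(wm, 113.35, tolerance = 1e-3)
  expect_true(gm >= 75 && gm <= 115)
  expect_true(wm >= 75 && wm <= 115)
  expect_equal(homogeneousDecayRate(0, 1e-4), 0)
  expect_error(homogeneousDecayRate(1, 0), "positive")
})

test_that("electromagnetic reference numbers match the textbook estimate", {
  expect_equal(emVelocity(100), 3e7)
  expect_equal(emVelocity(1), 3e8)
  expect_equal(emVelocity(4), 1.5e8)
  expect_equal(emWavelength(100, 10), 3e6)     # the 3000 km alpha estimate
  expect_equal(emWavelength(100, 3e7), 1)
  expect_equal(emWavelength(1, 1), 3e8)
  expect_equal(emWavelength(100, 10) * 10, emVelocity(100))
  ## angular flag
  expect_equal(emWavelength(100, 2 * pi * 10, angular = TRUE),
               emWavelength(100, 10))
  expect_error(emWavelength(100, 0), "positive")
  expect_error(emVelocity(-1), "positive")
})

test_that("persistence ratio is |gamma/omega| and needs oscillation", {
  r <- new("DispersionResult", Omega = complex(real = 100, imaginary = 2),
           omega = 100, gamma = 2, k = c(1, 0, 0), kUnits = "1/m")
  expect_equal(persistenceRatio(r), 0.02)
  hom <- wetcowDispersion(diag(3), array(0, c(3, 3, 3)), c(1, 0, 0))
  expect_error(persistenceRatio(hom), "zero oscillation")
  ## longer waves persist better: with gamma fixed by the tensor and
  ## omega ~ 1/k from its gradient, gamma/omega shrinks as k shrinks
  m <- boundaryLayerModel(epsilon = 0.1, x0 = 0, width = 2, low = 10,
                          high = 90)
  S <- boundaryLayerTensor(m, 0)
  G <- array(0, c(3, 3, 3))
  G[1, 1, 1] <- m@epsilon * m@b           # d_x Sigma_xx across the layer
  ratios <- vapply(c(2, 1, 0.5, 0.25), function(kx) {
    persistenceRatio(wetcowDispersion(S, G, c(kx, 0, 0)))
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})
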