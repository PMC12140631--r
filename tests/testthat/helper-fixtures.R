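# Shared fixtures, all built in code.

# Homogeneous isotropic tensor field with scaled conductivity `rate` (1/s)
# and permittivity eps (F/m).
homogeneousField <- function(dims, rate, eps = 3.6e-4) {
  dims <- as.integer(dims)
  sig <- array(0, c(dims, 6L))
  sig[, , , 1:3] <- rate
  new("TensorField", dims = dims, voxelSize = c(1, 1, 1),
      sigma = sig, eps = array(eps, dims))
}

# Arbitrary (possibly anisotropic) constant-tensor field.
constantTensorField <- function(dims, S, eps = 3.6e-4) {
  dims <- as.integer(dims)
  sig <- array(0, c(dims, 6L))
  comp <- c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3])
  for (c in 1:6) sig[, , , c] <- comp[c]
  new("TensorField", dims = dims, voxelSize = c(1, 1, 1),
      sigma = sig, eps = array(eps, dims))
}

# Single real Fourier mode cos(k . x) on an n^3 grid, with k = 2 pi m / n.
planeWave <- function(dims, m) {
  ax <- lapply(1:3, function(d) 2 * pi * m[d] * (0:(dims[d] - 1)) / dims[d])
  ph <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  cos(ph)
}

# Printed low-frequency tissue constants used across tests.
GM_SIGMA <- 2.75e-2
WM_SIGMA <- 2.77e-2
GM_EPSREL <- 4.07e7
WM_EPSREL <- 2.76e7
EPS0 <- 8.854187817e-12

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
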