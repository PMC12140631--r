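## Entropy-spectrum-pathway mode decomposition of 4D data.
##
## Space-time correlations between voxel time courses define a nonnegative
## symmetric coupling matrix Q; its leading eigenpairs are the ranked
## spatiotemporal power modes, and the squared leading eigenvector
## (normalized) is the equilibrium voxel distribution mu*. This is the
## operational core of the entropy field decomposition; the full
## field-theoretic machinery (higher-order interactions, cross-modality
## coupling) is intentionally not modeled.

#' Space-time coupling matrix of a 4D dataset
#'
#' Q_ij = max(0, Pearson correlation of the time courses of voxels i and j)
#' for voxel pairs within \code{radius} (Euclidean, voxel units), 0
#' otherwise; symmetric with zero diagonal. Clipping at 0 keeps Q
#' nonnegative so the equilibrium-distribution interpretation holds.
#' Constant time courses get zero coupling (with a message).
#'
#' @param data 4D numeric array (dims x time), >= 8 time points.
#' @param mask logical 3D array of retained voxels (default: all).
#' @param radius neighborhood radius in voxels (default 2).
#' @param dense compute the full (all-pairs) coupling instead of the
#'   neighborhood-restricted one; intended for small grids.
#' @return a \linkS4class{CouplingMatrix}
#' @export
couplingMatrix <- function(data, mask = NULL, radius = 2, dense = FALSE) {
  stopifnot(length(dim(data)) == 4L)
  dims <- dim(data)[1:3]
  nt <- dim(data)[4]
  if (nt < 8L) stop("need at least 8 time points")
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), as.integer(dims)))
  if (!any(mask)) stop("mask retains no voxels")
  vidx <- which(mask)
  X <- matrix(data, prod(dims), nt)[vidx, , drop = FALSE]
  mu <- rowMeans(X)
  Xc <- X - mu
  ss <- sqrt(rowSums(Xc^2))
  nConst <- sum(ss == 0)
  if (nConst > 0)
    message(nConst, " constant voxel time course(s): coupling set to 0")
  ss[ss == 0] <- Inf
  Xs <- Xc / ss                               # unit-norm rows
  n <- length(vidx)
  if (dense) {
    Q <- tcrossprod(Xs)
    Q[Q < 0] <- 0
    diag(Q) <- 0
    Q <- (Q + t(Q)) / 2
  } else {
    co <- arrayInd(vidx, dims)
    map <- array(0L, dims); map[vidx] <- seq_len(n)
    r <- ceiling(radius)
    offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
    offs <- offs[rowSums(offs^2) <= radius^2 & rowSums(offs^2) > 0, , drop = FALSE]
    ## keep one of each (d, -d) pair
    keep <- offs[, 1] > 0 |
      (offs[, 1] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 3] > 0)))
    offs <- offs[keep, , drop = FALSE]
    ii <- jj <- integer(0); xx <- numeric(0)
    for (o in seq_len(nrow(offs))) {
      nb <- sweep(co, 2, offs[o, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (!any(ok)) next
      w <- map[nb[ok, , drop = FALSE]]
      src <- which(ok)[w > 0]
      tgt <- w[w > 0]
      if (!length(src)) next
      cc <- rowSums(Xs[src, , drop = FALSE] * Xs[tgt, , drop = FALSE])
      pos <- cc > 0
      ii <- c(ii, src[pos]); jj <- c(jj, tgt[pos]); xx <- c(xx, cc[pos])
    }
    Q <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(xx, xx),
                              dims = c(n, n))
    Q <- Matrix::forceSymmetric(Q)
  }
  new("CouplingMatrix", Q = Q, voxelIndex = as.integer(vidx),
      dims = as.integer(dims))
}

#' Eigen-decomposition of the coupling matrix into ranked modes
#'
#' Computes the \code{n} leading eigenpairs of Q. Mode m's spatial map is
#' the absolute value of eigenvector m (unit L2 norm); its time course is
#' the projection of the data onto the map; its amplitude is the
#' eigenvalue. The equilibrium distribution mu* is the squared leading
#' eigenvector normalized to sum to 1. Eigenvector signs are fixed by
#' making each vector's largest-magnitude entry positive before taking
#' magnitudes, so the decomposition is fully deterministic. Only modes with
#' positive amplitude are available; asking for more returns the available
#' ones with a warning.
#'
#' @param Q a \linkS4class{CouplingMatrix}
#' @param data the originating 4D array (for the time courses)
#' @param n number of modes requested
#' @return a \linkS4class{ModeSet}
#' @export
espDecompose <- function(Q, data, n) {
  stopifnot(is(Q, "CouplingMatrix"), n >= 1L, length(dim(data)) == 4L)
  dims <- Q@dims
  stopifnot(identical(dim(data)[1:3], as.integer(dims)))
  Qd <- as.matrix(Q@Q)
  eg <- eigen(Qd, symmetric = TRUE)
  tolEv <- max(abs(eg$values)) * 1e-10
  nAvail <- sum(eg$values > tolEv)
  if (nAvail < 1L) stop("coupling matrix has no positive eigenvalue")
  if (n > nAvail) {
    warning("only ", nAvail, " modes with positive amplitude available (",
            n, " requested)")
    n <- nAvail
  }
  X <- matrix(data, prod(dims), dim(data)[4])[Q@voxelIndex, , drop = FALSE]
  maps <- matrix(0, nrow(Qd), n)
  tcs <- matrix(0, dim(data)[4], n)
  for (m in seq_len(n)) {
    v <- eg$vectors[, m]
    v <- v * sign(v[which.max(abs(v))])
    mp <- abs(v)
    mp <- mp / sqrt(sum(mp^2))
    maps[, m] <- mp
    tcs[, m] <- as.vector(t(X) %*% mp)
  }
  v1 <- eg$vectors[, 1]
  muStar <- v1^2 / sum(v1^2)
  new("ModeSet", maps = maps, timecourses = tcs,
      amplitudes = eg$values[seq_len(n)], muStar = muStar,
      voxelIndex = Q@voxelIndex, dims = as.integer(dims))
}

#' Amplitude-weighted summed power map
#'
#' The amplitude-weighted sum of the squared spatial maps of the first
#' \code{n} modes, rescaled to [0, 1] (max exactly 1 for nonzero input).
#' Rescaling makes the map invariant to a common scaling of the amplitudes.
#'
#' @param modes a \linkS4class{ModeSet}
#' @param n number of leading modes to sum (default: all)
#' @return 3D array in [0, 1]
#' @export
modePowerMap <- function(modes, n = length(modes@amplitudes)) {
  stopifnot(is(modes, "ModeSet"))
  if (n > length(modes@amplitudes))
    stop("requested more modes than the set contains")
  p <- as.vector(modes@maps[, seq_len(n), drop = FALSE]^2 %*%
                   modes@amplitudes[seq_len(n)])
  vol <- array(0, modes@dims)
  vol[modes@voxelIndex] <- p
  mx <- max(vol)
  if (mx > 0) vol <- vol / mx
  vol
}

#' Threshold a normalized map
#'
#' For maps scaled to [0, 1], values below \code{tau} are zeroed (the
#' boundary value tau itself is retained). For signed maps scaled to
#' [-1, 1] (e.g. difference maps), the threshold applies to the absolute
#' value and the sign is kept.
#'
#' @param map numeric array in [0,1] (or [-1,1] if signed)
#' @param tau threshold in [0, 1] (default 0.6)
#' @return array with sub-threshold entries zeroed
#' @export
thresholdMap <- function(map, tau = 0.6) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("threshold tau must lie in [0, 1]")
  out <- map
  out[abs(map) < tau] <- 0
  out
}

#' Mean map power per atlas region
#'
#' @param map numeric 3D array
#' @param atlas integer 3D array of region labels on the same grid (or a
#'   \linkS4class{TissueGrid})
#' @param includeBackground include label 0 as a region (default FALSE)
#' @return data.frame with columns \code{label} and \code{meanPower}
#' @export
regionPower <- function(map, atlas, includeBackground = FALSE) {
  if (is(atlas, "TissueGrid")) atlas <- labelVolume(atlas)
  if (!identical(dim(map), dim(atlas)))
    stop("atlas grid does not match the map grid")
  labs <- sort(unique(as.vector(atlas)))
  if (!includeBackground) labs <- setdiff(labs, 0L)
  mp <- vapply(labs, function(l) mean(map[atlas == l]), numeric(1))
  data.frame(label = as.integer(labs), meanPower = mp)
}
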