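# Shared fixtures and independent brute-force oracles.  Everything here is
# deliberately naive (triple loops, direct sums) so the vectorized package
# code is checked against a second, independent formulation.

randomVolume <- function(shape, seed, unit = "dimensionless", sd = 1) {
  set.seed(seed)
  ScalarVolume(array(rnorm(prod(shape), sd = sd), shape),
               VolumeGrid(shape), unit = unit)
}

randomVector <- function(shape, seed) {
  set.seed(seed)
  VectorVolume(array(rnorm(prod(shape)), shape),
               array(rnorm(prod(shape)), shape),
               array(rnorm(prod(shape)), shape),
               VolumeGrid(shape))
}

# triple-loop periodic forward difference
bruteForwardDiff <- function(v) {
  d <- dim(v)
  gx <- gy <- gz <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    gx[i, j, k] <- v[i %% d[1] + 1L, j, k] - v[i, j, k]
    gy[i, j, k] <- v[i, j %% d[2] + 1L, k] - v[i, j, k]
    gz[i, j, k] <- v[i, j, k %% d[3] + 1L] - v[i, j, k]
  }
  list(x = gx, y = gy, z = gz)
}

# triple-loop periodic 6-neighbor Laplacian
bruteLaplacian <- function(v) {
  d <- dim(v)
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    out[i, j, k] <-
      v[i %% d[1] + 1L, j, k] + v[(i - 2L) %% d[1] + 1L, j, k] +
      v[i, j %% d[2] + 1L, k] + v[i, (j - 2L) %% d[2] + 1L, k] +
      v[i, j, k %% d[3] + 1L] + v[i, j, (k - 2L) %% d[3] + 1L] -
      6 * v[i, j, k]
  }
  out
}

# minimal-image sampled r-space dipole, written independently of the package
bruteDipoleR <- function(shape, voxel = c(1, 1, 1), b0 = c(0, 0, 1)) {
  off <- function(n) { j <- 0:(n - 1); ifelse(j <= n %/% 2, j, j - n) }
  d <- array(0, shape)
  ox <- off(shape[1]) * voxel[1]
  oy <- off(shape[2]) * voxel[2]
  oz <- off(shape[3]) * voxel[3]
  for (i in 1:shape[1]) for (j in 1:shape[2]) for (k in 1:shape[3]) {
    r <- c(ox[i], oy[j], oz[k])
    r2 <- sum(r^2)
    if (r2 > 0) {
      ct2 <- (sum(r * b0))^2 / r2
      d[i, j, k] <- (3 * ct2 - 1) / (4 * pi * r2^1.5)
    }
  }
  d
}

vecInner <- function(a, b) sum(a@x * b@x) + sum(a@y * b@y) + sum(a@z * b@z)

relDiff <- function(a, b) {
  den <- max(sqrt(sum(b^2)), 1e-300)
  sqrt(sum((a - b)^2)) / den
}

fullMask <- function(shape) MaskVolume(array(TRUE, shape))

# small well-conditioned reconstruction problem shared by solver tests
smallProblem <- function(n = 8, seed = 7, lambda = 1e-3, noise = 0.01) {
  sh <- c(n, n, n)
  gr <- VolumeGrid(sh)
  D <- makeDipoleKernel(gr)
  set.seed(seed)
  chi0 <- array(rnorm(n^3, sd = 0.2), sh)
  phi <- ScalarVolume(
    volumeValues(forwardField(ScalarVolume(chi0, gr, unit = "ppm"), D)) +
      array(rnorm(n^3, sd = noise), sh),
    gr, unit = "ppm")
  mag <- ScalarVolume(array(abs(rnorm(n^3, 1, 0.3)), sh), gr, unit = "au")
  mask <- fullMask(sh)
  wm <- computeDataWeight(mag, mask)
  ew <- edgeWeights(mag, mask, mode = "matv")
  list(grid = gr, kernel = D, field = phi, mask = mask, wm = wm,
       wedge = ew$weight, threshold = ew$threshold, lambda = lambda)
}

# direct (non-package) evaluation of the smoothed objective on a flat vector
bruteSmoothedObjective <- function(x, prob, eps) {
  sh <- gridShape(prob$grid)
  xa <- array(x, sh)
  n1 <- sh[1]; n2 <- sh[2]; n3 <- sh[3]
  Ax <- Re(fft(volumeValues(prob$kernel) * fft(xa), inverse = TRUE)) /
    length(xa)
  r <- Ax - volumeValues(prob$field)
  fid <- sum((volumeValues(prob$wm) * r)^2)
  gx <- xa[c(2:n1, 1), , ] - xa
  gy <- xa[, c(2:n2, 1), ] - xa
  gz <- xa[, , c(2:n3, 1)] - xa
  w <- prob$wedge
  fid + prob$lambda * (sum(w@x * sqrt(gx^2 + eps^2)) +
                       sum(w@y * sqrt(gy^2 + eps^2)) +
                       sum(w@z * sqrt(gz^2 + eps^2)))
}
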