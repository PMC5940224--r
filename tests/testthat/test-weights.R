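# exhaustive-scan reference for the threshold rule: smallest candidate c
# (among the pooled values) whose tail fraction does not exceed the target
bruteThreshold <- function(pool, fraction) {
  n <- length(pool)
  for (cand in sort(unique(pool))) {
    if (sum(pool >= cand) <= fraction * n) return(cand)
  }
  max(pool) * (1 + 1e-9)
}

# build a VectorVolume + mask whose pooled in-mask component magnitudes are
# exactly `vals` (length divisible by 3)
gradientWithPool <- function(vals, shape = c(8, 8, 8)) {
  k <- length(vals) / 3
  stopifnot(k == floor(k), 3 * k <= prod(shape))
  gx <- gy <- gz <- array(0, shape)
  gx[seq_len(k)] <- vals[seq_len(k)]
  gy[seq_len(k)] <- vals[k + seq_len(k)]
  gz[seq_len(k)] <- vals[2 * k + seq_len(k)]
  m <- array(FALSE, shape); m[seq_len(k)] <- TRUE
  list(grad = VectorVolume(gx, gy, gz, VolumeGrid(shape)),
       mask = MaskVolume(m, VolumeGrid(shape)))
}

test_that("data weight is magnitude-proportional, masked and normalized", {
  sh <- c(8, 8, 8)
  mask <- fullMask(sh)

  # uniform magnitude: weight identically 1 inside the mask
  w <- computeDataWeight(ScalarVolume(array(5, sh), unit = "au"), mask)
  expect_equal(volumeValues(w), array(1, sh))

  # 10-voxel mask with magnitudes 1..10: weights (1..10)/5.5
  m10 <- array(FALSE, sh); m10[1:10] <- TRUE
  mag <- array(0, sh); mag[1:10] <- 1:10
  w10 <- computeDataWeight(ScalarVolume(mag, unit = "au"),
                           MaskVolume(m10, VolumeGrid(sh)))
  expect_equal(volumeValues(w10)[1:10], (1:10) / 5.5)
  expect_true(all(volumeValues(w10)[-(1:10)] == 0))
  expect_equal(mean(volumeValues(w10)[m10]), 1)

  # scale invariance: doubling the magnitude leaves the weight unchanged
  w2 <- computeDataWeight(ScalarVolume(2 * mag, unit = "au"),
                          MaskVolume(m10, VolumeGrid(sh)))
  expect_equal(volumeValues(w2), volumeValues(w10))

  # degenerate: zero magnitude inside the mask
  expect_error(computeDataWeight(ScalarVolume(array(0, sh), unit = "au"),
                                 mask), "degenerate")
})

test_that("edge threshold implements the smallest-c tail rule", {
  # pooled values exactly 1..300 at target 0.3: the 70% quantile, c = 211,
  # leaving exactly 90 of 300 values at or above the threshold
  gp <- gradientWithPool(as.numeric(1:300))
  thr <- selectEdgeThreshold(gp$grad, gp$mask, fraction = 0.3)
  expect_equal(thresholdValue(thr), bruteThreshold(as.numeric(1:300), 0.3))
  expect_equal(thresholdValue(thr), 211)
  expect_equal(achievedFraction(thr), 90 / 300)

  # random continuous pools: agreement with the exhaustive scan
  for (seed in 1:5) {
    set.seed(seed)
    vals <- abs(rnorm(3 * 120))
    gp <- gradientWithPool(vals)
    for (f in c(0.1, 0.3, 0.5)) {
      thr <- selectEdgeThreshold(gp$grad, gp$mask, fraction = f)
      expect_equal(thresholdValue(thr), bruteThreshold(vals, f))
      expect_lte(achievedFraction(thr), f)
    }
  }

  # all pooled values equal and positive: no candidate leaves a small
  # enough tail, so c sits just above the common value and nothing is
  # boundary
  gp <- gradientWithPool(rep(2, 30))
  thr <- selectEdgeThreshold(gp$grad, gp$mask, fraction = 0.3)
  expect_gt(thresholdValue(thr), 2)
  expect_lt(thresholdValue(thr), 2 * (1 + 1e-6))
  expect_equal(achievedFraction(thr), 0)

  # fraction near 1 with zeros present in the pool (flat regions): the
  # threshold collapses to the smallest positive pooled value
  vals <- c(rep(0, 30), 5, 7, 11, rep(0, 27))
  gp <- gradientWithPool(vals)
  thr <- selectEdgeThreshold(gp$grad, gp$mask, fraction = 0.999)
  expect_equal(thresholdValue(thr), 5)

  # degenerate: identically zero gradient inside the mask
  sh <- c(8, 8, 8)
  z <- VectorVolume(array(0, sh), array(0, sh), array(0, sh), VolumeGrid(sh))
  expect_error(selectEdgeThreshold(z, fullMask(sh)), "degenerate")
  expect_error(selectEdgeThreshold(z, fullMask(sh), fraction = 1.2),
               "between 0 and 1")
})

test_that("soft edge weight follows the inverse-gradient sine law", {
  c0 <- 0.4
  gvals <- c(0, 0.5 * c0, c0 * (1 - 1e-12), c0, 1.5 * c0, 2 * c0, 2.5 * c0,
             10 * c0)
  sh <- c(8, 8, 8)
  g <- array(0, sh); g[seq_along(gvals)] <- gvals
  gv <- VectorVolume(g, array(0, sh), array(0, sh), VolumeGrid(sh))
  thr <- new("EdgeThreshold", value = c0, fraction = 0.3, achieved = 0.3)
  w <- matvEdgeWeight(gv, thr)
  expect_identical(w@mode, "matv_soft")
  got <- w@x[seq_along(gvals)]
  expect_equal(got[1:3], c(1, 1, 1))               # smooth region
  expect_equal(got[4], 1)                          # continuity at c
  expect_equal(got[5], sin(pi / 3))                # 1.5 c
  expect_equal(got[6], sin(pi / 4))                # 2 c
  expect_equal(got[7], sin(pi / 5))                # 2.5 c
  expect_equal(got[8], sin(pi / 20))               # strong edge, ~ (pi c/2)/|g|
  expect_true(all(got > 0 & got <= 1))

  # dense 1-D sweep: continuous, monotone non-increasing, range (0, 1],
  # value 1 on [0, c]
  sweep <- seq(0, 5 * c0, length.out = 4001)
  gs <- array(0, c(63, 8, 8)); gs[seq_along(sweep)] <- sweep
  ws <- matvEdgeWeight(VectorVolume(gs, array(0, dim(gs)),
                                    array(0, dim(gs)),
                                    VolumeGrid(dim(gs))), thr)
  wvals <- ws@x[seq_along(sweep)]
  expect_true(all(diff(wvals) <= 1e-12))
  expect_true(all(wvals[sweep <= c0] == 1))
  expect_true(all(wvals > 0 & wvals <= 1))
  expect_lt(max(abs(diff(wvals))), 0.005)          # no jumps on the sweep
})

test_that("hard edge weight is the exact sub-threshold indicator", {
  c0 <- 0.4
  set.seed(9)
  sh <- c(8, 8, 8)
  g <- array(runif(prod(sh), 0, 3 * c0), sh)
  gv <- VectorVolume(g, g / 2, g * 2, VolumeGrid(sh))
  thr <- new("EdgeThreshold", value = c0, fraction = 0.3, achieved = 0.3)
  w <- mediEdgeWeight(gv, thr)
  expect_identical(w@mode, "medi_hard")
  expect_identical(w@x, array(as.numeric(abs(g) < c0), sh))
  expect_identical(w@y, array(as.numeric(abs(g / 2) < c0), sh))
  expect_identical(w@z, array(as.numeric(abs(g * 2) < c0), sh))

  # hard weight never exceeds the soft weight: equal below c (both 1),
  # 0 <= positive at and above c
  ws <- matvEdgeWeight(gv, thr)
  expect_true(all(w@x <= ws@x & w@y <= ws@y & w@z <= ws@z))
  at <- abs(g) >= c0
  expect_true(all(w@x[at] == 0) && all(ws@x[at] > 0))
})

test_that("masking zeroes edge weights outside the object", {
  sh <- c(8, 8, 8)
  set.seed(4)
  gv <- randomVector(sh, seed = 4)
  m <- array(FALSE, sh); m[3:6, 3:6, 3:6] <- TRUE
  mask <- MaskVolume(m, VolumeGrid(sh))
  thr <- new("EdgeThreshold", value = 0.5, fraction = 0.3, achieved = 0.3)
  for (w in list(matvEdgeWeight(gv, thr, mask),
                 mediEdgeWeight(gv, thr, mask))) {
    expect_true(all(w@x[!m] == 0) && all(w@y[!m] == 0) && all(w@z[!m] == 0))
  }
})

test_that("edgeWeights achieves the target fraction on continuous gradients", {
  mag <- randomVolume(c(24, 24, 24), seed = 31, unit = "au", sd = 0.05)
  mag <- ScalarVolume(volumeValues(mag) + 1, volumeGrid(mag), unit = "au")
  mask <- fullMask(c(24, 24, 24))
  ew <- edgeWeights(mag, mask, fraction = 0.3, mode = "matv")
  expect_lt(abs(achievedFraction(ew$threshold) - 0.3), 0.01)
  expect_identical(ew$weight@mode, "matv_soft")
  ewm <- edgeWeights(mag, mask, fraction = 0.3, mode = "medi")
  expect_identical(ewm$weight@mode, "medi_hard")
})
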