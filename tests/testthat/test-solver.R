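test_that("objective evaluates fidelity and weighted TV exactly", {
  prob <- smallProblem(n = 12, seed = 17, lambda = 0)
  sh <- c(12, 12, 12)
  z <- ScalarVolume(array(0, sh), prob$grid, unit = "ppm")

  # chi = 0, phi = 0: both terms vanish
  zf <- ScalarVolume(array(0, sh), prob$grid, unit = "ppm")
  expect_equal(matvObjective(z, zf, prob$wm, prob$wedge, prob$kernel, 1), 0)

  # chi = 0: the objective reduces to ||W_m phi||^2
  expect_equal(
    matvObjective(z, prob$field, prob$wm, prob$wedge, prob$kernel, 0.5),
    sum((volumeValues(prob$wm) * volumeValues(prob$field))^2))

  # lambda = 0 on a random iterate: pure weighted least squares, checked
  # against an independent term-by-term evaluation
  chi <- randomVolume(sh, seed = 18, unit = "ppm", sd = 0.1)
  direct <- bruteSmoothedObjective(as.numeric(volumeValues(chi)), prob,
                                   eps = 0)   # lambda = 0 in prob
  expect_equal(matvObjective(chi, prob$field, prob$wm, prob$wedge,
                             prob$kernel, 0),
               direct, tolerance = 1e-12)

  # lambda > 0: exact L1 term, same independent evaluation with eps = 0
  prob2 <- smallProblem(n = 12, seed = 17, lambda = 0.02)
  direct2 <- bruteSmoothedObjective(as.numeric(volumeValues(chi)), prob2,
                                    eps = 0)
  expect_equal(matvObjective(chi, prob2$field, prob2$wm, prob2$wedge,
                             prob2$kernel, 0.02),
               direct2, tolerance = 1e-12)

  # grid mismatch propagates as a dimension error
  bad <- randomVolume(c(8, 8, 8), seed = 1, unit = "ppm")
  expect_error(matvObjective(bad, prob$field, prob$wm, prob$wedge,
                             prob$kernel, 1), "dimension mismatch")
})

test_that("normal operator is linear, self-adjoint and composes correctly", {
  prob <- smallProblem(n = 10, seed = 23)
  sh <- c(10, 10, 10)
  irls <- randomVector(sh, seed = 24)
  irls <- VectorVolume(abs(irls@x), abs(irls@y), abs(irls@z), prob$grid)

  z <- ScalarVolume(array(0, sh), prob$grid, unit = "ppm")
  expect_true(all(volumeValues(applyNormalOperator(
    z, prob$wm, prob$wedge, irls, prob$kernel, 0.1)) == 0))

  # self-adjointness and positive semi-definiteness on random pairs
  for (rep in 1:5) {
    u <- randomVolume(sh, seed = 300 + rep, unit = "ppm")
    v <- randomVolume(sh, seed = 400 + rep, unit = "ppm")
    Lu <- volumeValues(applyNormalOperator(u, prob$wm, prob$wedge, irls,
                                           prob$kernel, 0.1))
    Lv <- volumeValues(applyNormalOperator(v, prob$wm, prob$wedge, irls,
                                           prob$kernel, 0.1))
    ip1 <- sum(Lu * volumeValues(v))
    ip2 <- sum(volumeValues(u) * Lv)
    expect_lt(abs(ip1 - ip2) / max(abs(ip1), 1e-300), 1e-10)
    expect_gte(sum(Lu * volumeValues(u)), -1e-10 * sum(volumeValues(u)^2))
  }

  # with unit weights the operator is F^H D^2 F + lambda * (-Laplacian)
  ones <- new("DataWeight", grid = prob$grid, values = array(1, sh))
  wone <- new("EdgeWeight", grid = prob$grid, x = array(1, sh),
              y = array(1, sh), z = array(1, sh), mode = "matv_soft")
  ione <- VectorVolume(array(1, sh), array(1, sh), array(1, sh), prob$grid)
  d <- randomVolume(sh, seed = 55, unit = "ppm")
  got <- volumeValues(applyNormalOperator(d, ones, wone, ione,
                                          prob$kernel, 0.3))
  D2 <- volumeValues(prob$kernel)^2
  fidRef <- Re(fft(D2 * fft(volumeValues(d)), inverse = TRUE)) / prod(sh)
  lapRef <- -bruteLaplacian(volumeValues(d))
  expect_equal(got, fidRef + 0.3 * lapRef, tolerance = 1e-12)
})

test_that("zero field yields the zero solution with zero objective", {
  prob <- smallProblem(n = 8, seed = 31)
  zf <- ScalarVolume(array(0, c(8, 8, 8)), prob$grid, unit = "ppm")
  res <- solveMATV(zf, prob$wm, prob$wedge, prob$kernel,
                   SolverConfig(lambda = prob$lambda))
  expect_true(all(volumeValues(chiMap(res)) == 0))
  expect_equal(objectiveTrace(res), c(0, 0))
  expect_true(res@converged)
})

test_that("solver matches a generic minimizer of the smoothed objective", {
  eps <- 1e-4
  prob <- smallProblem(n = 8, seed = 7, lambda = 1e-3)
  cfg <- SolverConfig(lambda = prob$lambda, epsilon = eps, maxOuter = 50L,
                      cgTol = 1e-8, cgMax = 500L, outerTol = 1e-9)
  res <- solveMATV(prob$field, prob$wm, prob$wedge, prob$kernel, cfg)
  fPkg <- matvObjective(chiMap(res), prob$field, prob$wm, prob$wedge,
                        prob$kernel, prob$lambda, epsilon = eps)

  o <- optim(rep(0, 8^3), bruteSmoothedObjective, prob = prob, eps = eps,
             method = "L-BFGS-B",
             control = list(maxit = 2000, factr = 10))
  expect_lt(abs(fPkg - o$value) / o$value, 1e-4)

  # objective trace is monotone non-increasing (exact objective)
  tr <- objectiveTrace(res)
  expect_true(all(diff(tr) <= 1e-8 * abs(tr[1])))
})

test_that("noiseless data are fit tightly when regularization is weak", {
  sh <- c(32, 32, 32)
  gr <- VolumeGrid(sh)
  spec <- PhantomSpec(gr, centers = matrix(c(16.5, 16.5, 16.5), 1),
                      radii = 5, chi = 1)
  chi <- makeBalloonPhantom(spec)
  D <- makeDipoleKernel(gr)
  phi <- forwardField(chi, D)
  mask <- fullMask(sh)
  set.seed(77)
  mag <- ScalarVolume(array(abs(rnorm(prod(sh), 1, 0.1)), sh), gr,
                      unit = "au")
  wm <- computeDataWeight(mag, mask)
  ew <- edgeWeights(mag, mask, mode = "matv")
  res <- solveMATV(phi, wm, ew$weight, D,
                   SolverConfig(lambda = 1e-6, maxOuter = 15L,
                                outerTol = 0.001))
  resid <- volumeValues(forwardField(chiMap(res), D)) - volumeValues(phi)
  relResid <- sqrt(sum((volumeValues(wm) * resid)^2)) /
    sqrt(sum((volumeValues(wm) * volumeValues(phi))^2))
  expect_lt(relResid, 0.05)
})

test_that("single-sphere phantom is recovered from its noiseless field", {
  sh <- c(48, 48, 48)
  gr <- VolumeGrid(sh)
  spec <- PhantomSpec(gr, centers = matrix(c(24.5, 24.5, 24.5), 1),
                      radii = 6, chi = 1, magnitudeContrasts = 2)
  chi <- makeBalloonPhantom(spec)
  D <- makeDipoleKernel(gr)
  phi <- forwardField(chi, D)
  mask <- MaskVolume(
    matvqsm:::.sphereMembership(sh, c(24.5, 24.5, 24.5), 20), gr)
  phi <- ScalarVolume(volumeValues(phi) * volumeValues(mask), gr,
                      unit = "ppm")
  mag <- makeMagnitude(spec, magSnr = 50, seed = 3)
  wm <- computeDataWeight(mag, mask)
  ew <- edgeWeights(mag, mask, mode = "matv")
  res <- solveMATV(phi, wm, ew$weight, D, SolverConfig(lambda = 1e-3),
                   mask = mask)
  roi <- matvqsm:::.sphereMembership(sh, c(24.5, 24.5, 24.5), 6)
  roiMean <- mean(volumeValues(chiMap(res))[roi])
  expect_lt(abs(roiMean - 1), 0.15)
  # solution respects the support constraint
  expect_true(all(volumeValues(chiMap(res))[!volumeValues(mask)] == 0))
})

test_that("stronger regularization yields smoother solutions", {
  # fixed noisy problem; total variation of the solution is non-increasing
  # across a lambda sweep spanning two decades
  sh <- c(16, 16, 16)
  gr <- VolumeGrid(sh)
  spec <- PhantomSpec(gr, centers = matrix(c(8.5, 8.5, 8.5), 1),
                      radii = 3, chi = 1)
  chi <- makeBalloonPhantom(spec)
  D <- makeDipoleKernel(gr)
  set.seed(101)
  phi <- ScalarVolume(volumeValues(forwardField(chi, D)) +
                        array(rnorm(prod(sh), sd = 0.01), sh),
                      gr, unit = "ppm")
  mask <- fullMask(sh)
  mag <- ScalarVolume(array(abs(rnorm(prod(sh), 1, 0.2)), sh), gr,
                      unit = "au")
  wm <- computeDataWeight(mag, mask)
  ew <- edgeWeights(mag, mask, mode = "matv")
  tvOf <- function(res) {
    g <- forwardDiff(chiMap(res))
    sum(abs(g@x)) + sum(abs(g@y)) + sum(abs(g@z))
  }
  tvs <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(lam) {
    tvOf(solveMATV(phi, wm, ew$weight, D,
                   SolverConfig(lambda = lam, maxOuter = 12L)))
  }, numeric(1))
  expect_true(all(diff(tvs) <= 1e-8 * tvs[1]))
})
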