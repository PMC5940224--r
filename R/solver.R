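## MATV reconstruction: minimize over chi
##
##     || W_m (F^H D F chi - phi) ||_2^2  +  lambda || W_grad-m grad chi ||_1
##
## by iteratively reweighted (smoothed-L1) Gauss-Newton.  At each outer
## iteration the anisotropic L1 penalty sum w |g| is majorized at the
## current iterate via |g| ~ sqrt(g^2 + epsilon^2), giving per-component
## IRLS weights v = 1 / sqrt(g^2 + epsilon^2); the resulting symmetric
## positive semi-definite normal equations are solved by conjugate
## gradients, and the update is confined to the mask.  This is the solver
## family used by the published MEDI implementations, which keeps the
## hard-threshold comparison mode faithful: the two modes differ only in
## the edge-weight map.

## raw-array pieces shared by objective / gradient / operator ------------

.fidelity <- function(x, phi, wm2, D) {
    r <- .applyKernel(x, D) - phi
    sum(wm2 * r * r)
}

.tvExact <- function(x, wx, wy, wz) {
    g <- .fdiff(x)
    sum(wx * abs(g$x)) + sum(wy * abs(g$y)) + sum(wz * abs(g$z))
}

.tvSmooth <- function(x, wx, wy, wz, eps) {
    g <- .fdiff(x)
    e2 <- eps * eps
    sum(wx * sqrt(g$x^2 + e2)) + sum(wy * sqrt(g$y^2 + e2)) +
        sum(wz * sqrt(g$z^2 + e2))
}

#' Evaluate the MATV objective
#'
#' Returns the value of the weighted dipole-inversion objective
#' `||W_m (forwardField(chi) - phi)||_2^2 + lambda * sum(W . |grad chi|)`
#' with the anisotropic L1 TV term.  By default the exact (unsmoothed) L1
#' is used; a positive `epsilon` evaluates the smoothed surrogate
#' `sqrt(g^2 + epsilon^2)` instead, which is what the solver's inner
#' iterations minimize.
#'
#' @param chi candidate susceptibility [ScalarVolume-class], ppm.
#' @param field measured local field [ScalarVolume-class], ppm.
#' @param wm [DataWeight-class] fidelity weight.
#' @param wedge [EdgeWeight-class] TV weight.
#' @param kernel [DipoleKernelK-class].
#' @param lambda regularization parameter (> 0, or 0 for pure weighted
#'   least squares).
#' @param epsilon L1 smoothing floor; 0 (default) evaluates the exact L1.
#' @return The scalar objective value.
#' @export
matvObjective <- function(chi, field, wm, wedge, kernel, lambda,
                          epsilon = 0) {
    stopifnot(is(chi, "ScalarVolume"), is(field, "ScalarVolume"),
              is(wm, "DataWeight"), is(wedge, "EdgeWeight"),
              is(kernel, "DipoleKernelK"))
    .checkSameGrid(chi, field, "chi and field")
    .checkSameGrid(chi, wm, "chi and fidelity weight")
    .checkSameGrid(chi, wedge, "chi and edge weight")
    .checkSameGrid(chi, kernel, "chi and kernel")
    fid <- .fidelity(chi@values, field@values, wm@values^2, kernel@values)
    tv <- if (epsilon > 0)
        .tvSmooth(chi@values, wedge@x, wedge@y, wedge@z, epsilon)
    else
        .tvExact(chi@values, wedge@x, wedge@y, wedge@z)
    fid + lambda * tv
}

#' Apply the Gauss-Newton normal operator
#'
#' Computes the matrix-vector product of the linearized system matrix,
#' `A W_m^2 A delta + lambda * t(grad) diag(W . irls_w) grad delta` with
#' `A = F^H D F`: the dipole-fidelity normal term plus the IRLS-weighted TV
#' curvature term.  Linear, self-adjoint and positive semi-definite in
#' `delta`.
#'
#' @param delta direction [ScalarVolume-class].
#' @param wm [DataWeight-class].
#' @param wedge [EdgeWeight-class].
#' @param irlsW [VectorVolume-class] of per-component IRLS weights
#'   `1 / sqrt(g^2 + epsilon^2)` evaluated at the current iterate.
#' @param kernel [DipoleKernelK-class].
#' @param lambda regularization parameter.
#' @return A [ScalarVolume-class] holding the product.
#' @export
applyNormalOperator <- function(delta, wm, wedge, irlsW, kernel, lambda) {
    stopifnot(is(delta, "ScalarVolume"), is(wm, "DataWeight"),
              is(wedge, "EdgeWeight"), is(irlsW, "VectorVolume"),
              is(kernel, "DipoleKernelK"))
    .checkSameGrid(delta, wm, "delta and fidelity weight")
    .checkSameGrid(delta, wedge, "delta and edge weight")
    .checkSameGrid(delta, irlsW, "delta and IRLS weights")
    .checkSameGrid(delta, kernel, "delta and kernel")
    out <- .normalOp(delta@values, wm@values^2,
                     wedge@x * irlsW@x, wedge@y * irlsW@y,
                     wedge@z * irlsW@z, kernel@values, lambda)
    ScalarVolume(out, grid = delta@grid, unit = delta@unit)
}

## wv* are the combined per-component weights (edge weight * IRLS weight)
.normalOp <- function(d, wm2, wvx, wvy, wvz, D, lambda) {
    fidPart <- .applyKernel(wm2 * .applyKernel(d, D), D)
    g <- .fdiff(d)
    tvPart <- .ndiv(wvx * g$x, wvy * g$y, wvz * g$z)
    fidPart + lambda * tvPart
}

#' Reconstruct a susceptibility map by MATV (or MEDI-mode) inversion
#'
#' Minimizes the weighted dipole-fidelity plus weighted anisotropic TV
#' objective by smoothed-L1 Gauss-Newton with inner conjugate-gradient
#' solves.  Starting from chi = 0, each outer iteration freezes the IRLS
#' weights at the current iterate, solves the normal equations to the CG
#' tolerance, backtracks if necessary so the exact objective never
#' increases, zeroes the update outside the mask, and stops once the
#' relative update norm drops below `outerTol` (or `maxOuter` is reached).
#'
#' @param field measured local tissue field [ScalarVolume-class], ppm
#'   (zero-mean inside the mask recommended).
#' @param wm [DataWeight-class] from [computeDataWeight()].
#' @param wedge [EdgeWeight-class] from [matvEdgeWeight()] or
#'   [mediEdgeWeight()]; the choice selects the reconstruction mode.
#' @param kernel [DipoleKernelK-class] from [makeDipoleKernel()].
#' @param config [SolverConfig-class].
#' @param mask optional [MaskVolume-class] support constraint; defaults to
#'   the positive support of `wm`.
#' @return A [SolveResult-class]: the reconstruction (zero outside the
#'   mask), the exact-objective trace, and convergence diagnostics.
#' @examples
#' \donttest{
#' study <- simulateStudy(defaultPhantomSpec(c(32, 32, 32)), snr = 50,
#'                        seed = 1)
#' wm <- computeDataWeight(study@magnitude, study@mask)
#' ew <- edgeWeights(study@magnitude, study@mask)
#' D <- makeDipoleKernel(volumeGrid(study@field))
#' res <- solveMATV(study@field, wm, ew$weight, D,
#'                  SolverConfig(lambda = 0.0017))
#' }
#' @export
solveMATV <- function(field, wm, wedge, kernel, config = SolverConfig(),
                      mask = NULL) {
    stopifnot(is(field, "ScalarVolume"), is(wm, "DataWeight"),
              is(wedge, "EdgeWeight"), is(kernel, "DipoleKernelK"),
              is(config, "SolverConfig"))
    .checkSameGrid(field, wm, "field and fidelity weight")
    .checkSameGrid(field, wedge, "field and edge weight")
    .checkSameGrid(field, kernel, "field and kernel")
    if (is.null(mask)) {
        mask <- MaskVolume(wm@values > 0, grid = wm@grid)
    } else {
        stopifnot(is(mask, "MaskVolume"))
        .checkSameGrid(field, mask, "field and mask")
    }

    phi <- field@values
    m <- as.numeric(mask@values)
    wm2 <- wm@values^2
    D <- kernel@values
    wx <- wedge@x; wy <- wedge@y; wz <- wedge@z
    lam <- config@lambda
    eps <- config@epsilon

    x <- array(0, dim(phi))
    fExact <- function(x) .fidelity(x, phi, wm2, D) +
        lam * .tvExact(x, wx, wy, wz)
    trace <- fExact(x)
    converged <- FALSE
    nOuter <- 0L

    for (outer in seq_len(config@maxOuter)) {
        g <- .fdiff(x)
        vx <- 1 / sqrt(g$x^2 + eps^2)
        vy <- 1 / sqrt(g$y^2 + eps^2)
        vz <- 1 / sqrt(g$z^2 + eps^2)
        ## half-gradient of the smoothed objective at x
        r <- .applyKernel(x, D) - phi
        grad <- .applyKernel(wm2 * r, D) +
            (lam / 2) * .ndiv(wx * vx * g$x, wy * vy * g$y, wz * vz * g$z)
        b <- -grad * m
        ## masked normal operator (half-Hessian of the smoothed objective)
        Lop <- function(d) {
            m * .normalOp(m * d, wm2, wx * vx, wy * vy, wz * vz, D, lam / 2)
        }
        delta <- .cgSolve(Lop, b, tol = config@cgTol, maxit = config@cgMax,
                          outer = outer)
        ## enforce monotone decrease of the exact objective
        fOld <- trace[length(trace)]
        step <- 1
        xNew <- x + delta
        fNew <- fExact(xNew)
        bt <- 0L
        while (fNew > fOld + 1e-12 * max(abs(fOld), 1e-300) && bt < 25L) {
            step <- step / 2
            xNew <- x + step * delta
            fNew <- fExact(xNew)
            bt <- bt + 1L
        }
        if (fNew > fOld + 1e-12 * max(abs(fOld), 1e-300)) {
            ## no descent possible along the CG direction: accept nothing
            nOuter <- outer
            converged <- TRUE
            break
        }
        relUpd <- sqrt(sum((xNew - x)^2)) / max(sqrt(sum(xNew^2)), 1e-300)
        x <- xNew
        trace <- c(trace, fNew)
        nOuter <- outer
        if (relUpd < config@outerTol) {
            converged <- TRUE
            break
        }
    }

    chi <- ScalarVolume(x * m, grid = field@grid, unit = "ppm")
    new("SolveResult", chi = chi, objectiveTrace = trace,
        nOuter = nOuter, converged = converged)
}

## standard conjugate gradients for a symmetric PSD operator
.cgSolve <- function(Lop, b, tol, maxit, outer = NA) {
    x <- array(0, dim(b))
    r <- b
    bnorm <- sqrt(sum(b * b))
    if (bnorm == 0) return(x)
    p <- r
    rs <- sum(r * r)
    for (it in seq_len(maxit)) {
        q <- Lop(p)
        pq <- sum(p * q)
        if (!is.finite(pq))
            stop("CG breakdown: non-finite curvature at outer iteration ",
                 outer, ", CG iteration ", it)
        if (pq <= 0) break   # null-space direction; current x is the answer
        alpha <- rs / pq
        x <- x + alpha * p
        r <- r - alpha * q
        rsNew <- sum(r * r)
        if (!is.finite(rsNew))
            stop("CG breakdown: non-finite residual at outer iteration ",
                 outer, ", CG iteration ", it)
        if (sqrt(rsNew) <= tol * bnorm) break
        p <- r + (rsNew / rs) * p
        rs <- rsNew
    }
    x
}
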