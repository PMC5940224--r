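## Dipole forward model: susceptibility (ppm) -> local field shift (ppm).
##
## The field a susceptibility distribution induces is its convolution with
## the unit dipole response.  In k-space this is a pointwise multiplication
## by D(k) = 1/3 - (k . b0)^2 / |k|^2, which vanishes on the magic-angle
## cone (3 cos^2 theta = 1) and is left 0 at k = 0 so the simulated field is
## zero-mean, the standard QSM convention.

## fftfreq-style frequency offsets in cycles per sample
.fftfreq <- function(n) {
    j <- 0:(n - 1L)
    ifelse(j <= (n - 1L) %/% 2L, j, j - n) / n
}

## signed minimal-image integer offsets for the periodic r-space lattice
.fftOffsets <- function(n) {
    j <- 0:(n - 1L)
    ifelse(j <= n %/% 2L, j, j - n)
}

#' Construct the k-space dipole kernel
#'
#' Samples `D(k) = 1/3 - (k . b0)^2 / |k|^2` on the FFT frequency grid of
#' the volume, with physical frequencies `k_i = n_i / (N_i * delta_i)`
#' (cycles/mm) so anisotropic voxels are handled correctly, and `D(0) = 0`.
#' Samples exactly on the magic-angle cone keep their formula value of 0: the
#' ill-posedness this creates is what the TV regularization addresses, so no
#' kernel-level truncation is applied.
#'
#' With `method = "rspace"` the kernel is instead the FFT of the sampled
#' r-space dipole `d(r) = (3 cos^2 theta - 1) / (4 pi r^3)` on the periodic
#' minimal-image lattice (d(0) = 0).  This variant exists to cross-check the
#' FFT forward model against direct r-space convolution; the analytic
#' k-space kernel is the one used for reconstruction.
#'
#' @param grid a [VolumeGrid-class].
#' @param method "kspace" (analytic, default) or "rspace" (FFT of the
#'   sampled r-space dipole).
#' @return A [DipoleKernelK-class].
#' @examples
#' D <- makeDipoleKernel(VolumeGrid(c(16, 16, 16)))
#' range(volumeValues(D))   # within [-2/3, 1/3]
#' @export
makeDipoleKernel <- function(grid, method = c("kspace", "rspace")) {
    stopifnot(is(grid, "VolumeGrid"))
    method <- match.arg(method)
    sh <- grid@shape
    if (method == "kspace") {
        kx <- .fftfreq(sh[1]) / grid@voxelSize[1]
        ky <- .fftfreq(sh[2]) / grid@voxelSize[2]
        kz <- .fftfreq(sh[3]) / grid@voxelSize[3]
        b0 <- grid@b0Dir
        ## (k . b0) and |k|^2 via outer sums, kept memory-light
        KX <- array(kx, sh)
        KY <- array(rep(ky, each = sh[1]), sh)
        KZ <- array(rep(kz, each = sh[1] * sh[2]), sh)
        kpar <- KX * b0[1] + KY * b0[2] + KZ * b0[3]
        k2 <- KX^2 + KY^2 + KZ^2
        D <- array(0, sh)
        nz <- k2 > 0
        D[nz] <- 1 / 3 - (kpar[nz]^2) / k2[nz]
    } else {
        d <- .sampleRspaceDipole(grid)
        D <- Re(fft(d))
    }
    new("DipoleKernelK", grid = grid, values = D)
}

## sampled r-space dipole on the periodic minimal-image lattice, d(0) = 0
.sampleRspaceDipole <- function(grid) {
    sh <- grid@shape
    rx <- .fftOffsets(sh[1]) * grid@voxelSize[1]
    ry <- .fftOffsets(sh[2]) * grid@voxelSize[2]
    rz <- .fftOffsets(sh[3]) * grid@voxelSize[3]
    RX <- array(rx, sh)
    RY <- array(rep(ry, each = sh[1]), sh)
    RZ <- array(rep(rz, each = sh[1] * sh[2]), sh)
    b0 <- grid@b0Dir
    r2 <- RX^2 + RY^2 + RZ^2
    rpar <- RX * b0[1] + RY * b0[2] + RZ * b0[3]
    d <- array(0, sh)
    nz <- r2 > 0
    d[nz] <- (3 * rpar[nz]^2 / r2[nz] - 1) / (4 * pi * r2[nz]^1.5)
    d
}

## raw-array forward model used in the solver hot path
.applyKernel <- function(values, D) {
    Re(fft(D * fft(values), inverse = TRUE)) / length(values)
}

#' Apply the dipole forward model
#'
#' Computes the local field a susceptibility map induces:
#' `Re(IFFT(D * FFT(chi)))`.  Linear and (because D is real and even)
#' self-adjoint; the output has zero mean over the periodic volume since
#' D(0) = 0.
#'
#' @param chi a [ScalarVolume-class] susceptibility map in ppm.
#' @param kernel a [DipoleKernelK-class] on the same grid.
#' @return A [ScalarVolume-class] field map, ppm.
#' @examples
#' g <- VolumeGrid(c(16, 16, 16))
#' chi <- ScalarVolume(array(rnorm(16^3), c(16, 16, 16)), g, unit = "ppm")
#' phi <- forwardField(chi, makeDipoleKernel(g))
#' @export
forwardField <- function(chi, kernel) {
    stopifnot(is(chi, "ScalarVolume"), is(kernel, "DipoleKernelK"))
    .checkSameGrid(chi, kernel, "susceptibility and kernel")
    if (chi@unit != "ppm")
        warning("forwardField expects susceptibility in ppm; got '",
                chi@unit, "'")
    ScalarVolume(.applyKernel(chi@values, kernel@values), grid = chi@grid,
                 unit = "ppm")
}

#' Direct r-space convolution reference for the forward model
#'
#' Computes the field by direct periodic discrete convolution of the
#' susceptibility map with the sampled r-space dipole kernel, summing over
#' every pair of voxels.  O(N^2) in the voxel count, so intended for small
#' grids (<= 32^3) as an independent check of [forwardField()]; both paths
#' share the same periodic wrap so their agreement is exact up to FFT
#' round-off.
#'
#' @param chi a [ScalarVolume-class] susceptibility map.
#' @param grid optional [VolumeGrid-class]; defaults to `chi`'s grid.
#' @return A [ScalarVolume-class] field map, ppm.
#' @export
rspaceConvolutionOracle <- function(chi, grid = NULL) {
    stopifnot(is(chi, "ScalarVolume"))
    if (is.null(grid)) grid <- chi@grid
    .checkSameGrid(chi, grid, "susceptibility and grid")
    d <- .sampleRspaceDipole(grid)
    sh <- grid@shape
    nx <- sh[1]; ny <- sh[2]; nz <- sh[3]
    ## conv[p] = sum_q d[(p - q) mod N] chi[q]: accumulate shifted copies of d
    sx <- lapply(0:(nx - 1L), function(q) (((0:(nx - 1L)) - q) %% nx) + 1L)
    sy <- lapply(0:(ny - 1L), function(q) (((0:(ny - 1L)) - q) %% ny) + 1L)
    sz <- lapply(0:(nz - 1L), function(q) (((0:(nz - 1L)) - q) %% nz) + 1L)
    v <- chi@values
    out <- array(0, sh)
    for (qk in seq_len(nz)) {
        dk <- d[, , sz[[qk]], drop = FALSE]
        for (qj in seq_len(ny)) {
            djk <- dk[, sy[[qj]], , drop = FALSE]
            for (qi in seq_len(nx)) {
                cq <- v[qi, qj, qk]
                if (cq != 0)
                    out <- out + cq * djk[sx[[qi]], , , drop = FALSE]
            }
        }
    }
    ScalarVolume(out, grid = grid, unit = "ppm")
}
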