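## Reconstruction quality metrics, all restricted to the mask support:
## relative error norm (RMSE, %), high-frequency error norm (HFEN, %,
## Laplacian-of-Gaussian filtered), structural similarity (SSIM), and
## ordinary least-squares regression of per-ROI means against a reference.

## periodic FFT convolution of a volume with a small centered kernel
.convPeriodic <- function(vol, kern) {
    sh <- dim(vol)
    kpad <- array(0, sh)
    ks <- dim(kern)
    if (any(ks > sh))
        stop("volume (", paste(sh, collapse = "x"),
             ") is smaller than the filter kernel (",
             paste(ks, collapse = "x"), ")")
    off <- -(ks - 1L) %/% 2L
    ## scatter taps with wraparound so the kernel is centered at the origin
    ix <- ((seq_len(ks[1]) - 1L + off[1]) %% sh[1]) + 1L
    iy <- ((seq_len(ks[2]) - 1L + off[2]) %% sh[2]) + 1L
    iz <- ((seq_len(ks[3]) - 1L + off[3]) %% sh[3]) + 1L
    for (k in seq_len(ks[3]))
        kpad[ix, iy, iz[k]] <- kpad[ix, iy, iz[k]] + kern[, , k]
    Re(fft(fft(vol) * fft(kpad), inverse = TRUE)) / length(vol)
}

## 3D Gaussian window, normalized to unit sum
.gaussKernel <- function(size = 11L, sigma = 1.5) {
    o <- seq_len(size) - (size + 1L) / 2
    r2 <- outer(outer(o^2, o^2, "+"), o^2, "+")
    g <- exp(-r2 / (2 * sigma^2))
    g / sum(g)
}

## 3D Laplacian-of-Gaussian, zero-sum so constants are annihilated
.logKernel <- function(size = 15L, sigma = 1.5) {
    o <- seq_len(size) - (size + 1L) / 2
    r2 <- outer(outer(o^2, o^2, "+"), o^2, "+")
    g <- exp(-r2 / (2 * sigma^2))
    h <- g * (r2 - 3 * sigma^2) / (sigma^4 * sum(g))
    h - mean(h)
}

.checkMetricInputs <- function(recon, ref, mask) {
    stopifnot(is(recon, "ScalarVolume"), is(ref, "ScalarVolume"),
              is(mask, "MaskVolume"))
    .checkSameGrid(recon, ref, "reconstruction and reference")
    .checkSameGrid(recon, mask, "reconstruction and mask")
}

#' Relative error norm (RMSE, percent)
#'
#' `100 * ||(recon - ref) * mask||_2 / ||ref * mask||_2`: the L2 norm of
#' the in-mask error relative to the in-mask reference norm, as a
#' percentage.  Identical volumes give 0; a zero reconstruction gives 100.
#'
#' @param recon reconstructed [ScalarVolume-class].
#' @param ref reference [ScalarVolume-class].
#' @param mask evaluation [MaskVolume-class].
#' @return RMSE in percent.
#' @export
metricRMSE <- function(recon, ref, mask) {
    .checkMetricInputs(recon, ref, mask)
    m <- mask@values
    den <- sqrt(sum((ref@values[m])^2))
    if (den == 0)
        stop("degenerate input: reference is identically zero inside the mask")
    100 * sqrt(sum((recon@values[m] - ref@values[m])^2)) / den
}

#' High-frequency error norm (HFEN, percent)
#'
#' Filters the masked reconstruction and reference with a 3D
#' Laplacian-of-Gaussian (15x15x15 taps, sigma = 1.5 voxels, the convention
#' of the compressed-sensing MRI literature the metric originates from) and
#' reports the relative L2 error of the filtered volumes in percent.  The
#' LoG passes edges and fine structure while annihilating constants and
#' smooth trends, so HFEN isolates high-spatial-frequency error.
#'
#' @inheritParams metricRMSE
#' @param size LoG kernel size per axis (odd; default 15).
#' @param sigma LoG Gaussian width in voxels (default 1.5).
#' @return HFEN in percent.
#' @export
metricHFEN <- function(recon, ref, mask, size = 15L, sigma = 1.5) {
    .checkMetricInputs(recon, ref, mask)
    h <- .logKernel(size, sigma)
    m <- mask@values
    fr <- .convPeriodic(recon@values * m, h)
    fg <- .convPeriodic(ref@values * m, h)
    den <- sqrt(sum(fg^2))
    if (den == 0)
        stop("degenerate input: LoG-filtered reference has zero norm")
    100 * sqrt(sum((fr - fg)^2)) / den
}

#' Structural similarity index (SSIM)
#'
#' Mean 3D SSIM over in-mask voxels between the masked reconstruction and
#' reference, computed with a Gaussian window (sigma = 1.5 voxels, 11^3
#' taps) and the standard constants C1 = (0.01 L)^2, C2 = (0.03 L)^2 where
#' the dynamic range L is max - min of the reference inside the mask
#' (overridable via `dynamicRange` for symmetric comparisons).
#'
#' @inheritParams metricRMSE
#' @param sigma Gaussian window width in voxels (default 1.5).
#' @param size window size per axis (odd; default 11).
#' @param dynamicRange optional fixed dynamic range L; by default derived
#'   from the reference.
#' @return Mean SSIM over the mask, in [-1, 1].
#' @export
metricSSIM <- function(recon, ref, mask, sigma = 1.5, size = 11L,
                       dynamicRange = NULL) {
    .checkMetricInputs(recon, ref, mask)
    m <- mask@values
    a <- recon@values * m
    b <- ref@values * m
    L <- if (is.null(dynamicRange))
        diff(range(ref@values[m]))
    else dynamicRange
    if (L <= 0)
        stop("degenerate input: reference has zero dynamic range inside the mask")
    C1 <- (0.01 * L)^2
    C2 <- (0.03 * L)^2
    w <- .gaussKernel(size, sigma)
    mu1 <- .convPeriodic(a, w)
    mu2 <- .convPeriodic(b, w)
    s1 <- pmax(.convPeriodic(a * a, w) - mu1^2, 0)
    s2 <- pmax(.convPeriodic(b * b, w) - mu2^2, 0)
    s12 <- .convPeriodic(a * b, w) - mu1 * mu2
    ssimMap <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
        ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2))
    mean(ssimMap[m])
}

#' Full metric report
#'
#' Convenience wrapper computing RMSE, HFEN and SSIM in one call.
#'
#' @inheritParams metricRMSE
#' @return A [MetricReport-class].
#' @export
evaluateQSM <- function(recon, ref, mask) {
    new("MetricReport",
        rmse = metricRMSE(recon, ref, mask),
        hfen = metricHFEN(recon, ref, mask),
        ssim = metricSSIM(recon, ref, mask),
        nVoxels = as.integer(sum(mask@values)))
}

#' ROI regression of reconstruction against reference
#'
#' Computes per-ROI mean susceptibilities in both volumes and fits the
#' ordinary least-squares line recon-mean = slope * ref-mean + intercept.
#' Slope 1, intercept 0 and R^2 = 1 indicate unbiased quantitative
#' recovery.
#'
#' @param recon reconstructed [ScalarVolume-class].
#' @param ref reference [ScalarVolume-class].
#' @param rois list of at least two [MaskVolume-class] ROIs.
#' @return A [RegressionResult-class].
#' @export
roiRegression <- function(recon, ref, rois) {
    stopifnot(is(recon, "ScalarVolume"), is(ref, "ScalarVolume"))
    if (!is.list(rois) || length(rois) < 2L)
        stop("at least 2 ROIs are required for regression")
    for (r in rois) {
        stopifnot(is(r, "MaskVolume"))
        .checkSameGrid(recon, r, "reconstruction and ROI")
    }
    mx <- vapply(rois, function(r) mean(ref@values[r@values]), numeric(1))
    my <- vapply(rois, function(r) mean(recon@values[r@values]), numeric(1))
    if (stats::var(mx) == 0)
        stop("degenerate input: reference ROI means are all equal")
    fit <- stats::lm(my ~ mx)
    new("RegressionResult",
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        rSquared = max(0, min(1,
            suppressWarnings(summary(fit)$r.squared))),
        roiMeansRecon = my, roiMeansRef = mx)
}
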