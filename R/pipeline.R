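## End-to-end pipeline entry points behind the command-line interface.
## Each run* function is a thin orchestration layer over the module
## functions and logs a run summary; the CLI script maps subcommand flags
## onto their arguments.

.logmsg <- function(verbose, ...) if (verbose) message(...)

#' Simulate a phantom study and write it to disk
#'
#' Generates a balloon-phantom study ([simulateStudy()]) and writes
#' `chi_true`, `field`, `magnitude`, `mask` and per-sphere `roi_<i>` NIfTI
#' volumes plus a plain-text echo of the specification to `outDir`.
#'
#' @param outDir output directory (created if needed).
#' @param shape grid shape (default 64^3).
#' @param snr field signal-to-noise ratio.
#' @param seed integer RNG seed.
#' @param edgeMismatch sphere index with suppressed magnitude contrast
#'   (0 = none).
#' @param verbose log progress to stderr.
#' @return The [SimulatedStudy-class], invisibly.
#' @export
runSimulate <- function(outDir, shape = c(64, 64, 64), snr = 50, seed = 0L,
                        edgeMismatch = 0L, verbose = TRUE) {
    spec <- defaultPhantomSpec(shape, edgeMismatch = edgeMismatch)
    study <- simulateStudy(spec, snr = snr, seed = seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeVolume(study@chiTrue, file.path(outDir, "chi_true.nii.gz"))
    writeVolume(study@field, file.path(outDir, "field.nii.gz"))
    writeVolume(study@magnitude, file.path(outDir, "magnitude.nii.gz"))
    writeVolume(study@mask, file.path(outDir, "mask.nii.gz"))
    for (i in seq_along(study@rois))
        writeVolume(study@rois[[i]],
                    file.path(outDir, sprintf("roi_%d.nii.gz", i)))
    writeRunConfig(list(shape = shape, snr = snr, seed = seed,
                        edge_mismatch = edgeMismatch,
                        noise_sd_ppm = study@noiseSd,
                        n_spheres = length(study@rois),
                        chi_ppm = spec@chi),
                   file.path(outDir, "spec.txt"))
    .logmsg(verbose, "simulated ", length(study@rois), "-sphere study (",
            paste(shape, collapse = "x"), ", snr ", snr, ", seed ", seed,
            ") -> ", outDir)
    invisible(study)
}

#' Reconstruct a susceptibility map from files
#'
#' Full reconstruction pipeline: read field, magnitude and mask; build the
#' fidelity weight; derive the magnitude gradient, boundary threshold and
#' soft (MATV) or hard (MEDI) edge weight; run the solver; write the
#' susceptibility map (and an absolute-error map if a reference is given).
#' A summary block (lambda, threshold, boundary fraction, iterations, final
#' objective) is always logged.
#'
#' @param fieldPath NIfTI local field map, ppm.
#' @param magnitudePath NIfTI magnitude image.
#' @param maskPath NIfTI binary mask.
#' @param outPath output NIfTI path for the susceptibility map.
#' @param mode "matv" (soft sine weighting) or "medi" (hard threshold).
#' @param lambda regularization parameter.
#' @param edgeFraction target boundary fraction for the threshold rule.
#' @param epsilon,maxOuter,cgTol,cgMax,outerTol solver controls, see
#'   [SolverConfig()].
#' @param b0Dir main-field direction (default +z).
#' @param referencePath optional NIfTI reference susceptibility; when
#'   given, `<outPath>` gains a sibling `*_abserr` absolute-error volume.
#' @param verbose log progress to stderr.
#' @return The [SolveResult-class], invisibly.
#' @export
runReconstruct <- function(fieldPath, magnitudePath, maskPath, outPath,
                           mode = c("matv", "medi"), lambda = 7e-4,
                           edgeFraction = 0.3, epsilon = 1e-6,
                           maxOuter = 10L, cgTol = 0.01, cgMax = 100L,
                           outerTol = 0.01, b0Dir = c(0, 0, 1),
                           referencePath = NULL, verbose = TRUE) {
    mode <- match.arg(mode)
    for (p in c(fieldPath, magnitudePath, maskPath))
        if (!file.exists(p)) stop("input file not found: ", p)
    field <- readVolume(fieldPath, unit = "ppm", b0Dir = b0Dir)
    magnitude <- readVolume(magnitudePath, unit = "au", b0Dir = b0Dir)
    mask <- readMask(maskPath, b0Dir = b0Dir)
    wm <- computeDataWeight(magnitude, mask)
    ew <- edgeWeights(magnitude, mask, fraction = edgeFraction, mode = mode)
    kernel <- makeDipoleKernel(volumeGrid(field))
    cfg <- SolverConfig(lambda = lambda, epsilon = epsilon,
                        maxOuter = maxOuter, cgTol = cgTol, cgMax = cgMax,
                        outerTol = outerTol)
    res <- solveMATV(field, wm, ew$weight, kernel, cfg, mask = mask)
    writeVolume(res@chi, outPath)
    if (!is.null(referencePath)) {
        ref <- readVolume(referencePath, unit = "ppm", b0Dir = b0Dir)
        .checkSameGrid(res@chi, ref, "reconstruction and reference")
        err <- ScalarVolume(abs(res@chi@values - ref@values) *
                            mask@values, grid = ref@grid, unit = "ppm")
        errPath <- sub("(\\.nii(\\.gz)?)$", "_abserr\\1", outPath)
        if (identical(errPath, outPath)) errPath <- paste0(outPath, "_abserr")
        writeVolume(err, errPath)
    }
    .logmsg(verbose, sprintf(
        "reconstruct [%s]: lambda = %g, c = %g, boundary %.1f%%, %d outer iterations%s, objective %.6g -> %.6g",
        mode, lambda, ew$threshold@value, 100 * ew$threshold@achieved,
        res@nOuter, if (res@converged) " (converged)" else "",
        res@objectiveTrace[1], res@objectiveTrace[length(res@objectiveTrace)]))
    invisible(res)
}

#' Evaluate a reconstruction against a reference
#'
#' Computes RMSE, HFEN and SSIM over the mask and, when ROI masks are
#' supplied, the ROI-mean linear regression.  Results are printed as
#' aligned text and returned.
#'
#' @param reconPath NIfTI reconstructed susceptibility map.
#' @param referencePath NIfTI reference susceptibility map.
#' @param maskPath NIfTI binary mask.
#' @param roiPaths optional character vector of >= 2 NIfTI ROI masks.
#' @param verbose print the report.
#' @return List with `metrics` ([MetricReport-class]) and, when ROIs were
#'   given, `regression` ([RegressionResult-class]), invisibly.
#' @export
runEvaluate <- function(reconPath, referencePath, maskPath,
                        roiPaths = NULL, verbose = TRUE) {
    for (p in c(reconPath, referencePath, maskPath, roiPaths))
        if (!file.exists(p)) stop("input file not found: ", p)
    recon <- readVolume(reconPath, unit = "ppm")
    ref <- readVolume(referencePath, unit = "ppm")
    mask <- readMask(maskPath)
    rep <- evaluateQSM(recon, ref, mask)
    out <- list(metrics = rep)
    if (verbose) show(rep)
    if (!is.null(roiPaths)) {
        rois <- lapply(roiPaths, readMask)
        out$regression <- roiRegression(recon, ref, rois)
        if (verbose) show(out$regression)
    }
    invisible(out)
}

#' Write the weight maps for inspection
#'
#' Computes and writes the fidelity weight `W_m` and the three per-axis TV
#' edge-weight volumes for the requested mode.
#'
#' @param magnitudePath NIfTI magnitude image.
#' @param maskPath NIfTI binary mask.
#' @param outPrefix path prefix; files `<prefix>_wm.nii.gz` and
#'   `<prefix>_wedge_{x,y,z}.nii.gz` are written.
#' @param edgeFraction target boundary fraction.
#' @param mode "matv" or "medi".
#' @param verbose log the threshold summary.
#' @return List with `wm`, `weight`, `threshold`, invisibly.
#' @export
runWeights <- function(magnitudePath, maskPath, outPrefix,
                       edgeFraction = 0.3, mode = c("matv", "medi"),
                       verbose = TRUE) {
    mode <- match.arg(mode)
    for (p in c(magnitudePath, maskPath))
        if (!file.exists(p)) stop("input file not found: ", p)
    magnitude <- readVolume(magnitudePath, unit = "au")
    mask <- readMask(maskPath)
    wm <- computeDataWeight(magnitude, mask)
    ew <- edgeWeights(magnitude, mask, fraction = edgeFraction, mode = mode)
    writeVolume(ScalarVolume(wm@values, grid = wm@grid,
                             unit = "dimensionless"),
                paste0(outPrefix, "_wm.nii.gz"))
    comps <- vectorComponents(ew$weight)
    for (ax in names(comps))
        writeVolume(ScalarVolume(comps[[ax]], grid = wm@grid,
                                 unit = "dimensionless"),
                    paste0(outPrefix, "_wedge_", ax, ".nii.gz"))
    .logmsg(verbose, sprintf("weights [%s]: c = %g, boundary %.1f%%",
                             mode, ew$threshold@value,
                             100 * ew$threshold@achieved))
    invisible(list(wm = wm, weight = ew$weight, threshold = ew$threshold))
}
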