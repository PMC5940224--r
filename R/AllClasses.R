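#' @import methods
NULL

## ---------------------------------------------------------------------------
## Grid and volume containers
## ---------------------------------------------------------------------------

#' Voxel grid geometry
#'
#' Describes the discrete 3D sampling grid shared by all volumes in a
#' reconstruction: array shape, physical voxel size, and the direction of the
#' main magnetic field B0 expressed in the volume frame.  The field direction
#' is what orients the dipole kernel; it defaults to the third array axis
#' (+z), the usual axial acquisition convention.
#'
#' @slot shape integer length-3, array dimensions (nx, ny, nz); each >= 8.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm; each > 0.
#' @slot b0Dir numeric length-3 unit vector, direction of B0.
#' @export
setClass("VolumeGrid", representation(
    shape = "integer",
    voxelSize = "numeric",
    b0Dir = "numeric"
))

setValidity("VolumeGrid", function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(is.na(object@shape)))
        msg <- c(msg, "'shape' must be 3 integers")
    else if (any(object@shape < 8L))
        msg <- c(msg, "all grid dimensions must be >= 8")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
        msg <- c(msg, "'voxelSize' must be 3 positive reals (mm)")
    if (length(object@b0Dir) != 3L || any(!is.finite(object@b0Dir)))
        msg <- c(msg, "'b0Dir' must be a length-3 numeric vector")
    else if (abs(sqrt(sum(object@b0Dir^2)) - 1) > 1e-12)
        msg <- c(msg, "'b0Dir' must have unit norm (|b0Dir| = 1 within 1e-12)")
    if (length(msg)) msg else TRUE
})

#' Construct a VolumeGrid
#'
#' @param shape integer length-3 array dimensions, each >= 8.
#' @param voxelSize numeric length-3 voxel edge lengths in mm (default
#'   isotropic 1 mm).
#' @param b0Dir length-3 direction of the main field; normalized to unit
#'   length internally.  Default +z.
#' @return A [VolumeGrid-class] object.
#' @examples
#' g <- VolumeGrid(c(64, 64, 64))
#' @export
VolumeGrid <- function(shape, voxelSize = c(1, 1, 1), b0Dir = c(0, 0, 1)) {
    b0 <- as.numeric(b0Dir)
    nb <- sqrt(sum(b0^2))
    if (!is.finite(nb) || nb == 0)
        stop("'b0Dir' must be a nonzero finite vector")
    new("VolumeGrid", shape = as.integer(shape),
        voxelSize = as.numeric(voxelSize), b0Dir = b0 / nb)
}

#' Scalar voxel volume
#'
#' A real-valued 3D array on a [VolumeGrid-class] with a unit tag.  Holds the
#' susceptibility map chi (ppm), the local tissue field phi (ppm), and the
#' magnitude image m (a.u.).
#'
#' @slot grid VolumeGrid.
#' @slot values real 3D array with dim equal to the grid shape; all finite.
#' @slot unit one of "ppm", "au", "dimensionless".
#' @export
setClass("ScalarVolume", representation(
    grid = "VolumeGrid",
    values = "array",
    unit = "character"
))

setValidity("ScalarVolume", function(object) {
    msg <- character()
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
        msg <- c(msg, "dim(values) must equal grid shape")
    if (!all(is.finite(object@values)))
        msg <- c(msg, "values must be finite everywhere")
    if (length(object@unit) != 1L ||
        !object@unit %in% c("ppm", "au", "dimensionless"))
        msg <- c(msg, "unit must be one of 'ppm', 'au', 'dimensionless'")
    if (length(msg)) msg else TRUE
})

#' Construct a ScalarVolume
#'
#' @param values real 3D array.
#' @param grid a [VolumeGrid-class]; by default built from `dim(values)` with
#'   1 mm isotropic voxels and B0 along +z.
#' @param unit unit tag: "ppm", "au" or "dimensionless".
#' @return A [ScalarVolume-class].
#' @export
ScalarVolume <- function(values, grid = NULL, unit = "dimensionless") {
    values <- as.array(values)
    if (is.null(grid)) grid <- VolumeGrid(dim(values))
    new("ScalarVolume", grid = grid, values = values, unit = unit)
}

#' Per-axis gradient (vector) volume
#'
#' Three co-registered 3D arrays holding the x, y and z forward differences
#' of a scalar volume, in units of the parent per voxel step.
#'
#' @slot grid VolumeGrid.
#' @slot x,y,z real 3D arrays, one per difference axis.
#' @export
setClass("VectorVolume", representation(
    grid = "VolumeGrid",
    x = "array", y = "array", z = "array"
))

setValidity("VectorVolume", function(object) {
    d <- as.integer(object@grid@shape)
    if (!identical(dim(object@x), d) || !identical(dim(object@y), d) ||
        !identical(dim(object@z), d))
        return("all three components must share the grid shape")
    TRUE
})

#' Construct a VectorVolume
#' @param x,y,z real 3D arrays of identical dim.
#' @param grid a [VolumeGrid-class]; defaults to `dim(x)` with 1 mm voxels.
#' @return A [VectorVolume-class].
#' @export
VectorVolume <- function(x, y, z, grid = NULL) {
    if (is.null(grid)) grid <- VolumeGrid(dim(x))
    new("VectorVolume", grid = grid, x = as.array(x), y = as.array(y),
        z = as.array(z))
}

#' Binary mask volume
#'
#' Region of support for reconstruction and evaluation (the object interior).
#'
#' @slot grid VolumeGrid.
#' @slot values logical 3D array; at least one voxel TRUE.
#' @export
setClass("MaskVolume", representation(
    grid = "VolumeGrid",
    values = "array"
))

setValidity("MaskVolume", function(object) {
    msg <- character()
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
        msg <- c(msg, "dim(values) must equal grid shape")
    if (!is.logical(object@values))
        msg <- c(msg, "mask values must be logical")
    else if (!any(object@values))
        msg <- c(msg, "mask must contain at least one voxel")
    if (length(msg)) msg else TRUE
})

#' Construct a MaskVolume
#' @param values array coercible to logical (nonzero = inside).
#' @param grid a [VolumeGrid-class]; defaults to `dim(values)`.
#' @return A [MaskVolume-class].
#' @export
MaskVolume <- function(values, grid = NULL) {
    v <- array(as.logical(values), dim = dim(values))
    if (is.null(grid)) grid <- VolumeGrid(dim(v))
    new("MaskVolume", grid = grid, values = v)
}

## ---------------------------------------------------------------------------
## Dipole kernel
## ---------------------------------------------------------------------------

#' k-space dipole kernel
#'
#' The unit magnetic dipole response sampled on the FFT frequency grid,
#' D(k) = 1/3 - (k . b0)^2 / |k|^2 with D(0) = 0.  Multiplying the Fourier
#' transform of a susceptibility map by D and inverting yields the local
#' field shift the tissue induces.
#'
#' @slot grid VolumeGrid.
#' @slot values real 3D array of kernel samples (dimensionless).
#' @export
setClass("DipoleKernelK", representation(
    grid = "VolumeGrid",
    values = "array"
))

setValidity("DipoleKernelK", function(object) {
    msg <- character()
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
        msg <- c(msg, "dim(values) must equal grid shape")
    if (!all(is.finite(object@values)))
        msg <- c(msg, "kernel values must be finite")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Weights
## ---------------------------------------------------------------------------

#' Data-fidelity weight W_m
#'
#' Diagonal weighting of the field-fit residual, proportional to image
#' magnitude (higher magnitude = higher phase SNR), zero outside the mask and
#' normalized so the in-mask mean is 1.
#'
#' @slot grid VolumeGrid.
#' @slot values non-negative real 3D array.
#' @export
setClass("DataWeight", representation(
    grid = "VolumeGrid",
    values = "array"
))

setValidity("DataWeight", function(object) {
    msg <- character()
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
        msg <- c(msg, "dim(values) must equal grid shape")
    if (any(!is.finite(object@values)) || any(object@values < 0))
        msg <- c(msg, "weights must be finite and non-negative")
    if (length(msg)) msg else TRUE
})

#' Magnitude-gradient edge threshold
#'
#' The scalar threshold c separating "smooth" from "boundary" voxels in the
#' magnitude gradient maps, chosen so that approximately a target fraction
#' (default 30%) of pooled in-mask gradient-component magnitudes lie at or
#' above c.
#'
#' @slot value positive real, threshold in magnitude units per voxel step.
#' @slot fraction target boundary fraction in (0, 1).
#' @slot achieved fraction of pooled gradient values actually at or above
#'   the chosen threshold.
#' @export
setClass("EdgeThreshold", representation(
    value = "numeric",
    fraction = "numeric",
    achieved = "numeric"
))

setValidity("EdgeThreshold", function(object) {
    msg <- character()
    if (length(object@value) != 1L || !is.finite(object@value) ||
        object@value <= 0)
        msg <- c(msg, "threshold value must be a positive real")
    if (length(object@fraction) != 1L || object@fraction <= 0 ||
        object@fraction >= 1)
        msg <- c(msg, "target fraction must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Per-axis TV edge weight W_grad-m
#'
#' Weights in [0, 1] multiplying the x, y and z components of the
#' susceptibility gradient inside the TV penalty.  Mode "matv_soft" is the
#' continuous sine soft threshold; mode "medi_hard" is the binary indicator
#' of sub-threshold gradient used by MEDI.
#'
#' @slot grid VolumeGrid.
#' @slot x,y,z real 3D arrays with entries in [0, 1].
#' @slot mode "matv_soft" or "medi_hard".
#' @export
setClass("EdgeWeight", representation(
    grid = "VolumeGrid",
    x = "array", y = "array", z = "array",
    mode = "character"
))

setValidity("EdgeWeight", function(object) {
    msg <- character()
    d <- as.integer(object@grid@shape)
    if (!identical(dim(object@x), d) || !identical(dim(object@y), d) ||
        !identical(dim(object@z), d))
        msg <- c(msg, "all three components must share the grid shape")
    rng <- range(object@x, object@y, object@z)
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1 + 1e-12)
        msg <- c(msg, "edge weights must lie in [0, 1]")
    if (length(object@mode) != 1L ||
        !object@mode %in% c("matv_soft", "medi_hard"))
        msg <- c(msg, "mode must be 'matv_soft' or 'medi_hard'")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Solver configuration and result
## ---------------------------------------------------------------------------

#' Solver configuration
#'
#' Parameters of the smoothed-L1 Gauss-Newton / conjugate-gradient solver.
#'
#' @slot lambda positive regularization parameter balancing fidelity and TV.
#' @slot epsilon positive L1 smoothing floor (|x| ~ sqrt(x^2 + epsilon^2)).
#' @slot maxOuter maximum Gauss-Newton (outer) iterations.
#' @slot cgTol inner CG relative-residual tolerance, in (0, 1).
#' @slot cgMax maximum inner CG iterations per outer iteration.
#' @slot outerTol relative update-norm stopping tolerance, in (0, 1).
#' @slot seed integer seed for any randomized initialization (the default
#'   zero initialization uses no randomness).
#' @export
setClass("SolverConfig", representation(
    lambda = "numeric",
    epsilon = "numeric",
    maxOuter = "integer",
    cgTol = "numeric",
    cgMax = "integer",
    outerTol = "numeric",
    seed = "integer"
))

setValidity("SolverConfig", function(object) {
    msg <- character()
    if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
    if (object@maxOuter < 1L) msg <- c(msg, "maxOuter must be >= 1")
    if (object@cgMax < 1L) msg <- c(msg, "cgMax must be >= 1")
    if (object@cgTol <= 0 || object@cgTol >= 1)
        msg <- c(msg, "cgTol must lie in (0, 1)")
    if (object@outerTol <= 0 || object@outerTol >= 1)
        msg <- c(msg, "outerTol must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Construct a SolverConfig
#'
#' Defaults follow the published MEDI solver family: smoothing floor
#' epsilon = 1e-6, 10 outer Gauss-Newton iterations stopping at 1% relative
#' update, inner CG to 1% relative residual.  The default lambda = 0.0007 is
#' the value used for in vivo brain reconstructions; 0.0017 is the value for
#' the gadolinium phantom.
#'
#' @param lambda regularization parameter (> 0).
#' @param epsilon L1 smoothing floor (> 0).
#' @param maxOuter maximum outer iterations.
#' @param cgTol inner CG relative-residual tolerance.
#' @param cgMax maximum CG iterations per outer solve.
#' @param outerTol relative update-norm stopping rule.
#' @param seed integer seed (unused by the deterministic zero init).
#' @return A [SolverConfig-class].
#' @export
SolverConfig <- function(lambda = 7e-4, epsilon = 1e-6, maxOuter = 10L,
                         cgTol = 0.01, cgMax = 100L, outerTol = 0.01,
                         seed = 0L) {
    new("SolverConfig", lambda = as.numeric(lambda),
        epsilon = as.numeric(epsilon), maxOuter = as.integer(maxOuter),
        cgTol = as.numeric(cgTol), cgMax = as.integer(cgMax),
        outerTol = as.numeric(outerTol), seed = as.integer(seed))
}

#' Reconstruction result
#'
#' @slot chi reconstructed susceptibility [ScalarVolume-class], ppm.
#' @slot objectiveTrace exact (unsmoothed) objective value at initialization
#'   and after each outer iteration; non-increasing within 1e-8 relative
#'   slack.
#' @slot nOuter number of outer iterations performed.
#' @slot converged TRUE if the relative-update stopping rule fired before
#'   maxOuter.
#' @export
setClass("SolveResult", representation(
    chi = "ScalarVolume",
    objectiveTrace = "numeric",
    nOuter = "integer",
    converged = "logical"
))

setValidity("SolveResult", function(object) {
    tr <- object@objectiveTrace
    if (length(tr) >= 2) {
        scale <- max(abs(tr[1]), 1e-300)
        if (any(diff(tr) > 1e-8 * scale))
            return("objectiveTrace must be non-increasing (1e-8 relative slack)")
    }
    TRUE
})

## ---------------------------------------------------------------------------
## Phantom specification and simulated study
## ---------------------------------------------------------------------------

#' Balloon phantom specification
#'
#' Declarative description of a gadolinium balloon phantom: non-overlapping
#' spheres of assigned susceptibility embedded in a uniform background, plus
#' per-region magnitude levels used to synthesize the co-registered
#' magnitude image.
#'
#' @slot grid VolumeGrid.
#' @slot centers numeric n x 3 matrix of sphere centers (voxel coordinates).
#' @slot radii numeric length-n sphere radii in voxels, each >= 2.
#' @slot chi numeric length-n susceptibilities (ppm).
#' @slot backgroundChi background susceptibility (ppm).
#' @slot magnitudeContrasts numeric length-n per-sphere magnitude levels
#'   (a.u.).
#' @slot backgroundMagnitude magnitude level of the background region (a.u.).
#' @slot edgeMismatch integer sphere index whose magnitude contrast is
#'   suppressed (edge present in chi but absent in magnitude); 0 = none.
#' @export
setClass("PhantomSpec", representation(
    grid = "VolumeGrid",
    centers = "matrix",
    radii = "numeric",
    chi = "numeric",
    backgroundChi = "numeric",
    magnitudeContrasts = "numeric",
    backgroundMagnitude = "numeric",
    edgeMismatch = "integer"
))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    n <- nrow(object@centers)
    if (ncol(object@centers) != 3L)
        msg <- c(msg, "centers must be an n x 3 matrix")
    if (length(object@radii) != n || length(object@chi) != n ||
        length(object@magnitudeContrasts) != n)
        msg <- c(msg, "radii, chi, magnitudeContrasts must match nrow(centers)")
    if (n > 0 && any(object@radii < 2))
        msg <- c(msg, "sphere radii must be >= 2 voxels")
    if (n > 0) {
        sh <- object@grid@shape
        for (i in seq_len(n)) {
            if (any(object@centers[i, ] - object@radii[i] < 1) ||
                any(object@centers[i, ] + object@radii[i] > sh))
                msg <- c(msg, sprintf("sphere %d extends outside the grid", i))
        }
    }
    if (object@edgeMismatch < 0L || object@edgeMismatch > n)
        msg <- c(msg, "edgeMismatch must be 0 or a valid sphere index")
    if (length(msg)) msg else TRUE
})

#' Simulated phantom study
#'
#' A complete synthetic dataset: ground-truth susceptibility, noisy
#' forward-simulated local field, co-registered magnitude, support mask and
#' one ROI per sphere.  Regenerated bit-identically from the stored seed.
#'
#' @slot chiTrue ground-truth susceptibility (ppm).
#' @slot field noisy local tissue field (ppm).
#' @slot magnitude magnitude image (a.u.).
#' @slot mask support [MaskVolume-class].
#' @slot rois list of per-sphere [MaskVolume-class] ROIs.
#' @slot noiseSd field noise standard deviation actually used (ppm).
#' @slot seed integer RNG seed.
#' @export
setClass("SimulatedStudy", representation(
    chiTrue = "ScalarVolume",
    field = "ScalarVolume",
    magnitude = "ScalarVolume",
    mask = "MaskVolume",
    rois = "list",
    noiseSd = "numeric",
    seed = "integer"
))

## ---------------------------------------------------------------------------
## Evaluation containers
## ---------------------------------------------------------------------------

#' Reconstruction quality report
#'
#' @slot rmse relative error norm, percent.
#' @slot hfen high-frequency error norm, percent.
#' @slot ssim mean structural similarity over the mask, in [-1, 1].
#' @slot nVoxels number of in-mask voxels evaluated.
#' @export
setClass("MetricReport", representation(
    rmse = "numeric", hfen = "numeric", ssim = "numeric",
    nVoxels = "integer"
))

setValidity("MetricReport", function(object) {
    if (object@rmse < 0 || object@hfen < 0)
        return("rmse and hfen must be non-negative")
    TRUE
})

#' ROI regression result
#'
#' Ordinary least-squares fit of per-ROI mean reconstructed susceptibility
#' against the per-ROI mean reference.
#'
#' @slot slope regression slope (1 = unbiased recovery).
#' @slot intercept intercept, ppm.
#' @slot rSquared coefficient of determination in [0, 1].
#' @slot roiMeansRecon,roiMeansRef per-ROI mean susceptibilities, ppm.
#' @export
setClass("RegressionResult", representation(
    slope = "numeric", intercept = "numeric", rSquared = "numeric",
    roiMeansRecon = "numeric", roiMeansRef = "numeric"
))

setValidity("RegressionResult", function(object) {
    if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
        return("rSquared must lie in [0, 1]")
    TRUE
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @describeIn VolumeGrid-class grid shape accessor
#' @param x object containing a grid
#' @export
gridShape <- function(x) {
    if (is(x, "VolumeGrid")) x@shape else x@grid@shape
}

#' @describeIn VolumeGrid-class voxel size accessor (mm)
#' @export
voxelSize <- function(x) {
    if (is(x, "VolumeGrid")) x@voxelSize else x@grid@voxelSize
}

#' @describeIn VolumeGrid-class B0 direction accessor (unit vector)
#' @export
b0Direction <- function(x) {
    if (is(x, "VolumeGrid")) x@b0Dir else x@grid@b0Dir
}

#' Extract the VolumeGrid of a volume-bearing object
#' @param x any object with a grid slot.
#' @return The [VolumeGrid-class].
#' @export
volumeGrid <- function(x) if (is(x, "VolumeGrid")) x else x@grid

#' Extract the value array of a scalar-valued volume object
#' @param x a ScalarVolume, MaskVolume, DataWeight or DipoleKernelK.
#' @return The underlying 3D array.
#' @export
volumeValues <- function(x) x@values

#' Extract the three component arrays of a vector-valued volume
#' @param x a VectorVolume or EdgeWeight.
#' @return Named list with elements x, y, z.
#' @export
vectorComponents <- function(x) list(x = x@x, y = x@y, z = x@z)

#' @describeIn EdgeThreshold-class threshold value accessor
#' @param x an EdgeThreshold
#' @export
thresholdValue <- function(x) x@value

#' @describeIn EdgeThreshold-class achieved boundary fraction accessor
#' @export
achievedFraction <- function(x) x@achieved

#' @describeIn SolveResult-class reconstructed susceptibility accessor
#' @param x a SolveResult
#' @export
chiMap <- function(x) x@chi

#' @describeIn SolveResult-class objective trace accessor
#' @export
objectiveTrace <- function(x) x@objectiveTrace

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
    cat(sprintf("VolumeGrid %dx%dx%d, voxel %.4gx%.4gx%.4g mm, B0 = (%.3g, %.3g, %.3g)\n",
                object@shape[1], object@shape[2], object@shape[3],
                object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
                object@b0Dir[1], object@b0Dir[2], object@b0Dir[3]))
})

setMethod("show", "ScalarVolume", function(object) {
    cat(sprintf("ScalarVolume [%s] %dx%dx%d, range [%.4g, %.4g]\n",
                object@unit, dim(object@values)[1], dim(object@values)[2],
                dim(object@values)[3], min(object@values), max(object@values)))
})

setMethod("show", "MaskVolume", function(object) {
    cat(sprintf("MaskVolume %dx%dx%d, %d voxels inside\n",
                dim(object@values)[1], dim(object@values)[2],
                dim(object@values)[3], sum(object@values)))
})

setMethod("show", "EdgeThreshold", function(object) {
    cat(sprintf("EdgeThreshold c = %.6g (target fraction %.3g, achieved %.4g)\n",
                object@value, object@fraction, object@achieved))
})

setMethod("show", "EdgeWeight", function(object) {
    cat(sprintf("EdgeWeight [%s] %dx%dx%d per axis, mean weight %.4g\n",
                object@mode, dim(object@x)[1], dim(object@x)[2],
                dim(object@x)[3], mean(c(object@x, object@y, object@z))))
})

setMethod("show", "SolverConfig", function(object) {
    cat(sprintf(paste0("SolverConfig lambda = %.4g, epsilon = %.3g, ",
                       "maxOuter = %d (tol %.3g), CG max %d (tol %.3g)\n"),
                object@lambda, object@epsilon, object@maxOuter,
                object@outerTol, object@cgMax, object@cgTol))
})

setMethod("show", "SolveResult", function(object) {
    cat(sprintf("SolveResult: %d outer iterations (%s), objective %.6g -> %.6g\n",
                object@nOuter,
                if (object@converged) "converged" else "max iterations",
                object@objectiveTrace[1],
                object@objectiveTrace[length(object@objectiveTrace)]))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %d spheres on %dx%dx%d grid\n",
                nrow(object@centers), object@grid@shape[1],
                object@grid@shape[2], object@grid@shape[3]))
    if (nrow(object@centers) > 0) {
        for (i in seq_len(nrow(object@centers)))
            cat(sprintf("  sphere %d: center (%g, %g, %g), r = %g vox, chi = %g ppm, mag = %g%s\n",
                        i, object@centers[i, 1], object@centers[i, 2],
                        object@centers[i, 3], object@radii[i], object@chi[i],
                        object@magnitudeContrasts[i],
                        if (object@edgeMismatch == i) " (edge mismatch)" else ""))
    }
})

setMethod("show", "SimulatedStudy", function(object) {
    cat(sprintf("SimulatedStudy: %d ROIs, field noise sd %.4g ppm, seed %d\n",
                length(object@rois), object@noiseSd, object@seed))
})

setMethod("show", "MetricReport", function(object) {
    cat(sprintf("MetricReport (n = %d in-mask voxels)\n  RMSE %7.2f %%\n  HFEN %7.2f %%\n  SSIM %7.4f\n",
                object@nVoxels, object@rmse, object@hfen, object@ssim))
})

setMethod("show", "RegressionResult", function(object) {
    cat(sprintf("RegressionResult: slope %.4f, intercept %.4g ppm, R^2 %.4f (%d ROIs)\n",
                object@slope, object@intercept, object@rSquared,
                length(object@roiMeansRecon)))
})

## internal: check two objects share a grid
.checkSameGrid <- function(a, b, what = "volumes") {
    ga <- volumeGrid(a); gb <- volumeGrid(b)
    if (!identical(ga@shape, gb@shape))
        stop("dimension mismatch: ", what, " live on different grids (",
             paste(ga@shape, collapse = "x"), " vs ",
             paste(gb@shape, collapse = "x"), ")")
    invisible(TRUE)
}
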