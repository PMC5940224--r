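## Synthetic gadolinium balloon phantom.
##
## Emulates the classic QSM validation object: spheres ("balloons") of
## known susceptibility embedded in a uniform gel background, imaged along
## B0.  The simulator produces the ground-truth susceptibility map, the
## forward-simulated noisy local field, a co-registered magnitude image
## whose edges coincide with (or, optionally, deliberately miss) the
## susceptibility edges, a support mask and per-sphere ROIs.

#' Default five-balloon phantom specification
#'
#' Five non-overlapping spheres with susceptibilities 0.05, 0.1, 0.2, 0.4
#' and 0.8 ppm in a zero-susceptibility background, on a 64^3 grid with
#' isotropic 1 mm voxels and B0 along +z; radii 6-8 voxels so each sphere
#' is resolved but desk-scale.  Sphere magnitude level 2 against gel level
#' 1 gives every balloon a clear magnitude edge.
#'
#' @param shape grid shape (default c(64, 64, 64)); sphere geometry scales
#'   with the grid.
#' @param edgeMismatch integer sphere index whose magnitude contrast is
#'   suppressed (edge visible in chi but not in magnitude), or 0 for none.
#' @return A [PhantomSpec-class].
#' @examples
#' defaultPhantomSpec()
#' @export
defaultPhantomSpec <- function(shape = c(64, 64, 64), edgeMismatch = 0L) {
    grid <- VolumeGrid(shape)
    s <- shape / 64                       # scale factors per axis
    centers <- rbind(
        c(18, 18, 24), c(46, 18, 24), c(18, 46, 24),
        c(46, 46, 24), c(32, 32, 44))
    centers <- sweep(centers, 2, s, "*")
    radii <- c(6, 6, 6, 7, 8) * min(s)
    new("PhantomSpec", grid = grid, centers = centers, radii = radii,
        chi = c(0.05, 0.1, 0.2, 0.4, 0.8), backgroundChi = 0,
        magnitudeContrasts = rep(2, 5), backgroundMagnitude = 1,
        edgeMismatch = as.integer(edgeMismatch))
}

#' Construct a PhantomSpec
#'
#' @param grid [VolumeGrid-class].
#' @param centers n x 3 matrix of sphere centers (voxel coordinates).
#' @param radii sphere radii in voxels (each >= 2).
#' @param chi per-sphere susceptibilities, ppm.
#' @param backgroundChi background susceptibility, ppm.
#' @param magnitudeContrasts per-sphere magnitude levels, a.u.
#' @param backgroundMagnitude background magnitude level, a.u.
#' @param edgeMismatch sphere index with suppressed magnitude contrast
#'   (0 = none).
#' @return A [PhantomSpec-class].
#' @export
PhantomSpec <- function(grid, centers, radii, chi, backgroundChi = 0,
                        magnitudeContrasts = rep(2, length(radii)),
                        backgroundMagnitude = 1, edgeMismatch = 0L) {
    new("PhantomSpec", grid = grid, centers = rbind(centers), radii = radii,
        chi = chi, backgroundChi = backgroundChi,
        magnitudeContrasts = magnitudeContrasts,
        backgroundMagnitude = backgroundMagnitude,
        edgeMismatch = as.integer(edgeMismatch))
}

## logical membership array for one sphere (center-of-voxel distance)
.sphereMembership <- function(shape, center, radius) {
    dx2 <- ((1:shape[1]) - center[1])^2
    dy2 <- ((1:shape[2]) - center[2])^2
    dz2 <- ((1:shape[3]) - center[3])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    r2 <= radius^2
}

.checkNonOverlap <- function(spec) {
    n <- nrow(spec@centers)
    if (n < 2L) return(invisible(TRUE))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        d <- sqrt(sum((spec@centers[i, ] - spec@centers[j, ])^2))
        if (d < spec@radii[i] + spec@radii[j])
            stop("spheres ", i, " and ", j, " overlap")
    }
    invisible(TRUE)
}

#' Ground-truth susceptibility map of a balloon phantom
#'
#' Piecewise-constant map: `backgroundChi` everywhere, the assigned
#' susceptibility inside each sphere; membership by center-of-voxel
#' distance.  ROI means therefore equal the assigned values exactly.
#'
#' @param spec [PhantomSpec-class] with non-overlapping spheres.
#' @return A [ScalarVolume-class] in ppm.
#' @export
makeBalloonPhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    .checkNonOverlap(spec)
    sh <- spec@grid@shape
    v <- array(spec@backgroundChi, sh)
    for (i in seq_len(nrow(spec@centers)))
        v[.sphereMembership(sh, spec@centers[i, ], spec@radii[i])] <-
            spec@chi[i]
    ScalarVolume(v, grid = spec@grid, unit = "ppm")
}

#' Co-registered magnitude image of a balloon phantom
#'
#' Piecewise-constant magnitude: background level outside the spheres and
#' the per-sphere contrast level inside, so magnitude edges coincide with
#' the susceptibility edges.  If `edgeMismatch` names a sphere,
#' that sphere takes the background level instead — an edge present in chi
#' but invisible in magnitude, emulating structures (such as putamen
#' against white matter) whose susceptibility contrast has no magnitude
#' counterpart.  Optional Gaussian noise (sd = level / magSnr, truncated at
#' zero) makes the magnitude gradients continuously distributed as in real
#' acquisitions.
#'
#' @param spec [PhantomSpec-class].
#' @param magSnr magnitude signal-to-noise ratio; `Inf` (default) for a
#'   noise-free image.
#' @param seed integer RNG seed used when `magSnr` is finite.
#' @return A [ScalarVolume-class] in a.u.
#' @export
makeMagnitude <- function(spec, magSnr = Inf, seed = 0L) {
    stopifnot(is(spec, "PhantomSpec"))
    .checkNonOverlap(spec)
    if (length(spec@magnitudeContrasts) != length(spec@radii))
        stop("magnitudeContrasts length must match the number of spheres")
    sh <- spec@grid@shape
    v <- array(spec@backgroundMagnitude, sh)
    for (i in seq_len(nrow(spec@centers))) {
        lvl <- if (spec@edgeMismatch == i) spec@backgroundMagnitude
               else spec@magnitudeContrasts[i]
        v[.sphereMembership(sh, spec@centers[i, ], spec@radii[i])] <- lvl
    }
    if (is.finite(magSnr)) {
        if (magSnr <= 0) stop("magSnr must be positive")
        noise <- .withSeed(seed,
            stats::rnorm(length(v), sd = as.numeric(v) / magSnr))
        v <- array(pmax(as.numeric(v) + noise, 0), sh)
    }
    ScalarVolume(v, grid = spec@grid, unit = "au")
}

## evaluate expr under a local RNG seed, restoring global state
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Simulate a complete phantom study
#'
#' Builds the ground truth, the support mask (a sphere comfortably
#' enclosing the balloons, emulating the gel container), the magnitude
#' image with noise, and the local field: the dipole forward model applied
#' to the truth plus Gaussian field noise with
#' `sd = max in-mask |noise-free field| / snr`, zero outside the mask.  The
#' whole study is regenerated bit-identically from the seed.
#'
#' @param spec [PhantomSpec-class].
#' @param snr field signal-to-noise ratio; `Inf` for a noiseless field.
#' @param seed integer RNG seed.
#' @param magSnr magnitude SNR (defaults to `snr` so the magnitude carries
#'   realistic continuously distributed gradients; `Inf` for a
#'   piecewise-constant magnitude).
#' @return A [SimulatedStudy-class].
#' @examples
#' study <- simulateStudy(defaultPhantomSpec(c(32, 32, 32)), snr = 50,
#'                        seed = 1)
#' @export
simulateStudy <- function(spec, snr = 50, seed = 0L, magSnr = snr) {
    stopifnot(is(spec, "PhantomSpec"))
    if (snr <= 0) stop("snr must be positive")
    chiTrue <- makeBalloonPhantom(spec)
    grid <- spec@grid
    sh <- grid@shape
    ## support mask: sphere centered on the grid enclosing all balloons
    ctr <- (sh + 1) / 2
    need <- if (nrow(spec@centers) > 0)
        max(sqrt(rowSums(sweep(spec@centers, 2, ctr)^2)) + spec@radii)
    else 0
    maskR <- min(min(sh) / 2 - 1, need + 4)
    mask <- MaskVolume(.sphereMembership(sh, ctr, max(maskR, 4)),
                       grid = grid)
    magnitude <- makeMagnitude(spec, magSnr = magSnr, seed = seed + 1L)
    kernel <- makeDipoleKernel(grid)
    clean <- forwardField(chiTrue, kernel)
    if (is.finite(snr)) {
        sd <- max(abs(clean@values[mask@values])) / snr
        noisy <- .withSeed(seed, {
            clean@values + array(stats::rnorm(prod(sh), sd = sd), sh)
        })
    } else {
        sd <- 0
        noisy <- clean@values
    }
    field <- ScalarVolume(noisy * mask@values, grid = grid, unit = "ppm")
    rois <- lapply(seq_len(nrow(spec@centers)), function(i)
        MaskVolume(.sphereMembership(sh, spec@centers[i, ], spec@radii[i]),
                   grid = grid))
    new("SimulatedStudy", chiTrue = chiTrue, field = field,
        magnitude = magnitude, mask = mask, rois = rois,
        noiseSd = sd, seed = as.integer(seed))
}
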