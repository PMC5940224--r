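## NIfTI-1 volume input/output and flat key-value run configuration.
##
## NIfTI-1 (.nii / .nii.gz) is the single on-disk volume format.  Field and
## susceptibility volumes are in ppm, magnitude in arbitrary units; voxel
## sizes travel in the header pixdim.  The B0 direction is not a NIfTI
## concept, so it defaults to the third volume axis and is overridable for
## oblique acquisitions.

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into a [ScalarVolume-class], taking voxel sizes
#' from the header.  4D (or higher) inputs and non-positive voxel sizes are
#' rejected.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param unit unit tag to attach ("ppm", "au", "dimensionless").
#' @param b0Dir main-field direction in the volume frame (default +z).
#' @return A [ScalarVolume-class].
#' @export
readVolume <- function(path, unit = "ppm", b0Dir = c(0, 0, 1)) {
    if (!file.exists(path))
        stop("input file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("expected a 3D volume, got ", length(d), "D data in ", path)
    vs <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(vs)) || any(vs <= 0))
        stop("non-positive voxel size in NIfTI header of ", path)
    grid <- VolumeGrid(d, voxelSize = vs, b0Dir = b0Dir)
    ScalarVolume(array(as.numeric(img), d), grid = grid, unit = unit)
}

#' Read a 3D NIfTI mask
#'
#' @inheritParams readVolume
#' @return A [MaskVolume-class] (nonzero voxels = inside).
#' @export
readMask <- function(path, b0Dir = c(0, 0, 1)) {
    v <- readVolume(path, unit = "dimensionless", b0Dir = b0Dir)
    MaskVolume(v@values != 0, grid = v@grid)
}

#' Write a volume to NIfTI-1
#'
#' Voxel sizes are written to the header pixdim; values are stored as
#' 64-bit floats so round-trips are exact.
#'
#' @param v a [ScalarVolume-class] or [MaskVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeVolume <- function(v, path) {
    vals <- if (is(v, "MaskVolume")) array(as.numeric(v@values), dim(v@values))
            else v@values
    vs <- voxelSize(v)
    img <- RNifti::asNifti(vals,
                           reference = list(pixdim = c(-1, vs, 1, 1, 1, 1)),
                           datatype = "double")
    RNifti::writeNifti(img, path)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Flat key-value configuration files
## ---------------------------------------------------------------------------

#' Write a run configuration as flat key = value text
#'
#' Every entry of the named list becomes one `key = value` line; vectors
#' are comma-separated.  [readRunConfig()] restores the list losslessly
#' (numbers as numerics, TRUE/FALSE as logicals, everything else as
#' character).
#'
#' @param cfg named list of scalar or vector values.
#' @param path output text file.
#' @return The path, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
    stopifnot(is.list(cfg), length(names(cfg)) == length(cfg))
    lines <- vapply(names(cfg), function(k) {
        paste0(k, " = ", paste(format(cfg[[k]], digits = 17, trim = TRUE),
                               collapse = ","))
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a flat key = value run configuration
#'
#' @param path text file written by [writeRunConfig()] (or by hand: one
#'   `key = value` per line, `#` comments allowed).
#' @return Named list; numeric-looking values become numerics, TRUE/FALSE
#'   become logicals, comma-separated values become vectors.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    cfg <- list()
    for (ln in lines) {
        m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
        if (length(m) != 3L)
            stop("malformed config line: '", ln, "'")
        key <- trimws(m[2])
        parts <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
        num <- suppressWarnings(as.numeric(parts))
        cfg[[key]] <- if (!any(is.na(num))) num
            else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
            else paste(parts, collapse = ",")
    }
    cfg
}
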