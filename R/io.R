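## NIfTI input/output for complex volumes and structured-text pipeline
## configuration.  NIfTI stores real data, so a complex volume travels as
## a file pair: magnitude + phase, or real + imaginary.  Arrays are
## indexed (x, y, z) matching the NIfTI affine; no reorientation is ever
## performed (pass-through).

.pairSuffixes <- list(magphase = c("mag", "phase"),
                      realimag = c("real", "imag"))

#' Read a complex volume from a NIfTI pair
#'
#' Phase images are interpreted as radians when their values lie within
#' \[-pi - 0.001, pi + 0.001\]; otherwise they are rescaled linearly from
#' the integer convention declared via `phaseRange` (e.g. `c(-4096, 4094)`
#' for a 12-bit scanner export), and it is an error to omit `phaseRange`
#' in that case.  Voxel size and echo time from the caller are
#' authoritative; a warning is emitted when the header voxel size
#' disagrees.
#'
#' @param paths Character vector of the two file paths, in pair order
#'   (magnitude then phase, or real then imaginary).
#' @param convention `"magphase"` or `"realimag"`.
#' @param acquisition An [AcquisitionParams-class] (authoritative source
#'   of TE and field strength).
#' @param voxelSize Optional mm-per-axis override; defaults to the NIfTI
#'   header.
#' @param phaseRange Optional length-2 numeric giving the stored phase
#'   range to map linearly onto \[-pi, pi\].
#' @return A [ComplexVolume-class].
#' @export
readComplexVolume <- function(paths, convention = c("magphase", "realimag"),
                              acquisition = acquisitionParams(),
                              voxelSize = NULL, phaseRange = NULL) {
    convention <- match.arg(convention)
    if (length(paths) != 2L) stop("expected exactly two file paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("input file not found: ", paste(missing, collapse = ", "))
    imgs <- lapply(paths, RNifti::readNifti)
    d1 <- dim(imgs[[1L]]); d2 <- dim(imgs[[2L]])
    if (!identical(d1, d2))
        stop("geometry error: the two images have different grids (",
             paste(d1, collapse = "x"), " vs ", paste(d2, collapse = "x"), ")")
    if (max(abs(RNifti::xform(imgs[[1L]]) - RNifti::xform(imgs[[2L]]))) > 1e-4)
        stop("geometry error: the two images have different affines")
    hdrVox <- RNifti::pixdim(imgs[[1L]])[1:3]
    if (is.null(voxelSize)) {
        voxelSize <- hdrVox
    } else if (max(abs(voxelSize - hdrVox)) > 1e-6) {
        warning("header voxel size (", paste(signif(hdrVox, 4), collapse = "x"),
                " mm) disagrees with the configured voxel size; ",
                "using the configured value")
    }
    a <- array(as.numeric(imgs[[1L]]), d1)
    b <- array(as.numeric(imgs[[2L]]), d1)
    if (convention == "magphase") {
        if (max(abs(b)) > pi + 1e-3) {
            if (is.null(phaseRange))
                stop("phase values exceed [-pi, pi]: declare the stored phase ",
                     "convention via 'phaseRange'")
            b <- -pi + (b - phaseRange[1L]) * 2 * pi / diff(phaseRange)
        }
        data <- a * exp(1i * b)
    } else {
        data <- complex(real = a, imaginary = b)
        dim(data) <- d1
    }
    complexVolume(data, voxelSize = voxelSize, acquisition = acquisition)
}

## write one real 3D array as NIfTI with the volume's voxel size
writeMap <- function(map, voxelSize, path) {
    img <- RNifti::asNifti(array(as.numeric(map), dim(map)))
    RNifti::pixdim(img) <- voxelSize
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Write a complex volume as a NIfTI pair
#'
#' @param volume A [ComplexVolume-class].
#' @param prefix Output path prefix; `_mag`/`_phase` (or `_real`/`_imag`)
#'   and `.nii.gz` are appended.
#' @param convention `"magphase"` or `"realimag"`.
#' @return The two file paths, invisibly.
#' @export
writeComplexVolume <- function(volume, prefix,
                               convention = c("magphase", "realimag")) {
    convention <- match.arg(convention)
    stopifnot(is(volume, "ComplexVolume"))
    suf <- .pairSuffixes[[convention]]
    paths <- paste0(prefix, "_", suf, ".nii.gz")
    S <- volume@data
    parts <- if (convention == "magphase") list(Mod(S), Arg(S))
             else list(Re(S), Im(S))
    for (i in 1:2) writeMap(array(parts[[i]], dim(S)), volume@voxelSize, paths[i])
    invisible(paths)
}
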