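## Accessor and show methods.

#' @rdname uteDixon-accessors
#' @aliases imageData,ComplexVolume-method
setMethod("imageData", "ComplexVolume", function(object) object@data)

#' @rdname uteDixon-accessors
setMethod("voxelSize", "ComplexVolume", function(object) object@voxelSize)

#' @rdname uteDixon-accessors
setMethod("acquisition", "ComplexVolume", function(object) object@acquisition)

#' @rdname uteDixon-accessors
setMethod("echoTime", "AcquisitionParams", function(object) object@echoTime)

#' @rdname uteDixon-accessors
setMethod("echoTime", "ComplexVolume", function(object) object@acquisition@echoTime)

#' @rdname uteDixon-accessors
setMethod("fieldStrength", "AcquisitionParams", function(object) object@fieldStrength)

#' @rdname uteDixon-accessors
setMethod("fieldStrength", "ComplexVolume", function(object) object@acquisition@fieldStrength)

#' @rdname uteDixon-accessors
setMethod("waterMap", "WaterFatResult", function(object) object@water)

#' @rdname uteDixon-accessors
setMethod("fatMap", "WaterFatResult", function(object) object@fat)

#' @rdname uteDixon-accessors
setMethod("fatFraction", "WaterFatResult", function(object) object@fatFraction)

#' @rdname uteDixon-accessors
setMethod("smoothPhase", "WaterFatResult", function(object) object@smoothPhase)

#' @rdname uteDixon-accessors
setMethod("correctedPhase", "WaterFatResult", function(object) object@correctedPhase)

#' @rdname uteDixon-accessors
setMethod("costTrace", "WaterFatResult", function(object) object@costTrace)

#' @rdname uteDixon-accessors
setMethod("converged", "WaterFatResult", function(object) object@converged)

#' @rdname uteDixon-accessors
setMethod("phaseMask", "SWLikeResult", function(object) object@phaseMask)

#' @rdname uteDixon-accessors
setMethod("weightedImages", "SWLikeResult", function(object) object@weighted)

#' @rdname uteDixon-accessors
setMethod("ctLikeImages", "SWLikeResult", function(object) object@ctLike)

#' @rdname uteDixon-accessors
setMethod("waterMap", "PhantomTruth", function(object) object@waterMap)

#' @rdname uteDixon-accessors
setMethod("fatMap", "PhantomTruth", function(object) object@fatMap)

#' @rdname uteDixon-accessors
setMethod("tissueLabels", "PhantomTruth", function(object) object@tissueLabels)

#' @rdname uteDixon-accessors
setMethod("labelCodes", "PhantomTruth", function(object) object@labelCodes)

setMethod("show", "AcquisitionParams", function(object) {
    cat("AcquisitionParams: TE", format(object@echoTime * 1e3), "ms,",
        "B0", format(object@fieldStrength), "T,",
        "TR", format(object@repetitionTime * 1e3), "ms,",
        "flip", format(object@flipAngle), "deg\n")
})

setMethod("show", "FatSpectrum", function(object) {
    cat("FatSpectrum with", length(object@chemicalShift), "peak(s):\n")
    for (i in seq_along(object@chemicalShift))
        cat(sprintf("  %+.2f ppm  amplitude %.4f\n",
                    object@chemicalShift[i], object@relAmplitude[i]))
})

setMethod("show", "ComplexVolume", function(object) {
    d <- dim(object@data)
    cat("ComplexVolume", paste(d, collapse = " x "), "voxels,",
        paste(format(object@voxelSize), collapse = " x "), "mm\n")
    cat("  |S| range:", format(range(Mod(object@data)), digits = 4), "\n")
    show(object@acquisition)
})

setMethod("show", "WaterFatResult", function(object) {
    cat("WaterFatResult", paste(dim(object@water), collapse = " x "), "voxels\n")
    cat("  iterations:", object@iterationsUsed,
        if (object@converged) "(converged)" else "(NOT converged)", "\n")
    cat("  final cost:", format(object@finalCost, digits = 6), "\n")
    cat("  fat fraction range:", format(range(object@fatFraction), digits = 4), "\n")
})

setMethod("show", "SWLikeResult", function(object) {
    cat("SWLikeResult with n =", paste(object@nValues, collapse = ", "), "\n")
    cat("  phase mask range:", format(range(object@phaseMask), digits = 4), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
    cat("PhantomSpec:", paste(object@gridShape, collapse = " x "), "voxels,",
        object@nVertebrae, "vertebrae\n")
    cat("  marrow fat fraction:", object@marrowFatFraction,
        "| cortical phase:", object@corticalPhaseOffset, "rad",
        "| SNR:", object@snr, "| seed:", object@seed, "\n")
    if (!is.na(object@edemaVertebraIndex))
        cat("  edema at vertebra", object@edemaVertebraIndex,
            "(fat fraction", object@edemaFatFraction, ")\n")
})

setMethod("show", "PhantomTruth", function(object) {
    cat("PhantomTruth", paste(dim(object@waterMap), collapse = " x "), "voxels\n")
    tab <- table(factor(as.vector(object@tissueLabels), levels = object@labelCodes,
                        labels = names(object@labelCodes)))
    cat("  voxels per tissue:\n")
    print(tab)
})

setMethod("show", "RatingTable", function(object) {
    cat("RatingTable:", length(object@subjects), "subjects,",
        object@scale, "scale\n")
    if (identical(object@scale, "ordinal"))
        cat("  categories:", paste(object@categories, collapse = ", "), "\n")
})
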