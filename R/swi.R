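## SWI-like processing: 0-1 phase masks from the corrected UTE phase,
## n-fold multiplication into the magnitude, and intensity inversion to a
## CT-like bone-bright contrast.
##
## Negative corrected phase marks cortical bone (local susceptibility
## phase) but also, via the chemical shift, fat-containing voxels; the
## resulting fat attenuation is an inherent property of the method, not
## suppressed here.

#' Construct SWI-like mask settings
#'
#' The mask ramps linearly from 1 at phase 0 down to 0 at
#' `negativePhaseCutoff` (the canonical negative-phase SWI mask);
#' nonnegative phase is left untouched.  The default cutoff is -pi (the
#' full negative half-range); narrower cutoffs sharpen the bone weighting.
#'
#' @param negativePhaseCutoff Phase (rad, < 0) at which the mask reaches 0.
#' @param nValues Mask powers to produce (default 1..5).
#' @param inversion `"max_minus"` or `"unit_complement"`.
#' @return A [MaskConfig-class] object.
#' @export
maskConfig <- function(negativePhaseCutoff = -pi, nValues = 1:5,
                       inversion = "max_minus") {
    if (length(negativePhaseCutoff) != 1L || !is.finite(negativePhaseCutoff) ||
        negativePhaseCutoff >= 0)
        stop("config error: 'negativePhaseCutoff' must be a negative phase in radians")
    new("MaskConfig",
        negativePhaseCutoff = as.numeric(negativePhaseCutoff),
        nValues = as.integer(nValues),
        inversion = match.arg(inversion, c("max_minus", "unit_complement")))
}

#' Build a 0-1 phase mask from the corrected phase
#'
#' \eqn{m(r) = \mathrm{clip}(1 - \varphi(r)/\varphi_{min}, 0, 1)} for
#' \eqn{\varphi(r) < 0} and 1 otherwise: the mask is 1 at phase >= 0,
#' falls linearly, and reaches 0 at \eqn{\varphi \le \varphi_{min}}.
#'
#' @param correctedPhase Phase map in (-pi, pi] (radians).
#' @param config A [MaskConfig-class].
#' @return A map in [0, 1] with the shape of `correctedPhase`.
#' @export
makePhaseMask <- function(correctedPhase, config = maskConfig()) {
    stopifnot(is(config, "MaskConfig"))
    validObject(config)
    m <- 1 - correctedPhase / config@negativePhaseCutoff
    m <- pmin(pmax(m, 0), 1)
    m[correctedPhase >= 0] <- 1
    dim(m) <- dim(correctedPhase)
    m
}

#' Multiply a phase mask into a magnitude image n times
#'
#' \eqn{S'_n = m^n \odot |S|}; `n = 0` returns the magnitude unchanged.
#'
#' @param magnitude Nonnegative magnitude map.
#' @param mask Map in [0, 1], same shape.
#' @param n Integer >= 0.
#' @return The weighted map \eqn{S'_n}.
#' @export
applyMask <- function(magnitude, mask, n) {
    if (!identical(dim(magnitude), dim(mask)))
        stop("dimension error: 'magnitude' and 'mask' must share one shape")
    if (length(n) != 1L || is.na(n) || n < 0)
        stop("domain error: 'n' must be a single integer >= 0")
    out <- mask^n * magnitude
    dim(out) <- dim(magnitude)
    out
}

#' Invert an SWI-like image to CT-like contrast
#'
#' `max_minus`: \eqn{I = \max(S') - S'}; `unit_complement`:
#' \eqn{I = 1 - S'/\max(S')}.  Either way voxels attenuated by the phase
#' mask (bone-like) become bright.  An all-zero input returns an all-zero
#' map with a warning (no division is attempted).
#'
#' @param sPrime Nonnegative weighted map \eqn{S'_n}.
#' @param config A [MaskConfig-class] selecting the inversion.
#' @return A nonnegative CT-like map.
#' @export
invertContrast <- function(sPrime, config = maskConfig()) {
    stopifnot(is(config, "MaskConfig"))
    mx <- max(sPrime)
    if (mx == 0) {
        warning("all-zero input: returning an all-zero CT-like map")
        return(sPrime)
    }
    out <- switch(config@inversion,
        max_minus = mx - sPrime,
        unit_complement = 1 - sPrime / mx)
    dim(out) <- dim(sPrime)
    out
}

#' Full SWI-like processing of a separated volume
#'
#' Builds the phase mask from the corrected phase, the weighted family
#' \eqn{S'_n} for every configured n, and their CT-like inversions.
#'
#' @param magnitude Nonnegative magnitude map of the original UTE image
#'   (raw magnitude; no bias correction is applied).
#' @param correctedPhase Corrected phase map in (-pi, pi].
#' @param config A [MaskConfig-class].
#' @return An [SWLikeResult-class].
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(32, 40, 8)))
#' res <- separate(ph$volume, config = solverConfig(maxIterations = 10))
#' sw <- swiLike(Mod(imageData(ph$volume)), correctedPhase(res))
#' sw
#' @export
swiLike <- function(magnitude, correctedPhase, config = maskConfig()) {
    stopifnot(is(config, "MaskConfig"))
    validObject(config)
    mask <- makePhaseMask(correctedPhase, config)
    nm <- paste0("n", config@nValues)
    weighted <- lapply(config@nValues, function(n) applyMask(magnitude, mask, n))
    names(weighted) <- nm
    ctLike <- lapply(weighted, invertContrast, config = config)
    names(ctLike) <- nm
    new("SWLikeResult", phaseMask = mask, weighted = weighted,
        ctLike = ctLike, nValues = config@nValues)
}
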