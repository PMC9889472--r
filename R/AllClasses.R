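## S4 class definitions and validity for the whole package.
## Constructors live in the topical files (signal_model.R, phantom.R, ...).

setClassUnion("integerOrNA", c("integer", "logical"))

#' AcquisitionParams: single-echo UTE acquisition metadata
#'
#' Holds the acquisition constants the signal model needs.  Echo time and
#' field strength enter the fat coefficient; repetition time and flip angle
#' are carried as metadata only (no T1 weighting is modelled).
#'
#' @slot echoTime Echo time in seconds (> 0).
#' @slot fieldStrength Main field strength in tesla (> 0).
#' @slot repetitionTime Repetition time in seconds (metadata only).
#' @slot flipAngle Excitation flip angle in degrees (metadata only).
#' @seealso [acquisitionParams()]
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
    representation(
        echoTime       = "numeric",
        fieldStrength  = "numeric",
        repetitionTime = "numeric",
        flipAngle      = "numeric"
    )
)

setValidity("AcquisitionParams", function(object) {
    msg <- character()
    for (s in c("echoTime", "fieldStrength", "repetitionTime", "flipAngle"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    if (length(msg)) return(msg)
    if (object@echoTime <= 0)      msg <- c(msg, "'echoTime' must be > 0")
    if (object@fieldStrength <= 0) msg <- c(msg, "'fieldStrength' must be > 0")
    if (length(msg)) msg else TRUE
})

#' FatSpectrum: multi-peak chemical-shift model of fat
#'
#' Chemical shifts are stored in ppm relative to water (fat peaks negative
#' by the water-referenced convention) and converted to Hz internally using
#' [protonGyromagneticRatio].  Relative amplitudes are nonnegative and sum
#' to one.
#'
#' @slot chemicalShift Numeric vector of peak shifts in ppm relative to water.
#' @slot relAmplitude Numeric vector of relative amplitudes (nonnegative,
#'   summing to 1 within 1e-9).
#' @seealso [fatSpectrum()], [fatCoefficient()]
#' @exportClass FatSpectrum
setClass("FatSpectrum",
    representation(
        chemicalShift = "numeric",
        relAmplitude  = "numeric"
    )
)

setValidity("FatSpectrum", function(object) {
    msg <- character()
    if (length(object@chemicalShift) < 1L)
        msg <- c(msg, "spectrum must contain at least one peak")
    if (length(object@chemicalShift) != length(object@relAmplitude))
        msg <- c(msg, "'chemicalShift' and 'relAmplitude' must have equal length")
    if (any(!is.finite(object@chemicalShift)) || any(!is.finite(object@relAmplitude)))
        msg <- c(msg, "peaks must be finite")
    if (length(msg)) return(msg)
    if (any(object@relAmplitude < 0))
        msg <- c(msg, "relative amplitudes must be nonnegative")
    if (abs(sum(object@relAmplitude) - 1) > 1e-9)
        msg <- c(msg, "relative amplitudes must sum to 1 (within 1e-9)")
    if (length(msg)) msg else TRUE
})

#' ComplexVolume: a complex 3D MR image with geometry and acquisition
#'
#' The container for the acquired single-echo UTE signal \eqn{S(r)}.  Data
#' are stored as a complex 3D array indexed (x, y, z); no reorientation is
#' performed anywhere in the package.
#'
#' @slot data 3D complex array (arbitrary units), finite everywhere.
#' @slot voxelSize Numeric length-3 vector, mm per axis, all > 0.
#' @slot acquisition An [AcquisitionParams-class] object.
#' @seealso [complexVolume()], [readComplexVolume()]
#' @exportClass ComplexVolume
setClass("ComplexVolume",
    representation(
        data        = "array",
        voxelSize   = "numeric",
        acquisition = "AcquisitionParams"
    )
)

setValidity("ComplexVolume", function(object) {
    msg <- character()
    if (!is.complex(object@data))
        msg <- c(msg, "'data' must be a complex array")
    if (length(dim(object@data)) != 3L || any(dim(object@data) < 1L))
        msg <- c(msg, "'data' must be a 3D array with all dimensions >= 1")
    if (any(!is.finite(Re(object@data))) || any(!is.finite(Im(object@data))))
        msg <- c(msg, "'data' must be finite everywhere (no NaN/Inf)")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
        msg <- c(msg, "'voxelSize' must be 3 positive values (mm)")
    if (length(msg)) msg else TRUE
})

#' SolverConfig: settings for the smoothness-constrained separation solver
#'
#' @slot smoothnessWeight Regularisation weight \eqn{\lambda \ge 0} applied
#'   to the norm of the phase-basis coefficients (polynomial basis; the
#'   low-frequency constraint itself is implicit in the basis truncation).
#' @slot maxIterations Maximum number of outer block-coordinate iterations.
#' @slot tolerance Relative cost-change threshold declaring convergence.
#' @slot phaseBasis `"polynomial"` (tensor basis truncated to total order
#'   `basisOrder`) or `"gaussian_lowpass"` (Gaussian smoothing of the
#'   magnitude-weighted complex phase residual).
#' @slot basisOrder Total polynomial order of the smooth-phase basis.
#' @slot lowpassSigma Gaussian kernel sigma in mm (gaussian_lowpass basis).
#' @slot maskQuantile Quantile of the nonzero magnitudes below which voxels
#'   are excluded from phase fitting (they are still decomposed).
#' @seealso [solverConfig()], [separate()]
#' @exportClass SolverConfig
setClass("SolverConfig",
    representation(
        smoothnessWeight = "numeric",
        maxIterations    = "integer",
        tolerance        = "numeric",
        phaseBasis       = "character",
        basisOrder       = "integer",
        lowpassSigma     = "numeric",
        maskQuantile     = "numeric"
    )
)

setValidity("SolverConfig", function(object) {
    msg <- character()
    if (object@smoothnessWeight < 0) msg <- c(msg, "'smoothnessWeight' must be >= 0")
    if (object@maxIterations < 1L)   msg <- c(msg, "'maxIterations' must be >= 1")
    if (object@tolerance <= 0)       msg <- c(msg, "'tolerance' must be > 0")
    if (!object@phaseBasis %in% c("polynomial", "gaussian_lowpass"))
        msg <- c(msg, "'phaseBasis' must be 'polynomial' or 'gaussian_lowpass'")
    if (object@basisOrder < 0L)      msg <- c(msg, "'basisOrder' must be >= 0")
    if (object@lowpassSigma <= 0)    msg <- c(msg, "'lowpassSigma' must be > 0 (mm)")
    if (object@maskQuantile < 0 || object@maskQuantile >= 1)
        msg <- c(msg, "'maskQuantile' must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' WaterFatResult: output of the water-fat separation solver
#'
#' @slot water Nonnegative water map.
#' @slot fat Nonnegative fat map.
#' @slot smoothPhase The estimated smooth (removed) low-frequency phase, rad.
#' @slot correctedPhase `Arg(S * exp(-i smoothPhase))`, in (-pi, pi].
#' @slot fatFraction `fat / (water + fat)` with 0/0 mapped to 0.
#' @slot iterationsUsed Outer iterations actually run.
#' @slot finalCost Final value of the data-plus-penalty cost.
#' @slot costTrace Cost after initialisation and after each outer iteration.
#' @slot converged TRUE if the relative cost change fell below tolerance.
#' @seealso [separate()]
#' @exportClass WaterFatResult
setClass("WaterFatResult",
    representation(
        water          = "array",
        fat            = "array",
        smoothPhase    = "array",
        correctedPhase = "array",
        fatFraction    = "array",
        iterationsUsed = "integer",
        finalCost      = "numeric",
        costTrace      = "numeric",
        converged      = "logical"
    )
)

setValidity("WaterFatResult", function(object) {
    msg <- character()
    if (any(object@water < 0))          msg <- c(msg, "'water' must be nonnegative")
    if (any(object@fat < 0))            msg <- c(msg, "'fat' must be nonnegative")
    if (any(object@fatFraction < 0) || any(object@fatFraction > 1))
        msg <- c(msg, "'fatFraction' must lie in [0, 1]")
    if (any(object@correctedPhase <= -pi - 1e-12) || any(object@correctedPhase > pi + 1e-12))
        msg <- c(msg, "'correctedPhase' must lie in (-pi, pi]")
    if (object@finalCost < 0)           msg <- c(msg, "'finalCost' must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' MaskConfig: settings for SWI-like phase masking and inversion
#'
#' @slot negativePhaseCutoff Phase \eqn{\varphi_{min} < 0} (rad) at or below
#'   which the mask reaches 0; the mask ramps linearly from 1 at phase 0.
#' @slot nValues Integer vector of mask powers n (each >= 1; default 1..5).
#' @slot inversion `"max_minus"` (I = max(S') - S') or `"unit_complement"`
#'   (I = 1 - S'/max(S')).
#' @seealso [maskConfig()], [swiLike()]
#' @exportClass MaskConfig
setClass("MaskConfig",
    representation(
        negativePhaseCutoff = "numeric",
        nValues             = "integer",
        inversion           = "character"
    )
)

setValidity("MaskConfig", function(object) {
    msg <- character()
    if (length(object@negativePhaseCutoff) != 1L ||
        !is.finite(object@negativePhaseCutoff) || object@negativePhaseCutoff >= 0)
        msg <- c(msg, "'negativePhaseCutoff' must be a finite negative scalar (rad)")
    if (length(object@nValues) < 1L || any(object@nValues < 1L))
        msg <- c(msg, "'nValues' must be a non-empty set of integers >= 1")
    if (!object@inversion %in% c("max_minus", "unit_complement"))
        msg <- c(msg, "'inversion' must be 'max_minus' or 'unit_complement'")
    if (length(msg)) msg else TRUE
})

#' SWLikeResult: phase mask, weighted magnitudes and CT-like inversions
#'
#' @slot phaseMask Map in [0, 1].
#' @slot weighted Named list of nonnegative maps S'_n = mask^n * magnitude,
#'   one per n.
#' @slot ctLike Named list of nonnegative inverted-contrast maps I_n.
#' @slot nValues The n values the lists are indexed by.
#' @seealso [swiLike()]
#' @exportClass SWLikeResult
setClass("SWLikeResult",
    representation(
        phaseMask = "array",
        weighted  = "list",
        ctLike    = "list",
        nValues   = "integer"
    )
)

setValidity("SWLikeResult", function(object) {
    msg <- character()
    if (any(object@phaseMask < 0) || any(object@phaseMask > 1))
        msg <- c(msg, "'phaseMask' must lie in [0, 1]")
    if (length(object@weighted) != length(object@nValues) ||
        length(object@ctLike) != length(object@nValues))
        msg <- c(msg, "'weighted' and 'ctLike' must have one entry per n")
    if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic spine phantom
#'
#' Describes a schematic sagittal spine slab: stacked vertebral bodies with
#' fatty marrow, a thin low-magnitude cortical shell carrying a locally
#' negative phase (the property the SWI mask exploits), water-rich discs, an
#' optional edema vertebra (reduced fat fraction, raised water), an optional
#' weakly hyperintense venous-plexus stripe, a smooth polynomial background
#' phase, and complex Gaussian noise at a given SNR.
#'
#' @slot gridShape Integer length-3 vector of voxels per axis (x, y, z).
#' @slot voxelSize mm per axis.
#' @slot nVertebrae Number of vertebral bodies stacked along y.
#' @slot marrowFatFraction Fat fraction of normal marrow, in [0, 1].
#' @slot edemaVertebraIndex 1-based index of the edema vertebra, or NA to
#'   disable edema.
#' @slot edemaFatFraction Fat fraction inside the edema marrow; must be
#'   below `marrowFatFraction` when edema is enabled.
#' @slot corticalPhaseOffset Local phase added at cortical voxels, rad,
#'   <= 0 (0 disables the local bone phase).
#' @slot corticalMagnitudeFactor Cortical magnitude relative to marrow, [0,1].
#' @slot backgroundPhaseCoeffs Coefficients of the order-2 background-phase
#'   polynomial over normalised coordinates (see [polyBasisMatrix()]).
#' @slot venousPlexusEnabled Add the venous-plexus stripe?
#' @slot venousPlexusIntensityFactor Stripe magnitude relative to marrow.
#' @slot snr Signal-to-noise ratio: mean marrow magnitude over per-channel
#'   noise sd; `Inf` for noiseless.
#' @slot seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(
        gridShape                   = "integer",
        voxelSize                   = "numeric",
        nVertebrae                  = "integer",
        marrowFatFraction           = "numeric",
        edemaVertebraIndex          = "integerOrNA",
        edemaFatFraction            = "numeric",
        corticalPhaseOffset         = "numeric",
        corticalMagnitudeFactor     = "numeric",
        backgroundPhaseCoeffs       = "numeric",
        venousPlexusEnabled         = "logical",
        venousPlexusIntensityFactor = "numeric",
        snr                         = "numeric",
        seed                        = "integer"
    )
)

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
        msg <- c(msg, "'gridShape' must give 3 dimensions, each >= 8 voxels")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "'voxelSize' must be 3 positive values (mm)")
    if (object@nVertebrae < 1L) msg <- c(msg, "'nVertebrae' must be >= 1")
    if (object@marrowFatFraction < 0 || object@marrowFatFraction > 1)
        msg <- c(msg, "'marrowFatFraction' must lie in [0, 1]")
    edemaOn <- !is.na(object@edemaVertebraIndex)
    if (edemaOn) {
        if (object@edemaFatFraction < 0 || object@edemaFatFraction > 1)
            msg <- c(msg, "'edemaFatFraction' must lie in [0, 1]")
        if (object@edemaFatFraction >= object@marrowFatFraction)
            msg <- c(msg, "'edemaFatFraction' must be below 'marrowFatFraction'")
    }
    if (object@corticalPhaseOffset > 0)
        msg <- c(msg, "'corticalPhaseOffset' must be <= 0 (bone phase is locally negative)")
    if (object@corticalMagnitudeFactor < 0 || object@corticalMagnitudeFactor > 1)
        msg <- c(msg, "'corticalMagnitudeFactor' must lie in [0, 1]")
    if (length(object@backgroundPhaseCoeffs) != 10L)
        msg <- c(msg, "'backgroundPhaseCoeffs' must have 10 values (order-2 3D polynomial)")
    if (!(object@snr > 0)) msg <- c(msg, "'snr' must be positive (Inf allowed)")
    if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground-truth maps behind a generated phantom
#'
#' @slot waterMap,fatMap Nonnegative true component maps.
#' @slot phaseBackground Smooth background phase, rad.
#' @slot phaseLocal Local (susceptibility-like) phase, rad; nonzero only at
#'   cortical voxels.
#' @slot tissueLabels Integer label array; see `labelCodes` for the coding.
#' @slot labelCodes Named integer vector mapping tissue names
#'   (background/marrow/cortex/disc/edema/plexus) to label values.
#' @seealso [generatePhantom()]
#' @exportClass PhantomTruth
setClass("PhantomTruth",
    representation(
        waterMap        = "array",
        fatMap          = "array",
        phaseBackground = "array",
        phaseLocal      = "array",
        tissueLabels    = "array",
        labelCodes      = "integer"
    )
)

setValidity("PhantomTruth", function(object) {
    msg <- character()
    if (any(object@waterMap < 0) || any(object@fatMap < 0))
        msg <- c(msg, "truth maps must be nonnegative")
    if (!all(unique(as.vector(object@tissueLabels)) %in% object@labelCodes))
        msg <- c(msg, "every voxel label must be one of 'labelCodes'")
    if (length(msg)) msg else TRUE
})

#' RatingTable: paired ratings or measurements by two readers
#'
#' @slot subjects Subject identifiers.
#' @slot raterA,raterB Paired ratings (integer categories, ordinal scale) or
#'   measurements (continuous scale), equal length >= 2.
#' @slot scale `"ordinal"` or `"continuous"`.
#' @slot categories Declared finite category set (ordinal scale only; may
#'   include categories never used by either rater).
#' @seealso [ratingTable()], [weightedKappa()], [iccAgreement()]
#' @exportClass RatingTable
setClass("RatingTable",
    representation(
        subjects   = "character",
        raterA     = "numeric",
        raterB     = "numeric",
        scale      = "character",
        categories = "numeric"
    )
)

setValidity("RatingTable", function(object) {
    msg <- character()
    n <- length(object@subjects)
    if (n < 2L) msg <- c(msg, "at least 2 subjects required")
    if (length(object@raterA) != n || length(object@raterB) != n)
        msg <- c(msg, "'raterA' and 'raterB' must match 'subjects' in length")
    if (!object@scale %in% c("ordinal", "continuous"))
        msg <- c(msg, "'scale' must be 'ordinal' or 'continuous'")
    if (identical(object@scale, "ordinal")) {
        if (length(object@categories) < 2L)
            msg <- c(msg, "ordinal scale requires at least 2 declared categories")
        if (!all(c(object@raterA, object@raterB) %in% object@categories))
            msg <- c(msg, "ordinal ratings must come from the declared category set")
    }
    if (length(msg)) msg else TRUE
})
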