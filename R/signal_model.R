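## Signal model: acquisition/spectrum constructors, the complex fat
## coefficient, and the noiseless forward model shared by the solver and
## the phantom generator.
##
## Phase convention used throughout the package: e^{+i phi}, phi in
## radians, mathematically positive rotation.

#' Construct acquisition parameters
#'
#' Defaults reproduce a 3-T single-echo UTE spine protocol: TE 0.14 ms,
#' TR 6.3 ms, flip angle 5 degrees.  TR and flip angle are metadata only.
#'
#' @param echoTime Echo time in seconds.
#' @param fieldStrength Field strength in tesla.
#' @param repetitionTime Repetition time in seconds.
#' @param flipAngle Flip angle in degrees.
#' @return An [AcquisitionParams-class] object.
#' @examples
#' acquisitionParams()                     # 3-T UTE defaults
#' acquisitionParams(echoTime = 1.2e-3)    # a longer echo
#' @export
acquisitionParams <- function(echoTime = 0.14e-3, fieldStrength = 3.0,
                              repetitionTime = 6.3e-3, flipAngle = 5) {
    new("AcquisitionParams",
        echoTime = as.numeric(echoTime),
        fieldStrength = as.numeric(fieldStrength),
        repetitionTime = as.numeric(repetitionTime),
        flipAngle = as.numeric(flipAngle))
}

#' Construct a fat chemical-shift spectrum
#'
#' The default is the minimal standard single-peak model: one methylene
#' peak at -3.4 ppm relative to water with amplitude 1.  A multi-peak
#' marrow model can be supplied instead; amplitudes must be nonnegative
#' and sum to 1.
#'
#' @param chemicalShift Peak positions in ppm relative to water (fat
#'   negative by the water-referenced convention).
#' @param relAmplitude Relative amplitudes, summing to 1.
#' @return A [FatSpectrum-class] object.
#' @examples
#' fatSpectrum()   # single peak at -3.4 ppm
#' # a two-peak toy model
#' fatSpectrum(c(-3.4, -2.6), c(0.85, 0.15))
#' @export
fatSpectrum <- function(chemicalShift = -3.4, relAmplitude = 1) {
    if (length(chemicalShift) == 0L)
        stop("invalid spectrum: at least one peak is required")
    new("FatSpectrum",
        chemicalShift = as.numeric(chemicalShift),
        relAmplitude = as.numeric(relAmplitude))
}

#' Construct a complex MR volume
#'
#' @param data A complex (or real, promoted to complex) 3D array.
#' @param voxelSize mm per axis, length 3.
#' @param acquisition An [AcquisitionParams-class] object.
#' @return A [ComplexVolume-class] object.
#' @export
complexVolume <- function(data, voxelSize = c(1, 1, 1),
                          acquisition = acquisitionParams()) {
    if (is.null(dim(data)) || length(dim(data)) != 3L)
        stop("'data' must be a 3D array")
    storage.mode(data) <- "complex"
    new("ComplexVolume", data = data, voxelSize = as.numeric(voxelSize),
        acquisition = acquisition)
}

#' Complex fat coefficient at a given echo time
#'
#' Evaluates the chemical-shift phasor of the fat signal,
#' \deqn{c = \sum_p \alpha_p \exp(i 2\pi \, \delta_p 10^{-6} \bar\gamma B_0 \, TE),}
#' where \eqn{\delta_p} are the peak shifts in ppm, \eqn{\alpha_p} the
#' relative amplitudes and \eqn{\bar\gamma B_0} the proton Larmor
#' frequency in Hz.  \eqn{|c| \le 1}, with equality iff the spectrum has a
#' single peak (or all peaks align in phase); at TE = 0, \eqn{c = 1}.
#'
#' @param spectrum A [FatSpectrum-class].
#' @param acq An [AcquisitionParams-class].
#' @return A complex scalar.
#' @examples
#' fatCoefficient(fatSpectrum(), acquisitionParams())
#' @export
fatCoefficient <- function(spectrum, acq) {
    stopifnot(is(spectrum, "FatSpectrum"), is(acq, "AcquisitionParams"))
    validObject(spectrum); validObject(acq)
    freqHz <- spectrum@chemicalShift * 1e-6 *
        protonGyromagneticRatio * acq@fieldStrength
    sum(spectrum@relAmplitude * exp(1i * 2 * pi * freqHz * acq@echoTime))
}

#' Noiseless single-echo forward signal
#'
#' Evaluates \eqn{S(r) = (W(r) + c F(r)) e^{i \varphi(r)}} elementwise.
#' This is the model the separation solver inverts; no noise, decay or T1
#' weighting is applied here.
#'
#' @param water,fat Nonnegative real maps of identical shape.
#' @param phase Real phase map in radians, same shape.
#' @param c Complex fat coefficient (see [fatCoefficient()]).
#' @return A complex array of the same shape.
#' @examples
#' c0 <- fatCoefficient(fatSpectrum(), acquisitionParams())
#' forwardSignal(array(1, c(2, 2, 1)), array(0, c(2, 2, 1)),
#'               array(0, c(2, 2, 1)), c0)
#' @export
forwardSignal <- function(water, fat, phase, c) {
    if (!identical(dim(water), dim(fat)) || !identical(dim(water), dim(phase)))
        stop("dimension error: 'water', 'fat' and 'phase' must share one shape")
    if (any(water < 0) || any(fat < 0))
        stop("domain error: 'water' and 'fat' must be nonnegative")
    out <- (water + c * fat) * exp(1i * phase)
    dim(out) <- dim(water)
    out
}
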