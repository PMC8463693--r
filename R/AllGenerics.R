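#' @include AllClasses.R
NULL

#' Accessors for polarization states
#'
#' @param object a [PolarizationState-class].
#' @return `intensity`, `azimuth` and `ellipticity` return single
#'   numbers; `stokes` returns the length-4 Stokes vector
#'   `c(S0, S1, S2, S3)`.
#' @name polarization-accessors
#' @aliases intensity azimuth ellipticity stokes
#'
#' @examples
#' s <- PolarizationState(azimuth = 30, ellipticity = 40)
#' stokes(s)
NULL

#' @rdname polarization-accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname polarization-accessors
#' @export
setGeneric("azimuth", function(object) standardGeneric("azimuth"))

#' @rdname polarization-accessors
#' @export
setGeneric("ellipticity", function(object) standardGeneric("ellipticity"))

#' @rdname polarization-accessors
#' @export
setGeneric("stokes", function(object) standardGeneric("stokes"))

#' @rdname applyRetarder
#' @export
setGeneric("applyRetarder",
           function(state, ret) standardGeneric("applyRetarder"))

#' @rdname fanState
#' @export
setGeneric("fanState",
           function(fan, wavelength) standardGeneric("fanState"))

#' @rdname generatePhantom
#' @export
setGeneric("generatePhantom", function(spec) standardGeneric("generatePhantom"))

#' @rdname renderPPMPair
#' @export
setGeneric("renderPPMPair",
           function(phantom, ...) standardGeneric("renderPPMPair"))

#' Views of a differential PPM image
#'
#' @param object a [DifferentialImage-class].
#' @return `signedDifference` returns the signed height x width x 3
#'   array; `colorView` its elementwise positive part.
#' @name differential-accessors
#' @aliases signedDifference colorView
NULL

#' @rdname differential-accessors
#' @export
setGeneric("signedDifference",
           function(object) standardGeneric("signedDifference"))

#' @rdname differential-accessors
#' @export
setGeneric("colorView", function(object) standardGeneric("colorView"))

#' @rdname toMonochrome
#' @export
setGeneric("toMonochrome", function(object) standardGeneric("toMonochrome"))
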