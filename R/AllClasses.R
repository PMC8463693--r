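#' @import methods
NULL

## ---------------------------------------------------------------------------
## Optics layer
## ---------------------------------------------------------------------------

#' Fully polarized monochromatic polarization state
#'
#' Represents fully polarized light by its intensity, the azimuth of the
#' polarization-ellipse major axis (degrees, counter-clockwise from
#' horizontal, taken modulo 180), and the ellipticity angle (degrees in
#' \eqn{[-45, 45]}; positive values are right-handed, \eqn{\pm 45}
#' circular, 0 linear).
#'
#' The azimuth of a circular state (\eqn{|\chi| = 45}) is undefined; by
#' convention it is stored as 0 so that every state has a total
#' representation.
#'
#' @slot intensity non-negative intensity (arbitrary units; the Stokes S0).
#' @slot azimuth ellipse major-axis orientation in degrees, \eqn{[0, 180)}.
#' @slot ellipticity ellipticity angle in degrees, \eqn{[-45, 45]}.
#'
#' @seealso [PolarizationState()], [stokes()], [applyRetarder()]
#' @export
setClass("PolarizationState",
  representation(
    intensity   = "numeric",
    azimuth     = "numeric",
    ellipticity = "numeric"
  )
)

setValidity("PolarizationState", function(object) {
  msg <- character()
  if (length(object@intensity) != 1L || !is.finite(object@intensity) ||
      object@intensity < 0)
    msg <- c(msg, "'intensity' must be a single non-negative finite number")
  if (length(object@azimuth) != 1L || !is.finite(object@azimuth) ||
      object@azimuth < 0 || object@azimuth >= 180)
    msg <- c(msg, "'azimuth' must be a single number in [0, 180)")
  if (length(object@ellipticity) != 1L || !is.finite(object@ellipticity) ||
      abs(object@ellipticity) > 45)
    msg <- c(msg, "'ellipticity' must be a single number in [-45, 45]")
  if (length(msg)) msg else TRUE
})

#' Spectral polarization fan
#'
#' The polychromatic polarization state generator produces, for each
#' wavelength, fully polarized light whose ellipse azimuth is a linear
#' function of the wavelength, sweeping 180 degrees across the visible
#' range, at a common ellipticity angle.  The `offset` slot (0 or 90
#' degrees) selects one of the two complementary fans used for the
#' image pair.
#'
#' @slot lambdaMin,lambdaMax wavelength range in nm.
#' @slot ellipticity common ellipticity angle in degrees.
#' @slot offset fan rotation in degrees, one of 0 or 90.
#' @slot nSamples number of spectral samples on the regular grid.
#'
#' @seealso [SpectralFan()], [fanState()], [renderPixel()]
#' @export
setClass("SpectralFan",
  representation(
    lambdaMin   = "numeric",
    lambdaMax   = "numeric",
    ellipticity = "numeric",
    offset      = "numeric",
    nSamples    = "integer"
  )
)

setValidity("SpectralFan", function(object) {
  msg <- character()
  if (!(object@lambdaMin < object@lambdaMax))
    msg <- c(msg, "'lambdaMin' must be strictly less than 'lambdaMax'")
  if (abs(object@ellipticity) > 45)
    msg <- c(msg, "'ellipticity' must lie in [-45, 45]")
  if (!object@offset %in% c(0, 90))
    msg <- c(msg, "'offset' must be 0 or 90 degrees")
  if (object@nSamples < 2L)
    msg <- c(msg, "'nSamples' must be at least 2")
  if (length(msg)) msg else TRUE
})

#' Linear retarder
#'
#' A birefringent element characterized by its retardance (the phase
#' delay between the fast- and slow-axis field components, degrees) and
#' the orientation of its fast axis.  Zero retardance is the identity.
#'
#' @slot retardance phase retardance in degrees, non-negative.
#' @slot fastAxis fast-axis orientation in degrees, \eqn{[0, 180)}.
#'
#' @seealso [Retarder()], [applyRetarder()]
#' @export
setClass("Retarder",
  representation(retardance = "numeric", fastAxis = "numeric")
)

setValidity("Retarder", function(object) {
  msg <- character()
  if (length(object@retardance) != 1L || !is.finite(object@retardance) ||
      object@retardance < 0)
    msg <- c(msg, "'retardance' must be a single non-negative number")
  if (length(object@fastAxis) != 1L || !is.finite(object@fastAxis) ||
      object@fastAxis < 0 || object@fastAxis >= 180)
    msg <- c(msg, "'fastAxis' must be a single number in [0, 180)")
  if (length(msg)) msg else TRUE
})

#' Spectral camera model
#'
#' Three spectral sensitivity curves (R, G, B) sampled on the same
#' wavelength grid as a [SpectralFan-class], together with the
#' illuminant spectrum.  Each sensitivity curve is normalized to
#' integrate to one on the grid (trapezoidal rule), so that a spectrally
#' flat transmitted spectrum under a flat illuminant renders as a
#' neutral (equal-channel) gray.
#'
#' @slot wavelengths wavelength grid in nm.
#' @slot sensitivities numeric matrix, `length(wavelengths)` x 3,
#'   columns R, G, B; non-negative, each integrating to 1.
#' @slot illuminant illuminant spectral power on the same grid.
#'
#' @seealso [CameraModel()], [gaussianCamera()], [renderPixel()]
#' @export
setClass("CameraModel",
  representation(
    wavelengths   = "numeric",
    sensitivities = "matrix",
    illuminant    = "numeric"
  )
)

setValidity("CameraModel", function(object) {
  msg <- character()
  n <- length(object@wavelengths)
  if (n < 2L)
    msg <- c(msg, "need at least 2 wavelength samples")
  if (!identical(dim(object@sensitivities), c(n, 3L)))
    msg <- c(msg, "'sensitivities' must be a length(wavelengths) x 3 matrix")
  else {
    if (any(object@sensitivities < 0))
      msg <- c(msg, "sensitivities must be non-negative")
    ints <- apply(object@sensitivities, 2L, trapz, x = object@wavelengths)
    if (any(abs(ints - 1) > 1e-8))
      msg <- c(msg, "each sensitivity curve must integrate to 1 on the grid")
  }
  if (length(object@illuminant) != n)
    msg <- c(msg, "'illuminant' must match the wavelength grid")
  else if (any(object@illuminant < 0))
    msg <- c(msg, "'illuminant' must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Phantom layer
## ---------------------------------------------------------------------------

#' Specification of a synthetic fiber phantom
#'
#' Parameters for the seeded generator of fibrillar-collagen phantoms:
#' image geometry, the number and thickness of fibers, their
#' orientation distribution (axial von Mises, i.e. von Mises on doubled
#' angles), an optional sinusoidal curvature, per-fiber retardance, an
#' absorbing H&E-like background stain, a camera white-balance tint,
#' and additive Gaussian noise.
#'
#' @slot height,width image dimensions in pixels.
#' @slot nFibers number of fibers.
#' @slot thicknessRange two-element range of fiber thickness in pixels.
#' @slot lengthRange two-element range of fiber length in pixels.
#' @slot meanOrientation mean fiber orientation in degrees, \eqn{[0,180)}.
#' @slot kappa von Mises concentration on doubled angles; 0 = uniform,
#'   `Inf` = all fibers at `meanOrientation`.
#' @slot curveAmplitude sinusoidal centerline displacement amplitude in
#'   pixels; 0 gives straight fibers.
#' @slot curvePeriod sinusoidal period along the fiber in pixels.
#' @slot retardance per-fiber retardance in degrees.
#' @slot stainAbsorbance RGB absorbance triple of the background stain
#'   (Beer-Lambert exponents; transmittance is `exp(-A)`).
#' @slot cameraTint multiplicative RGB gain triple emulating an
#'   uncorrected camera white balance.
#' @slot noiseSd standard deviation of additive Gaussian noise on
#'   [0, 1]-scaled intensities, applied after rendering.
#' @slot seed integer seed; the phantom and its rendering are
#'   deterministic functions of the spec.
#'
#' @seealso [PhantomSpec()], [generatePhantom()], [renderPPMPair()]
#' @export
setClass("PhantomSpec",
  representation(
    height          = "integer",
    width           = "integer",
    nFibers         = "integer",
    thicknessRange  = "numeric",
    lengthRange     = "numeric",
    meanOrientation = "numeric",
    kappa           = "numeric",
    curveAmplitude  = "numeric",
    curvePeriod     = "numeric",
    retardance      = "numeric",
    stainAbsorbance = "numeric",
    cameraTint      = "numeric",
    noiseSd         = "numeric",
    seed            = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@height < 1L || object@width < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (object@nFibers < 0L)
    msg <- c(msg, "'nFibers' must be non-negative")
  if (length(object@thicknessRange) != 2L ||
      any(object@thicknessRange <= 0) ||
      diff(object@thicknessRange) < 0)
    msg <- c(msg, "'thicknessRange' must be an increasing positive pair")
  if (length(object@lengthRange) != 2L ||
      any(object@lengthRange <= 0) || diff(object@lengthRange) < 0)
    msg <- c(msg, "'lengthRange' must be an increasing positive pair")
  if (object@meanOrientation < 0 || object@meanOrientation >= 180)
    msg <- c(msg, "'meanOrientation' must lie in [0, 180)")
  if (object@kappa < 0)
    msg <- c(msg, "'kappa' must be non-negative")
  if (object@curveAmplitude < 0)
    msg <- c(msg, "'curveAmplitude' must be non-negative")
  if (object@curvePeriod <= 0)
    msg <- c(msg, "'curvePeriod' must be positive")
  if (object@retardance < 0)
    msg <- c(msg, "'retardance' must be non-negative")
  if (length(object@stainAbsorbance) != 3L || any(object@stainAbsorbance < 0))
    msg <- c(msg, "'stainAbsorbance' must be a non-negative RGB triple")
  if (length(object@cameraTint) != 3L || any(object@cameraTint <= 0))
    msg <- c(msg, "'cameraTint' must be a positive RGB triple")
  if (object@noiseSd < 0)
    msg <- c(msg, "'noiseSd' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Synthetic fiber phantom with ground truth
#'
#' Co-registered rasters describing a synthetic specimen: per-pixel
#' retardance (degrees), slow-axis orientation (degrees, only defined
#' where retardance is positive), fiber density in [0, 1], and an RGB
#' stain-absorbance raster; plus the per-fiber ground-truth records.
#'
#' @slot retardanceMap numeric matrix (height x width), degrees.
#' @slot axisMap numeric matrix of local fiber orientations in degrees;
#'   `NA` where no fiber is present.
#' @slot densityMap numeric matrix in [0, 1].
#' @slot stainMap numeric array height x width x 3 of RGB absorbances.
#' @slot fiberRecords data.frame with one row per fiber: `fiber`,
#'   `orientation` (degrees), `thickness` (px), `length` (px),
#'   `retardance` (degrees), `x0`, `y0` (centerline midpoint, image
#'   coordinates).
#' @slot spec the generating [PhantomSpec-class].
#'
#' @seealso [generatePhantom()], [renderPPMPair()]
#' @export
setClass("Phantom",
  representation(
    retardanceMap = "matrix",
    axisMap       = "matrix",
    densityMap    = "matrix",
    stainMap      = "array",
    fiberRecords  = "data.frame",
    spec          = "PhantomSpec"
  )
)

setValidity("Phantom", function(object) {
  msg <- character()
  d <- dim(object@retardanceMap)
  if (!identical(dim(object@axisMap), d) ||
      !identical(dim(object@densityMap), d))
    msg <- c(msg, "retardance, axis and density maps must share dimensions")
  if (!identical(dim(object@stainMap), c(d, 3L)))
    msg <- c(msg, "'stainMap' must be height x width x 3")
  if (any(object@retardanceMap < 0))
    msg <- c(msg, "retardance must be non-negative")
  fib <- object@retardanceMap > 0
  if (any(fib & !is.finite(object@axisMap)))
    msg <- c(msg, "axis map must be finite wherever retardance > 0")
  if (any(object@densityMap < 0 | object@densityMap > 1))
    msg <- c(msg, "density map must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Pipeline layer
## ---------------------------------------------------------------------------

#' Differential PPM image
#'
#' The signed per-channel difference of the two complementary PPM
#' images (fan offsets 0 and 90 degrees).  Non-birefringent structures
#' (including stain colour) cancel; birefringent structures survive as
#' signed colour.  The colour view is the positive part; the monochrome
#' view is the Rec.709 luminance of the per-channel absolute
#' difference.
#'
#' @slot signed numeric array height x width x 3 of signed differences.
#'
#' @seealso [differentialImage()], [colorView()], [toMonochrome()]
#' @export
setClass("DifferentialImage", representation(signed = "array"))

setValidity("DifferentialImage", function(object) {
  d <- dim(object@signed)
  if (length(d) != 3L || d[3L] != 3L)
    return("'signed' must be a height x width x 3 array")
  if (!all(is.finite(object@signed)))
    return("'signed' must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## Fiber metrics layer
## ---------------------------------------------------------------------------

#' Non-overlapping block tiling of an image
#'
#' Square blocks of a fixed size tiling an image from the top-left
#' corner, row-major, 0-based origins, half-open extents.  Partial edge
#' blocks are dropped so that all block statistics are computed over
#' the same area.
#'
#' @slot imageDim integer height, width of the tiled image.
#' @slot blockSize block edge length in pixels.
#' @slot origins integer matrix with columns `row`, `col`: the 0-based
#'   top-left corner of each block, row-major order.
#'
#' @seealso [tileBlocks()], [selectRois()], [blockMetrics()]
#' @export
setClass("BlockGrid",
  representation(
    imageDim  = "integer",
    blockSize = "integer",
    origins   = "matrix"
  )
)

setValidity("BlockGrid", function(object) {
  msg <- character()
  if (object@blockSize < 1L)
    msg <- c(msg, "'blockSize' must be positive")
  if (ncol(object@origins) != 2L)
    msg <- c(msg, "'origins' must have two columns (row, col)")
  else if (nrow(object@origins)) {
    if (any(object@origins < 0L))
      msg <- c(msg, "origins must be non-negative")
    if (any(object@origins[, 1L] + object@blockSize > object@imageDim[1L]) ||
        any(object@origins[, 2L] + object@blockSize > object@imageDim[2L]))
      msg <- c(msg, "blocks must fit inside the image")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Agreement layer
## ---------------------------------------------------------------------------

#' Bland-Altman method-agreement summary
#'
#' Summary of paired differences between two measurement methods: the
#' bias (mean difference), the sample standard deviation of the
#' differences, the limits of agreement `bias +/- 1.96 * sd`, and the
#' fraction of differences falling within those limits.  Per-pair means
#' and differences are retained for plotting.
#'
#' @slot n number of pairs.
#' @slot bias mean of the differences `x - y`.
#' @slot sd sample (n-1) standard deviation of the differences.
#' @slot loaLow,loaHigh lower and upper limits of agreement.
#' @slot fractionWithin fraction of differences inside `[loaLow, loaHigh]`.
#' @slot means per-pair means `(x + y) / 2` (plot abscissa).
#' @slot differences per-pair differences `x - y`.
#'
#' @seealso [blandAltman()], [baPlot()], [biasConfint()]
#' @export
setClass("BlandAltmanResult",
  representation(
    n              = "integer",
    bias           = "numeric",
    sd             = "numeric",
    loaLow         = "numeric",
    loaHigh        = "numeric",
    fractionWithin = "numeric",
    means          = "numeric",
    differences    = "numeric"
  )
)

setValidity("BlandAltmanResult", function(object) {
  msg <- character()
  if (object@n < 2L)
    msg <- c(msg, "'n' must be at least 2")
  if (object@loaHigh < object@loaLow)
    msg <- c(msg, "'loaHigh' must be >= 'loaLow'")
  if (object@fractionWithin < 0 || object@fractionWithin > 1)
    msg <- c(msg, "'fractionWithin' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
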