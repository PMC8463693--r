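#' @include AllGenerics.R
NULL

## degrees <-> radians helpers used throughout
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## trapezoidal integration on an arbitrary grid
trapz <- function(y, x) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

## trapezoid quadrature weights for a grid (so integrals vectorize)
trapzWeights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1L] <- dx[1L] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-1L] + dx[-(n - 1L)]) / 2
  w
}

#' Construct a polarization state
#'
#' @param intensity non-negative intensity (Stokes S0); default 1.
#' @param azimuth ellipse azimuth in degrees; reduced modulo 180.
#' @param ellipticity ellipticity angle in degrees, in \eqn{[-45, 45]};
#'   positive values are right-handed.
#' @return a [PolarizationState-class].
#'
#' @details For a circular state (`abs(ellipticity) == 45`) the azimuth
#' is undefined and stored as 0.
#'
#' @examples
#' PolarizationState(azimuth = 10, ellipticity = 40)
#' @export
PolarizationState <- function(intensity = 1, azimuth = 0, ellipticity = 0) {
  azimuth <- azimuth %% 180
  if (abs(abs(ellipticity) - 45) < 1e-12) azimuth <- 0
  new("PolarizationState", intensity = as.numeric(intensity),
      azimuth = as.numeric(azimuth), ellipticity = as.numeric(ellipticity))
}

#' @rdname polarization-accessors
#' @export
setMethod("intensity", "PolarizationState", function(object) object@intensity)

#' @rdname polarization-accessors
#' @export
setMethod("azimuth", "PolarizationState", function(object) object@azimuth)

#' @rdname polarization-accessors
#' @export
setMethod("ellipticity", "PolarizationState",
          function(object) object@ellipticity)

#' @rdname polarization-accessors
#' @export
setMethod("stokes", "PolarizationState", function(object) {
  chi2 <- deg2rad(2 * object@ellipticity)
  th2 <- deg2rad(2 * object@azimuth)
  s0 <- object@intensity
  c(S0 = s0,
    S1 = s0 * cos(chi2) * cos(th2),
    S2 = s0 * cos(chi2) * sin(th2),
    S3 = s0 * sin(chi2))
})

## inverse of stokes(): build a state from a fully polarized Stokes vector
stateFromStokes <- function(s) {
  s0 <- s[1L]
  chi <- rad2deg(asin(max(-1, min(1, s[4L] / s0)))) / 2
  if (abs(abs(chi) - 45) < 1e-9) {
    theta <- 0  # azimuth undefined for circular light
  } else {
    theta <- (rad2deg(atan2(s[3L], s[2L])) / 2) %% 180
  }
  PolarizationState(intensity = s0, azimuth = theta, ellipticity = chi)
}

setMethod("show", "PolarizationState", function(object) {
  cat(sprintf(
    "PolarizationState: I = %.4g, azimuth = %.3f deg, ellipticity = %+.3f deg (%s)\n",
    object@intensity, object@azimuth, object@ellipticity,
    if (object@ellipticity > 0) "right-handed"
    else if (object@ellipticity < 0) "left-handed" else "linear"))
})

#' Construct a spectral polarization fan
#'
#' @param lambdaMin,lambdaMax wavelength range in nm (default 400-700).
#' @param ellipticity common ellipticity angle in degrees (default +40,
#'   right-handed).
#' @param offset fan rotation in degrees, 0 or 90; the two values give
#'   the complementary image pair.
#' @param nSamples number of samples on the regular spectral grid
#'   (default 31, i.e. 10 nm spacing over the default range).
#' @return a [SpectralFan-class].
#'
#' @examples
#' fan <- SpectralFan()
#' fanState(fan, 550)
#' @export
SpectralFan <- function(lambdaMin = 400, lambdaMax = 700, ellipticity = 40,
                        offset = 0, nSamples = 31L) {
  new("SpectralFan", lambdaMin = as.numeric(lambdaMin),
      lambdaMax = as.numeric(lambdaMax), ellipticity = as.numeric(ellipticity),
      offset = as.numeric(offset), nSamples = as.integer(nSamples))
}

setMethod("show", "SpectralFan", function(object) {
  cat(sprintf(
    "SpectralFan: %g-%g nm (%d samples), ellipticity %+g deg, offset %g deg\n",
    object@lambdaMin, object@lambdaMax, object@nSamples,
    object@ellipticity, object@offset))
})

#' Wavelength grid of a spectral fan
#'
#' @param fan a [SpectralFan-class].
#' @return numeric vector of `nSamples` equally spaced wavelengths.
#' @export
fanWavelengths <- function(fan) {
  seq(fan@lambdaMin, fan@lambdaMax, length.out = fan@nSamples)
}

## azimuth (deg) of the fan ellipse at given wavelengths, vectorized
fanAzimuth <- function(fan, wavelength) {
  frac <- (wavelength - fan@lambdaMin) / (fan@lambdaMax - fan@lambdaMin)
  (fan@offset + 180 * frac) %% 180
}

#' Polarization state emitted by the fan at one wavelength
#'
#' The fan maps wavelength linearly onto ellipse azimuth, sweeping 180
#' degrees over its spectral range (plus the fan offset, modulo 180),
#' at the fan's common ellipticity and unit intensity.
#'
#' @param fan a [SpectralFan-class].
#' @param wavelength wavelength in nm, inside the fan range.
#' @return a unit-intensity [PolarizationState-class].
#'
#' @examples
#' fanState(SpectralFan(), 400)  # azimuth 0
#' fanState(SpectralFan(), 550)  # azimuth 90
#' @rdname fanState
#' @export
setMethod("fanState", "SpectralFan", function(fan, wavelength) {
  if (wavelength < fan@lambdaMin || wavelength > fan@lambdaMax)
    stop("wavelength ", wavelength, " nm outside fan range [",
         fan@lambdaMin, ", ", fan@lambdaMax, "]")
  PolarizationState(intensity = 1, azimuth = fanAzimuth(fan, wavelength),
                    ellipticity = fan@ellipticity)
})

#' Construct a linear retarder
#'
#' @param retardance phase retardance in degrees (>= 0).
#' @param fastAxis fast-axis orientation in degrees; reduced modulo 180.
#' @return a [Retarder-class].
#'
#' @examples
#' Retarder(10, 45)
#' @export
Retarder <- function(retardance = 0, fastAxis = 0) {
  new("Retarder", retardance = as.numeric(retardance),
      fastAxis = as.numeric(fastAxis %% 180))
}

setMethod("show", "Retarder", function(object) {
  cat(sprintf("Retarder: retardance %g deg, fast axis %g deg\n",
              object@retardance, object@fastAxis))
})

#' Propagate a polarization state through a linear retarder
#'
#' On the Poincare sphere a retarder of retardance \eqn{\delta} with
#' fast axis \eqn{\alpha} rotates the Stokes vector by \eqn{\delta}
#' about the equatorial axis at longitude \eqn{2\alpha}.  The rotation
#' sense follows the convention in which a quarter-wave retarder at 45
#' degrees turns horizontal linear light into right-circular light;
#' intensity (S0) is unchanged.
#'
#' @param state a [PolarizationState-class].
#' @param ret a [Retarder-class].
#' @return the transformed [PolarizationState-class].
#'
#' @examples
#' # a 10-degree retarder at 45 degrees pushes a +40-degree elliptical
#' # state with azimuth 0 all the way to circular (+45)
#' applyRetarder(PolarizationState(azimuth = 0, ellipticity = 40),
#'               Retarder(10, 45))
#' @rdname applyRetarder
#' @export
setMethod("applyRetarder", signature("PolarizationState", "Retarder"),
  function(state, ret) {
    s <- stokes(state)
    v <- s[2:4]
    delta <- deg2rad(ret@retardance)
    a2 <- deg2rad(2 * ret@fastAxis)
    a <- c(cos(a2), sin(a2), 0)
    ## Rodrigues rotation of v by -delta about a (fast-axis convention)
    axv <- c(a[2L] * v[3L] - a[3L] * v[2L],
             a[3L] * v[1L] - a[1L] * v[3L],
             a[1L] * v[2L] - a[2L] * v[1L])
    vr <- cos(delta) * v - sin(delta) * axv +
      (1 - cos(delta)) * sum(a * v) * a
    stateFromStokes(c(s[1L], vr))
  })

#' Intensity transmission through an achromatic circular analyzer
#'
#' For fully polarized light of ellipticity angle \eqn{\chi} the left
#' circular analyzer transmits \eqn{(1 - \sin 2\chi)/2} and the right
#' one \eqn{(1 + \sin 2\chi)/2}; the two always sum to one.  A
#' right-circular state (\eqn{\chi = +45}) is extinguished completely
#' by the left analyzer.
#'
#' @param state a [PolarizationState-class].
#' @param handedness `"left"` or `"right"`.
#' @return transmitted intensity fraction in [0, 1].
#'
#' @examples
#' analyzerTransmission(PolarizationState(ellipticity = 45), "left")   # 0
#' analyzerTransmission(PolarizationState(ellipticity = 40), "left")
#' @export
analyzerTransmission <- function(state, handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  s3 <- sin(deg2rad(2 * ellipticity(state)))
  if (handedness == "left") (1 - s3) / 2 else (1 + s3) / 2
}

#' Construct a camera model
#'
#' @param wavelengths wavelength grid in nm.
#' @param sensitivities length(wavelengths) x 3 matrix of non-negative
#'   R, G, B sensitivities; each column is renormalized to integrate to
#'   one on the grid.
#' @param illuminant illuminant spectrum on the grid; default flat.
#' @return a [CameraModel-class].
#' @seealso [gaussianCamera()] for the default Gaussian-band model.
#' @export
CameraModel <- function(wavelengths, sensitivities,
                        illuminant = rep(1, length(wavelengths))) {
  sensitivities <- as.matrix(sensitivities)
  ints <- apply(sensitivities, 2L, trapz, x = wavelengths)
  if (any(ints <= 0)) stop("each sensitivity curve must have positive area")
  sensitivities <- sweep(sensitivities, 2L, ints, "/")
  colnames(sensitivities) <- c("R", "G", "B")
  new("CameraModel", wavelengths = as.numeric(wavelengths),
      sensitivities = sensitivities, illuminant = as.numeric(illuminant))
}

#' Gaussian-band RGB camera on a fan's spectral grid
#'
#' Convenience constructor: three Gaussian sensitivity bands on the
#' wavelength grid of a [SpectralFan-class], with a flat illuminant.
#' The default centers (650/550/450 nm, sigma 30 nm) are spaced evenly
#' across the fan's spectral range, so the three channels sample fan
#' azimuths 120 degrees apart on the doubled-angle circle; this makes
#' the hue of the differential image injective in fiber orientation
#' over the full 180-degree range (unevenly spaced bands leave arcs of
#' orientation in which only one channel survives rectification, and
#' distinct orientations then share one hue).
#'
#' @param fan the [SpectralFan-class] whose grid the camera samples.
#' @param centers RGB band centers in nm.
#' @param sigma common band standard deviation in nm.
#' @return a [CameraModel-class].
#'
#' @examples
#' gaussianCamera(SpectralFan())
#' @export
gaussianCamera <- function(fan, centers = c(650, 550, 450), sigma = 30) {
  wl <- fanWavelengths(fan)
  sens <- vapply(centers, function(mu) exp(-((wl - mu)^2) / (2 * sigma^2)),
                 numeric(length(wl)))
  CameraModel(wl, sens)
}

setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel: %d samples over %g-%g nm\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths)))
})

## ---------------------------------------------------------------------------
## Vectorized spectral rendering core
##
## For fan ellipticity chi and a pixelwise retarder field (delta, alpha),
## the left-analyzer transmission at wavelength lambda is
##   T = (1 - S3') / 2,
##   S3' = cos(delta) sin(2 chi) - sin(delta) cos(2 chi) sin(2 theta(lambda)
##         - 2 alpha)
## which follows from the Poincare rotation used in applyRetarder.
## ---------------------------------------------------------------------------

## Render a retarder field (vectors delta, alpha in degrees) to linear RGB.
## Returns an n x 3 matrix; grayLevel sets the channel value of a
## zero-retardance pixel.
renderField <- function(fan, camera, delta, alpha, grayLevel = 0.2) {
  wl <- fanWavelengths(fan)
  if (length(camera@wavelengths) != length(wl) ||
      max(abs(camera@wavelengths - wl)) > 1e-9)
    stop("camera spectral grid does not match the fan grid")
  chi2 <- deg2rad(2 * fan@ellipticity)
  th2 <- deg2rad(2 * fanAzimuth(fan, wl))      # length nw
  d <- deg2rad(delta)                          # length np
  a2 <- deg2rad(2 * (alpha %% 180))
  ## T matrix: np x nw
  s3p <- outer(cos(d) * sin(chi2), rep(1, length(wl))) -
    (sin(d) * cos(chi2)) * sin(outer(-a2, th2, "+"))
  tr <- (1 - s3p) / 2
  w <- trapzWeights(wl) * camera@illuminant
  raw <- tr %*% (w * camera@sensitivities)     # np x 3
  ## neutral normalization: a zero-retardance pixel has flat transmission
  t0 <- (1 - sin(chi2)) / 2
  neutral <- as.numeric(t0 * crossprod(w, camera@sensitivities))
  out <- sweep(raw, 2L, neutral, "/") * grayLevel
  colnames(out) <- c("R", "G", "B")
  out
}

#' Render the PPM colour of a single birefringent pixel
#'
#' Sends every fan wavelength through the local retarder and the left
#' circular analyzer, then integrates the transmitted spectrum
#' (weighted by the illuminant) against the camera's R, G, B
#' sensitivity curves.  Channels are normalized so that a
#' zero-retardance pixel renders as a neutral gray of value
#' `grayLevel` in all three channels.
#'
#' @param fan a [SpectralFan-class].
#' @param sample the local [Retarder-class] (the birefringent particle).
#' @param camera a [CameraModel-class] on the fan's grid.
#' @param grayLevel neutral background level in [0, 1]; default 0.2.
#' @return named RGB triple (linear values; may exceed `grayLevel`
#'   where transmission is enhanced).
#'
#' @examples
#' fan <- SpectralFan()
#' cam <- gaussianCamera(fan)
#' renderPixel(fan, Retarder(10, 45), cam)  # mostly green
#' renderPixel(SpectralFan(offset = 90), Retarder(10, 45), cam)  # mostly red
#' @export
renderPixel <- function(fan, sample, camera, grayLevel = 0.2) {
  drop(renderField(fan, camera, sample@retardance, sample@fastAxis,
                   grayLevel = grayLevel))
}
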