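#' @include optics.R
NULL

#' Construct a phantom specification
#'
#' @param height,width image dimensions in pixels.
#' @param nFibers number of fibers (default 50).
#' @param thicknessRange min/max fiber thickness in pixels.
#' @param lengthRange min/max fiber length in pixels; fibers are finite
#'   segments, as collagen fibers in tissue are.
#' @param meanOrientation mean fiber orientation in degrees.
#' @param kappa axial von Mises concentration (on doubled angles);
#'   0 gives a uniform orientation distribution, `Inf` puts every fiber
#'   exactly at `meanOrientation`.
#' @param curveAmplitude,curvePeriod sinusoidal centerline modulation
#'   (amplitude 0 = straight fibers).
#' @param retardance per-fiber retardance in degrees (default 10).
#' @param stainAbsorbance RGB absorbance of the background stain; the
#'   default emulates an eosin-like pink (strongest absorption in
#'   green).
#' @param cameraTint multiplicative RGB gains emulating an uncorrected
#'   camera white balance (default neutral).
#' @param noiseSd additive Gaussian noise SD on [0, 1] intensities
#'   (default 0).
#' @param seed integer seed making the phantom deterministic.
#' @return a [PhantomSpec-class].
#'
#' @examples
#' PhantomSpec(256, 256, nFibers = 20, kappa = Inf, meanOrientation = 30)
#' @export
PhantomSpec <- function(height, width, nFibers = 50L,
                        thicknessRange = c(2, 4),
                        lengthRange = c(100, 200), meanOrientation = 90,
                        kappa = 0, curveAmplitude = 0, curvePeriod = 128,
                        retardance = 10,
                        stainAbsorbance = c(0.08, 0.35, 0.18),
                        cameraTint = c(1, 1, 1), noiseSd = 0, seed = 1L) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      nFibers = as.integer(nFibers),
      thicknessRange = as.numeric(thicknessRange),
      lengthRange = as.numeric(lengthRange),
      meanOrientation = as.numeric(meanOrientation %% 180),
      kappa = as.numeric(kappa), curveAmplitude = as.numeric(curveAmplitude),
      curvePeriod = as.numeric(curvePeriod), retardance = as.numeric(retardance),
      stainAbsorbance = as.numeric(stainAbsorbance),
      cameraTint = as.numeric(cameraTint), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Canonical phantom conditions for parameter-recovery studies
#'
#' A fixed set of phantom conditions used throughout the package's
#' orientation- and alignment-recovery experiments: a 512 x 512 pixel
#' field (four 256-pixel analysis blocks) holding 600 finite fibers of
#' thickness 1-1.8 px and length 60-120 px at 10 degrees retardance,
#' i.e. a moderately dense stroma-like field (about 35-40 percent fiber
#' coverage) in which each block samples well over a hundred fibers.
#' Only the orientation distribution and the seed vary between
#' experiments.
#'
#' @param kappa axial von Mises concentration.
#' @param meanOrientation mean fiber orientation in degrees.
#' @param seed integer seed.
#' @param noiseSd additive Gaussian noise SD (default 0).
#' @return a [PhantomSpec-class].
#'
#' @examples
#' fiberStudySpec(kappa = Inf, meanOrientation = 30, seed = 5)
#' @export
fiberStudySpec <- function(kappa = 0, meanOrientation = 90, seed = 1L,
                           noiseSd = 0) {
  PhantomSpec(512, 512, nFibers = 600L, thicknessRange = c(1, 1.8),
              lengthRange = c(60, 120), meanOrientation = meanOrientation,
              kappa = kappa, retardance = 10, noiseSd = noiseSd,
              seed = seed)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d px, %d fibers, mean orientation %g deg (kappa %s)\n",
    object@height, object@width, object@nFibers, object@meanOrientation,
    format(object@kappa)))
  cat(sprintf("  retardance %g deg, curvature A=%g P=%g px, noise sd %g, seed %d\n",
              object@retardance, object@curveAmplitude, object@curvePeriod,
              object@noiseSd, object@seed))
})

## ---------------------------------------------------------------------------
## von Mises sampling (Best & Fisher 1979 rejection sampler).
## Used on doubled angles for axial fiber orientations.
## ---------------------------------------------------------------------------
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric())
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2L] > 0 || log(c0 / u[2L]) + 1 - c0 >= 0) {
      out[i] <- (mu + sign(u[3L] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

## axial orientation sample in degrees, [0, 180)
sampleOrientations <- function(n, meanDeg, kappa) {
  (rad2deg(rvonmises(n, deg2rad(2 * meanDeg), kappa)) / 2) %% 180
}

## ---------------------------------------------------------------------------
## Fiber rasterization.
##
## A fiber is a (possibly sinusoidally displaced) centerline stamped with
## an anti-aliased round profile: per pixel, coverage =
## clamp(thickness/2 + 0.5 - distance_to_centerline, 0, 1).  The
## centerline is sampled finely and each pixel keeps the maximum coverage
## over samples (stamps along one fiber must not accumulate); the local
## tangent angle of the best sample is kept as the pixel's axis.
## Image coordinates: x = column, y = row counted upward from the bottom
## so that orientations are counter-clockwise from the horizontal axis.
## ---------------------------------------------------------------------------
rasterizeFiber <- function(h, w, x0, y0, phiDeg, thickness, len, ampl,
                           period) {
  halfw <- thickness / 2
  phi <- deg2rad(phiDeg)
  u <- c(cos(phi), sin(phi))            # along-fiber unit vector
  nv <- c(-sin(phi), cos(phi))          # normal
  tt <- seq(-len / 2, len / 2, by = 0.5)
  xs <- x0 + tt * u[1L] + ampl * sin(2 * pi * tt / period) * nv[1L]
  ys <- y0 + tt * u[2L] + ampl * sin(2 * pi * tt / period) * nv[2L]
  ## local tangent angle (degrees mod 180)
  dtan <- ampl * (2 * pi / period) * cos(2 * pi * tt / period)
  txs <- u[1L] + dtan * nv[1L]
  tys <- u[2L] + dtan * nv[2L]
  ang <- rad2deg(atan2(tys, txs)) %% 180
  ## keep samples within the padded image frame
  pad <- halfw + 1.5
  keep <- xs >= 1 - pad & xs <= w + pad & ys >= 1 - pad & ys <= h + pad
  if (!any(keep)) return(NULL)
  xs <- xs[keep]; ys <- ys[keep]; ang <- ang[keep]
  ## stamp neighborhood offsets
  rad <- ceiling(halfw + 1)
  off <- expand.grid(dx = -rad:rad, dy = -rad:rad)
  off <- off[off$dx^2 + off$dy^2 <= (rad + 0.8)^2, , drop = FALSE]
  ns <- length(xs); no <- nrow(off)
  px <- round(rep(xs, each = no) + off$dx)
  py <- round(rep(ys, each = no) + off$dy)
  dist <- sqrt((px - rep(xs, each = no))^2 + (py - rep(ys, each = no))^2)
  cov <- pmin(1, pmax(0, halfw + 0.5 - dist))
  angv <- rep(ang, each = no)
  ok <- cov > 0 & px >= 1 & px <= w & py >= 1 & py <= h
  if (!any(ok)) return(NULL)
  ## pixel linear index: row = h + 1 - y (y counts up), column-major
  idx <- (px[ok] - 1L) * h + (h + 1L - py[ok])
  cov <- cov[ok]; angv <- angv[ok]
  ## best (max-coverage) sample per pixel
  o <- order(idx, -cov)
  first <- !duplicated(idx[o])
  list(idx = idx[o][first], coverage = cov[o][first], axis = angv[o][first])
}

#' Generate a synthetic fiber phantom
#'
#' Draws `nFibers` fibers with orientations from an axial von Mises
#' distribution, anti-aliased round profiles of random thickness, and
#' optional sinusoidal curvature; deterministic given the spec's seed.
#' Where fibers overlap, retardance adds and the axis of the locally
#' dominant (highest retardance contribution) fiber wins.  The density
#' map is total fiber coverage clipped to [0, 1]; the stain map is a
#' smoothly varying absorbance field scaled by the spec's RGB
#' absorbance triple.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [Phantom-class] with ground-truth fiber records.
#'
#' @examples
#' ph <- generatePhantom(PhantomSpec(128, 128, nFibers = 5, seed = 7))
#' range(retardanceMap(ph))
#' @rdname generatePhantom
#' @export
setMethod("generatePhantom", "PhantomSpec", function(spec) {
  h <- spec@height; w <- spec@width
  set.seed(spec@seed)
  n <- spec@nFibers
  phis <- sampleOrientations(n, spec@meanOrientation, spec@kappa)
  thick <- stats::runif(n, spec@thicknessRange[1L], spec@thicknessRange[2L])
  lens <- stats::runif(n, spec@lengthRange[1L], spec@lengthRange[2L])
  x0 <- stats::runif(n, 1, w)
  y0 <- stats::runif(n, 1, h)
  ret <- matrix(0, h, w)
  cov <- matrix(0, h, w)
  axis <- matrix(NA_real_, h, w)
  best <- matrix(0, h, w)     # strongest single-fiber contribution so far
  for (k in seq_len(n)) {
    fb <- rasterizeFiber(h, w, x0[k], y0[k], phis[k], thick[k], lens[k],
                         spec@curveAmplitude, spec@curvePeriod)
    if (is.null(fb)) next
    contrib <- spec@retardance * fb$coverage
    ret[fb$idx] <- ret[fb$idx] + contrib
    cov[fb$idx] <- cov[fb$idx] + fb$coverage
    win <- contrib > best[fb$idx]
    axis[fb$idx[win]] <- fb$axis[win]
    best[fb$idx[win]] <- contrib[win]
  }
  ## smooth stain-density field: low-frequency random blotches on top of a
  ## uniform base, scaled by the RGB absorbance triple
  field <- matrix(stats::rnorm(64), 8, 8)
  big <- bilinearUpsample(field, h, w)
  stainScale <- 1 + 0.3 * (big - mean(big)) / max(stats::sd(big), 1e-9)
  stainScale <- pmax(stainScale, 0)
  stain <- array(0, c(h, w, 3L))
  for (c in 1:3) stain[, , c] <- stainScale * spec@stainAbsorbance[c]
  recs <- data.frame(fiber = seq_len(n), orientation = phis,
                     thickness = thick, length = lens,
                     retardance = rep(spec@retardance, n),
                     x0 = x0, y0 = y0)
  new("Phantom", retardanceMap = ret, axisMap = axis,
      densityMap = pmin(cov, 1), stainMap = stain,
      fiberRecords = recs, spec = spec)
})

## bilinear upsampling of a coarse matrix to h x w
bilinearUpsample <- function(m, h, w) {
  ri <- seq(1, nrow(m), length.out = h)
  ci <- seq(1, ncol(m), length.out = w)
  r0 <- pmin(floor(ri), nrow(m) - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), ncol(m) - 1L); fc <- ci - c0
  a <- m[r0, c0, drop = FALSE]; b <- m[r0 + 1L, c0, drop = FALSE]
  cc <- m[r0, c0 + 1L, drop = FALSE]; d <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  fr <- matrix(fr, h, w); fc <- matrix(fc, h, w, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + cc * (1 - fr) * fc +
    d * fr * fc
}

#' Phantom accessors
#'
#' @param object a [Phantom-class].
#' @return the corresponding raster (matrix or array) or the
#'   ground-truth fiber `data.frame`.
#' @name phantom-accessors
#' @export
retardanceMap <- function(object) object@retardanceMap

#' @rdname phantom-accessors
#' @export
axisMap <- function(object) object@axisMap

#' @rdname phantom-accessors
#' @export
densityMap <- function(object) object@densityMap

#' @rdname phantom-accessors
#' @export
stainMap <- function(object) object@stainMap

#' @rdname phantom-accessors
#' @export
fiberRecords <- function(object) object@fiberRecords

setMethod("show", "Phantom", function(object) {
  d <- dim(object@retardanceMap)
  cat(sprintf("Phantom: %d x %d px, %d fibers, %.1f%% fiber coverage\n",
              d[1L], d[2L], nrow(object@fiberRecords),
              100 * mean(object@densityMap > 0)))
})

#' Render the complementary PPM image pair for a phantom
#'
#' Renders, per pixel, the PPM colour under the two complementary fans
#' (offsets 0 and 90 degrees) using the phantom's local retardance and
#' slow-axis maps, multiplies by the Beer-Lambert stain transmittance
#' and the camera tint, and adds Gaussian noise last (clipped to
#' [0, 1]).  Also produces the unpolarized brightfield image (stain
#' transmittance only, no analyzer modulation) and an SHG-like
#' reference channel proportional to fiber density.
#'
#' @param phantom a [Phantom-class].
#' @param fan a [SpectralFan-class]; its `offset` is ignored (both
#'   offsets are rendered).
#' @param camera a [CameraModel-class] on the fan's grid.
#' @param grayLevel neutral background gray level (default 0.2).
#' @param ... unused.
#' @return list with elements `i0`, `i90`, `bf` (height x width x 3
#'   arrays in [0, 1]) and `shg` (height x width matrix in [0, 1]).
#'
#' @examples
#' ph <- generatePhantom(PhantomSpec(64, 64, nFibers = 3, seed = 2))
#' imgs <- renderPPMPair(ph)
#' str(imgs$i0)
#' @rdname renderPPMPair
#' @export
setMethod("renderPPMPair", "Phantom",
  function(phantom, fan = SpectralFan(), camera = gaussianCamera(fan),
           grayLevel = 0.2, ...) {
    spec <- phantom@spec
    h <- nrow(phantom@retardanceMap); w <- ncol(phantom@retardanceMap)
    delta <- as.vector(phantom@retardanceMap)
    alpha <- as.vector(phantom@axisMap)
    alpha[is.na(alpha)] <- 0          # irrelevant where delta == 0
    fan0 <- SpectralFan(fan@lambdaMin, fan@lambdaMax, fan@ellipticity,
                        offset = 0, nSamples = fan@nSamples)
    fan90 <- SpectralFan(fan@lambdaMin, fan@lambdaMax, fan@ellipticity,
                         offset = 90, nSamples = fan@nSamples)
    rgb0 <- renderField(fan0, camera, delta, alpha, grayLevel = grayLevel)
    rgb90 <- renderField(fan90, camera, delta, alpha, grayLevel = grayLevel)
    trans <- exp(-phantom@stainMap)   # Beer-Lambert per channel
    toImg <- function(m) {
      out <- array(0, c(h, w, 3L))
      for (c in 1:3)
        out[, , c] <- matrix(m[, c], h, w) * trans[, , c] * spec@cameraTint[c]
      out
    }
    i0 <- toImg(rgb0)
    i90 <- toImg(rgb90)
    bf <- array(0, c(h, w, 3L))
    for (c in 1:3)
      bf[, , c] <- grayLevel * trans[, , c] * spec@cameraTint[c]
    shg <- phantom@densityMap
    if (spec@noiseSd > 0) {
      set.seed(spec@seed + 1L)        # noise stream separate from geometry
      addNoise <- function(x)
        x + stats::rnorm(length(x), sd = spec@noiseSd)
      i0 <- addNoise(i0); i90 <- addNoise(i90)
      bf <- addNoise(bf); shg <- matrix(addNoise(shg), h, w)
    }
    clip01 <- function(x) pmin(pmax(x, 0), 1)
    list(i0 = clip01(i0), i90 = clip01(i90), bf = clip01(bf),
         shg = clip01(shg))
  })
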