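#' @include optics.R
NULL

## Rec.709 luma weights, used for brightness throughout the pipeline
REC709 <- c(0.2126, 0.7152, 0.0722)

checkRGB <- function(img, what = "image") {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3L] != 3L)
    stop("'", what, "' must be a height x width x 3 array")
  if (!all(is.finite(img)))
    stop("'", what, "' contains non-finite values")
  invisible(d)
}

luminance <- function(img) {
  img[, , 1L] * REC709[1L] + img[, , 2L] * REC709[2L] + img[, , 3L] * REC709[3L]
}

#' White-balance an RGB image against its background
#'
#' Divides each channel by its mean over the background region, then
#' rescales so that the background luminance is preserved; the
#' background thus becomes neutral (equal channel means).  By default
#' the background is taken as the pixels at or above the 99th luminance
#' percentile (the brightest, least tissue-dense pixels); pass an
#' explicit logical mask for tissue-dense fields.
#'
#' The operation is idempotent: white-balancing a white-balanced image
#' changes nothing (within numerical tolerance).
#'
#' @param img height x width x 3 array in [0, 1].
#' @param mask optional logical matrix marking background pixels.
#' @return the white-balanced array.
#'
#' @examples
#' img <- array(0.5, c(8, 8, 3))
#' img[, , 1] <- 0.4  # red-deficient tint
#' wb <- whiteBalance(img)
#' apply(wb, 3, mean)
#' @export
whiteBalance <- function(img, mask = NULL) {
  checkRGB(img)
  lum <- luminance(img)
  if (is.null(mask)) {
    thr <- stats::quantile(lum, 0.99, names = FALSE)
    mask <- lum >= thr
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(lum)))
      stop("'mask' must be a logical matrix matching the image")
    if (!any(mask)) stop("white balance failed: empty background mask")
  }
  bgLum <- mean(lum[mask])
  if (!is.finite(bgLum) || bgLum < 1e-3)
    stop("white balance failed: no bright background found (image too dark)")
  gains <- vapply(1:3, function(c) mean(img[, , c][mask]), numeric(1))
  if (any(gains <= 0))
    stop("white balance failed: a channel is zero over the background")
  out <- img
  for (c in 1:3) out[, , c] <- img[, , c] / gains[c] * bgLum
  out
}

#' Differential PPM image from the complementary pair
#'
#' Computes the signed per-channel difference `i0 - i90` of the two
#' complementary PPM images.  Non-birefringent structures — including
#' stain colour, which is identical in both images — cancel to zero;
#' birefringent structures survive as signed colour.
#'
#' @param i0,i90 height x width x 3 arrays of the fan-offset-0 and
#'   fan-offset-90 images (ideally white-balanced).
#' @return a [DifferentialImage-class].
#'
#' @examples
#' a <- array(runif(48), c(4, 4, 3))
#' d <- differentialImage(a, a)
#' max(abs(signedDifference(d)))
#' @export
differentialImage <- function(i0, i90) {
  checkRGB(i0, "i0"); checkRGB(i90, "i90")
  if (!identical(dim(i0), dim(i90)))
    stop("shape mismatch: i0 is ", paste(dim(i0), collapse = "x"),
         " but i90 is ", paste(dim(i90), collapse = "x"))
  new("DifferentialImage", signed = i0 - i90)
}

#' @rdname differential-accessors
#' @export
setMethod("signedDifference", "DifferentialImage",
          function(object) object@signed)

#' @rdname differential-accessors
#' @export
setMethod("colorView", "DifferentialImage",
          function(object) pmax(object@signed, 0))

#' Monochrome view of a differential PPM image
#'
#' Collapses the signed differential to a single brightness channel:
#' the Rec.709 luminance (weights 0.2126, 0.7152, 0.0722) of the
#' per-channel absolute difference, clipped to [0, 1].  Because the
#' absolute value is sign-symmetric, swapping the two input images
#' leaves the monochrome view unchanged.
#'
#' @param object a [DifferentialImage-class].
#' @return height x width matrix in [0, 1].
#' @rdname toMonochrome
#' @export
setMethod("toMonochrome", "DifferentialImage", function(object) {
  a <- abs(object@signed)
  pmin(luminance(a), 1)
})

setMethod("show", "DifferentialImage", function(object) {
  d <- dim(object@signed)
  cat(sprintf("DifferentialImage: %d x %d px, |diff| range [%.4g, %.4g]\n",
              d[1L], d[2L], min(abs(object@signed)), max(abs(object@signed))))
})

#' Overlay the monochrome birefringence signal on the brightfield
#'
#' Converts the brightfield image to a gray backdrop (Rec.709
#' luminance) and additively boosts one colour channel by
#' `gain * mono`, clipping to [0, 1].  With an all-zero signal the
#' output is exactly the grayscale brightfield.
#'
#' @param mono height x width matrix in [0, 1] (the monochrome
#'   differential view).
#' @param bf height x width x 3 brightfield array.
#' @param channel which channel carries the signal: `"R"`, `"G"` or
#'   `"B"` (default `"G"`).
#' @param gain multiplicative boost applied to `mono` (default 1).
#' @return height x width x 3 overlay array.
#' @export
overlayImage <- function(mono, bf, channel = c("G", "R", "B"), gain = 1) {
  channel <- match.arg(channel)
  checkRGB(bf, "bf")
  if (!identical(dim(mono), dim(bf)[1:2]))
    stop("shape mismatch: mono is ", paste(dim(mono), collapse = "x"),
         " but bf is ", paste(dim(bf)[1:2], collapse = "x"))
  gray <- luminance(bf)
  out <- array(rep(gray, 3L), c(dim(gray), 3L))
  ci <- match(channel, c("R", "G", "B"))
  out[, , ci] <- pmin(out[, , ci] + gain * mono, 1)
  out
}

#' Hue angle of RGB values
#'
#' Standard HSV hue in degrees [0, 360); achromatic (equal-channel)
#' pixels return `NA`.  Used to check that the differential colour
#' encodes fiber orientation and nothing else.
#'
#' @param rgb either a length-3 RGB vector or an n x 3 matrix.
#' @return hue angle(s) in degrees.
#'
#' @examples
#' hueAngle(c(1, 0, 0))  # 0 (red)
#' hueAngle(c(0, 1, 0))  # 120 (green)
#' @export
hueAngle <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1L)
  r <- rgb[, 1L]; g <- rgb[, 2L]; b <- rgb[, 3L]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- rep(NA_real_, length(r))
  i <- d > 0 & mx == r
  h[i] <- 60 * (((g[i] - b[i]) / d[i]) %% 6)
  i <- d > 0 & mx == g & is.na(h)
  h[i] <- 60 * ((b[i] - r[i]) / d[i] + 2)
  i <- d > 0 & mx == b & is.na(h)
  h[i] <- 60 * ((r[i] - g[i]) / d[i] + 4)
  if (length(h) == 1L) h[[1L]] else h
}

## smallest absolute difference between two hue angles (degrees)
hueDistance <- function(h1, h2) {
  d <- abs(h1 - h2) %% 360
  pmin(d, 360 - d)
}
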