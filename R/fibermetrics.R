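#' @include pipeline.R
NULL

#' Tile an image into non-overlapping square blocks
#'
#' Blocks of `blockSize` pixels tile the image from the top-left
#' corner in row-major order; partial blocks at the right/bottom edges
#' are dropped so every block covers the same area.
#'
#' @param imageDim integer vector `c(height, width)` (a matrix is also
#'   accepted, in which case its `dim` is used).
#' @param blockSize block edge length in pixels (default 256).
#' @return a [BlockGrid-class].
#'
#' @examples
#' nBlocks(tileBlocks(c(512, 512)))  # 4
#' nBlocks(tileBlocks(c(300, 300)))  # 1
#' @export
tileBlocks <- function(imageDim, blockSize = 256L) {
  if (!is.null(dim(imageDim))) imageDim <- dim(imageDim)[1:2]
  imageDim <- as.integer(imageDim)
  blockSize <- as.integer(blockSize)
  nr <- imageDim[1L] %/% blockSize
  nc <- imageDim[2L] %/% blockSize
  if (nr < 1L || nc < 1L)
    stop("image (", imageDim[1L], "x", imageDim[2L],
         ") is smaller than one ", blockSize, "-pixel block")
  og <- expand.grid(col = (seq_len(nc) - 1L) * blockSize,
                    row = (seq_len(nr) - 1L) * blockSize)
  origins <- cbind(row = og$row, col = og$col)   # row-major order
  new("BlockGrid", imageDim = imageDim, blockSize = blockSize,
      origins = origins)
}

#' BlockGrid accessors
#'
#' @param grid a [BlockGrid-class].
#' @return `nBlocks` the number of blocks; `blockOrigins` the integer
#'   matrix of 0-based (row, col) origins.
#' @name blockgrid-accessors
#' @export
nBlocks <- function(grid) nrow(grid@origins)

#' @rdname blockgrid-accessors
#' @export
blockOrigins <- function(grid) grid@origins

setMethod("show", "BlockGrid", function(object) {
  cat(sprintf("BlockGrid: %d blocks of %d px over a %d x %d image\n",
              nrow(object@origins), object@blockSize,
              object@imageDim[1L], object@imageDim[2L]))
})

## extract one block (1-based matrix indices) from a matrix
blockSubmatrix <- function(m, origin, blockSize) {
  m[(origin[1L] + 1L):(origin[1L] + blockSize),
    (origin[2L] + 1L):(origin[2L] + blockSize), drop = FALSE]
}

#' Select analysis blocks by reference-channel coverage
#'
#' A block is kept when the fraction of reference pixels with
#' intensity strictly above `pixelThreshold` reaches
#' `signalThreshold`; blocks with less signal (by default, less than
#' 10 percent) are excluded from analysis.
#'
#' @param reference single-channel reference raster (e.g. an SHG-like
#'   collagen channel), co-registered with the grid.
#' @param grid a [BlockGrid-class].
#' @param signalThreshold minimum covered fraction (default 0.10).
#' @param pixelThreshold intensity floor defining "signal" (default 0:
#'   any strictly positive pixel counts).
#' @return logical vector, one element per block, `TRUE` = kept.
#'
#' @examples
#' ref <- matrix(0, 256, 512); ref[, 1:200] <- 1
#' selectRois(ref, tileBlocks(ref))
#' @export
selectRois <- function(reference, grid, signalThreshold = 0.10,
                       pixelThreshold = 0) {
  stopifnot(is(grid, "BlockGrid"))
  if (!identical(dim(reference)[1:2], as.integer(grid@imageDim)))
    stop("reference raster does not match the grid's image dimensions")
  apply(grid@origins, 1L, function(o) {
    blk <- blockSubmatrix(reference, o, grid@blockSize)
    mean(blk > pixelThreshold) >= signalThreshold
  })
}

## ---------------------------------------------------------------------------
## Structure-tensor orientation field.
##
## Gradients of the Gaussian-smoothed image (sigma = gradSigma) are
## combined into the structure tensor, which is then smoothed with
## sigma = tensorSigma.  The fiber orientation is the gradient-normal
## direction; coherence (the tensor's eigenvalue anisotropy) measures
## how well-defined the local orientation is.  Orientations are
## measured counter-clockwise from the horizontal image axis (y up),
## in [0, 180).
## ---------------------------------------------------------------------------

gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  g <- EBImage::gblur(m, sigma = sigma)
  matrix(as.numeric(g), nrow(m), ncol(m))
}

## central-difference gradients with replicated edges
gradientXY <- function(m) {
  h <- nrow(m); w <- ncol(m)
  padc <- cbind(m[, 1L], m, m[, w])
  gx <- (padc[, 3:(w + 2L)] - padc[, 1:w]) / 2          # along columns (x)
  padr <- rbind(m[1L, ], m, m[h, ])
  gdown <- (padr[3:(h + 2L), ] - padr[1:h, ]) / 2       # along rows (down)
  list(gx = gx, gy = -gdown)                            # y counts up
}

#' Per-pixel orientation field from the structure tensor
#'
#' @param img single-channel image matrix.
#' @param gradSigma Gaussian pre-smoothing sigma for gradients, in
#'   pixels (default 2).
#' @param tensorSigma Gaussian smoothing sigma of the tensor
#'   components, in pixels (default 3).  Kept close to the fiber
#'   radius: a much wider window performs a local majority vote among
#'   crossing fibers, which inflates the alignment of isotropic fields.
#' @return list with matrices `orientation` (fiber orientation in
#'   degrees, [0, 180)), `coherence` (anisotropy in [0, 1]) and
#'   `weight` (coherence times signal).
#' @seealso [blockOrientation()], [blockMetrics()]
#' @export
orientationField <- function(img, gradSigma = 2, tensorSigma = 3) {
  sm <- gaussianSmooth(img, gradSigma)
  g <- gradientXY(sm)
  jxx <- gaussianSmooth(g$gx * g$gx, tensorSigma)
  jyy <- gaussianSmooth(g$gy * g$gy, tensorSigma)
  jxy <- gaussianSmooth(g$gx * g$gy, tensorSigma)
  ## dominant gradient direction; the fiber runs normal to it
  psi <- 0.5 * atan2(2 * jxy, jxx - jyy)
  orientation <- (rad2deg(psi) + 90) %% 180
  tr <- jxx + jyy
  coherence <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / pmax(tr, 1e-12)
  coherence[tr < 1e-12] <- 0
  list(orientation = orientation, coherence = coherence,
       weight = coherence * img)
}

#' Weighted orientation of a single block
#'
#' Computes the structure-tensor orientation field of the block,
#' weights each pixel by coherence times signal, drops pixels whose
#' weight falls below `weightFloor` times the block's maximum weight,
#' and returns the weighted circular mean on doubled angles.
#'
#' @param block single-channel block matrix.
#' @param weightFloor weight cut-off as a fraction of the block
#'   maximum (default 0.05).
#' @inheritParams orientationField
#' @return list with `orientation` (degrees in [0, 180), `NA` for a
#'   no-fiber block), `nPixelsUsed`, and the per-pixel `orientationMap`
#'   and `weightMap`.
#'
#' @examples
#' stripes <- sin(outer(1:128, 1:128, function(r, c) 2 * pi * r / 8))^2
#' blockOrientation(stripes)$orientation  # ~0 degrees (horizontal)
#' @export
blockOrientation <- function(block, weightFloor = 0.05, gradSigma = 2,
                             tensorSigma = 3) {
  of <- orientationField(block, gradSigma, tensorSigma)
  wmax <- max(of$weight)
  keep <- wmax > 0 & of$weight >= weightFloor * wmax
  if (!any(keep))
    return(list(orientation = NA_real_, nPixelsUsed = 0L,
                orientationMap = of$orientation, weightMap = of$weight))
  th <- of$orientation[keep]
  w <- of$weight[keep]
  z <- sum(w * exp(2i * deg2rad(th)))
  list(orientation = (rad2deg(Arg(z)) / 2) %% 180,
       nPixelsUsed = sum(keep),
       orientationMap = of$orientation, weightMap = of$weight)
}

#' Sinusoid mapping of fiber orientation
#'
#' Fiber orientation measured against the horizontal axis is ambiguous
#' at the ends of its range: 1 degree and 179 degrees describe nearly
#' the same axis but differ numerically by 178.  Taking the sine of
#' the orientation (in degrees on [0, 180]) maps both ends to the same
#' value and the range onto [0, 1], removing the ambiguity.
#'
#' @param orientation orientation(s) in degrees, each in [0, 180].
#' @return `sin(orientation)` in [0, 1].
#'
#' @examples
#' sinMap(c(0, 45, 90, 180))
#' @export
sinMap <- function(orientation) {
  if (any(!is.finite(orientation)) ||
      any(orientation < 0 | orientation > 180))
    stop("orientation values must lie in [0, 180] degrees")
  sin(deg2rad(orientation))
}

#' Alignment coefficient of a set of fiber orientations
#'
#' The mean resultant vector length of the doubled orientation angles
#' (axial circular statistics):
#' \deqn{R = \left| \sum_k w_k e^{i 2\theta_k} \right| / \sum_k w_k.}
#' R equals 1 exactly when all orientations coincide modulo 180
#' degrees, and approaches 0 for orientations spread uniformly in all
#' directions.
#'
#' @param orientations fiber orientations in degrees.
#' @param weights optional non-negative weights (default equal).
#' @return alignment coefficient in [0, 1].
#'
#' @examples
#' alignmentCoefficient(rep(37, 100))   # 1
#' alignmentCoefficient(c(0, 90))       # 0
#' @export
alignmentCoefficient <- function(orientations, weights = NULL) {
  if (length(orientations) == 0L)
    stop("need at least one orientation")
  if (is.null(weights)) weights <- rep(1, length(orientations))
  if (length(weights) != length(orientations))
    stop("'weights' must match 'orientations' in length")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("'weights' must be non-negative with positive sum")
  z <- sum(weights * exp(2i * deg2rad(orientations))) / sum(weights)
  min(Mod(z), 1)
}

#' Block-based fiber metrics for a monochrome birefringence image
#'
#' The full quantification workflow: tile the image into blocks,
#' optionally exclude blocks with insufficient reference-channel
#' signal, and compute per-block coverage, weighted structure-tensor
#' orientation, its sinusoid mapping, and the alignment coefficient of
#' the block's per-pixel orientations.
#'
#' @param mono single-channel image matrix (e.g. the monochrome
#'   differential PPM view, or an SHG image).
#' @param reference optional single-channel reference raster for ROI
#'   selection; blocks whose covered fraction falls below
#'   `signalThreshold` are dropped.  Default: the `mono` image itself.
#' @param blockSize block edge length in pixels (default 256).
#' @param signalThreshold minimum reference coverage per block
#'   (default 0.10).
#' @param pixelThreshold reference intensity floor (default 0).
#' @inheritParams blockOrientation
#' @return data.frame with one row per kept block: `block_id`, `row`,
#'   `col` (0-based block origin), `coverage`, `orientation_deg`,
#'   `sin_orientation`, `alignment`, `n_pixels_used`.
#'
#' @examples
#' img <- matrix(0, 256, 256)
#' img[101:110, ] <- 1    # one horizontal stripe
#' blockMetrics(img, blockSize = 256)
#' @export
blockMetrics <- function(mono, reference = NULL, blockSize = 256L,
                         signalThreshold = 0.10, pixelThreshold = 0,
                         weightFloor = 0.05, gradSigma = 2,
                         tensorSigma = 3) {
  grid <- tileBlocks(dim(mono), blockSize)
  if (is.null(reference)) reference <- mono
  kept <- selectRois(reference, grid, signalThreshold, pixelThreshold)
  rows <- lapply(which(kept), function(i) {
    o <- grid@origins[i, ]
    blk <- blockSubmatrix(mono, o, grid@blockSize)
    ref <- blockSubmatrix(reference, o, grid@blockSize)
    bo <- blockOrientation(blk, weightFloor, gradSigma, tensorSigma)
    if (is.na(bo$orientation)) return(NULL)   # no-fiber block
    keep <- bo$weightMap >= weightFloor * max(bo$weightMap)
    data.frame(
      block_id = i, row = o[1L], col = o[2L],
      coverage = mean(ref > pixelThreshold),
      orientation_deg = bo$orientation,
      sin_orientation = sinMap(bo$orientation),
      alignment = alignmentCoefficient(bo$orientationMap[keep],
                                       bo$weightMap[keep]),
      n_pixels_used = bo$nPixelsUsed)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(block_id = integer(), row = integer(),
                      col = integer(), coverage = numeric(),
                      orientation_deg = numeric(),
                      sin_orientation = numeric(), alignment = numeric(),
                      n_pixels_used = integer())
  rownames(out) <- NULL
  out
}
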