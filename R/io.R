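#' @include agreement.R
NULL

#' Read a raster image (TIFF or PNG)
#'
#' @param path file path; format selected by extension (`.tif`,
#'   `.tiff`, `.png`).
#' @return numeric array in [0, 1]: height x width x channels, or a
#'   matrix for single-channel images.
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("input file not found: '", path, "'")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: '", ext, "'"))
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L)
    img <- img[, , 1:3]   # drop alpha
  img
}

#' Write a raster image as 16-bit TIFF
#'
#' Values are clipped to [0, 1] and stored losslessly at 16 bits per
#' sample.
#'
#' @param img matrix or height x width x 3 array in [0, 1].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRaster16 <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

## Signed rasters (the differential image) are stored as 32-bit TIFF
## after the affine map v -> (v - offset) / scale into [0, 1]; the
## transform parameters travel in a JSON sidecar next to the file.
writeSignedTIFF <- function(img, path) {
  lo <- min(img, -1e-12); hi <- max(img, 1e-12)
  scale <- hi - lo
  tiff::writeTIFF((img - lo) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

readSignedTIFF <- function(path) {
  tf <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tiff::readTIFF(path) * tf$scale + tf$offset
}

## md5 checksums of existing files, named by basename
fileChecksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  sums <- tools::md5sum(paths)
  stats::setNames(as.list(unname(sums)), basename(paths))
}

## Write a run manifest beside stage outputs: enough to re-run the stage.
writeManifest <- function(dir, stage, config, seed, inputs = character(),
                          outputs = character()) {
  manifest <- list(
    stage = stage,
    package = "ppmfiber",
    version = as.character(utils::packageVersion("ppmfiber")),
    seed = seed,
    config = config,
    input_checksums = fileChecksums(inputs),
    outputs = basename(outputs))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
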