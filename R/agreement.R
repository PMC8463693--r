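#' @include fibermetrics.R
NULL

#' Bland-Altman analysis of two paired measurement sets
#'
#' Computes, for paired measurements of the same quantity by two
#' methods, the differences `d = x - y`, their mean (the bias), their
#' sample standard deviation, the limits of agreement
#' `bias +/- 1.96 * sd`, and the fraction of differences falling
#' inside the limits.  Per-pair means `(x + y) / 2` are retained as
#' the plot abscissa.
#'
#' @param x,y numeric vectors of equal length (n >= 2), paired by
#'   position.
#' @return a [BlandAltmanResult-class].
#'
#' @examples
#' ba <- blandAltman(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9))
#' bias(ba)
#' limitsOfAgreement(ba)
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length (got ", length(x), " and ",
         length(y), ")")
  if (length(x) < 2L)
    stop("need at least 2 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  new("BlandAltmanResult", n = length(d), bias = bias, sd = s,
      loaLow = lo, loaHigh = hi,
      fractionWithin = mean(d >= lo & d <= hi),
      means = m, differences = d)
}

#' BlandAltmanResult accessors
#'
#' @param object a [BlandAltmanResult-class].
#' @return `bias` the mean difference; `limitsOfAgreement` the
#'   two-element vector `c(low, high)`; `fractionWithin` the fraction
#'   of differences inside the limits; `biasConfint` the 95 percent
#'   confidence interval of the bias itself
#'   (`bias +/- 1.96 * sd / sqrt(n)`), which is a different, narrower
#'   construct than the limits of agreement.
#' @name blandaltman-accessors
#' @export
bias <- function(object) object@bias

#' @rdname blandaltman-accessors
#' @export
limitsOfAgreement <- function(object) c(low = object@loaLow,
                                        high = object@loaHigh)

#' @rdname blandaltman-accessors
#' @export
fractionWithin <- function(object) object@fractionWithin

#' @rdname blandaltman-accessors
#' @export
biasConfint <- function(object) {
  half <- 1.96 * object@sd / sqrt(object@n)
  c(low = object@bias - half, high = object@bias + half)
}

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf("Bland-Altman agreement over %d pairs\n", object@n))
  cat(sprintf("  bias                %+.5g\n", object@bias))
  cat(sprintf("  sd of differences   %.5g\n", object@sd))
  cat(sprintf("  limits of agreement [%+.5g, %+.5g]\n",
              object@loaLow, object@loaHigh))
  cat(sprintf("  within limits       %.1f%%\n",
              100 * object@fractionWithin))
})

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means, with a
#' dotted horizontal line at the bias and solid lines at both limits
#' of agreement.  If `path` is given the plot is written to that file
#' (PNG or PDF, by extension); otherwise it is drawn on the current
#' device.
#'
#' @param result a [BlandAltmanResult-class].
#' @param path optional output file path (`.png` or `.pdf`).
#' @param metricName axis-label name of the compared metric.
#' @param ... further arguments passed to [graphics::plot()].
#' @return the path, invisibly (or `NULL` when drawing on the current
#'   device).
#' @export
baPlot <- function(result, path = NULL, metricName = "measurement", ...) {
  draw <- function() {
    pad <- max(diff(range(result@differences)), 2 * result@sd, 1e-3)
    ylim <- range(result@differences, result@loaLow, result@loaHigh)
    ylim <- ylim + c(-0.1, 0.1) * pad
    graphics::plot(result@means, result@differences,
                   xlab = paste("mean of", metricName),
                   ylab = paste("difference in", metricName),
                   main = "Bland-Altman agreement", pch = 19,
                   col = "grey30", ylim = ylim, ...)
    graphics::abline(h = result@bias, lty = 3, col = "blue")
    graphics::abline(h = c(result@loaLow, result@loaHigh), col = "red")
  }
  if (is.null(path)) {
    draw()
    return(invisible(NULL))
  }
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
           png = grDevices::png(path, width = 800, height = 600),
           pdf = grDevices::pdf(path, width = 8, height = 6),
           stop("unsupported plot format: '", ext, "'"))
    TRUE
  }, error = function(e) stop("cannot open plot file '", path, "': ",
                              conditionMessage(e)))
  on.exit(grDevices::dev.off(), add = TRUE)
  draw()
  invisible(path)
}
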