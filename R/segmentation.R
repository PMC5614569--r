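# Otsu thresholding of ICA spatial maps into binary vessel masks, and
# extraction of time-density curves by masking the (registered) series.

#' Otsu's between-class-variance threshold
#'
#' Values are histogrammed into \code{nBins} equal-width bins over
#' \code{[min, max]}; the returned threshold is the bin edge maximizing the
#' between-class variance of the two classes it induces (class means taken
#' from the actual values, not bin centres). Ties return the lowest such
#' edge.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param nBins number of histogram bins (default 256).
#' @return The scalar threshold, strictly between min and max.
#' @export
otsuThreshold <- function(values, nBins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite values")
  lo <- min(values); hi <- max(values)
  if (hi <= lo) stop("all values equal; no threshold exists")
  width <- (hi - lo) / nBins
  bin <- pmin(floor((values - lo) / width), nBins - 1L)  # 0-based bin index
  counts <- tabulate(bin + 1L, nBins)
  sums <- vapply(seq_len(nBins), function(b) sum(values[bin == b - 1L]), 0)
  n <- length(values); total <- sum(values)
  # candidate edges k = 1..nBins-1: class 1 = bins 0..k-1 (values < edge)
  cn <- cumsum(counts)[-nBins]
  cs <- cumsum(sums)[-nBins]
  valid <- cn > 0 & cn < n
  w1 <- cn / n; w2 <- 1 - w1
  mu1 <- cs / cn; mu2 <- (total - cs) / (n - cn)
  bc <- ifelse(valid, w1 * w2 * (mu1 - mu2)^2, -Inf)
  k <- which.max(bc)                       # first maximum = lowest edge
  lo + k * width
}

#' Build a binary vessel mask from a component spatial map
#'
#' Negative map weights are clipped to zero (under the fixed sign convention
#' only positive loading indicates contrast arrival), the Otsu threshold is
#' computed over the clipped values, and the mask keeps pixels strictly
#' above it. A constant (e.g. all-negative) map yields a degenerate mask,
#' flagged rather than raised.
#'
#' @param map numeric H x W spatial map.
#' @param phase label carried into the mask ("arterial", "capillary",
#'   "venous" or an ROI name).
#' @param nBins histogram bins for the Otsu cut (default 256).
#' @return A [VesselMask-class].
#' @export
makeMask <- function(map, phase, nBins = 256L) {
  stopifnot(is.matrix(map))
  if (any(!is.finite(map))) stop("map must be finite")
  clipped <- pmax(map, 0)
  if (max(clipped) <= min(clipped)) {
    warning("constant map after clipping; mask is degenerate", call. = FALSE)
    return(new("VesselMask", mask = matrix(FALSE, nrow(map), ncol(map)),
               phase = phase, threshold = NA_real_, fractionOn = 0,
               degenerate = TRUE))
  }
  th <- otsuThreshold(as.vector(clipped), nBins = nBins)
  m <- clipped > th
  new("VesselMask", mask = m, phase = phase, threshold = th,
      fractionOn = mean(m), degenerate = !any(m))
}

#' @rdname VesselMask-class
#' @param x a \code{VesselMask}.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname VesselMask-class
#' @export
setMethod("maskMatrix", "VesselMask", function(x) x@mask)

setMethod("show", "VesselMask", function(object) {
  cat(sprintf("VesselMask (%s): %d px on (%.1f%%), threshold %.4g%s\n",
              object@phase, sum(object@mask), 100 * object@fractionOn,
              object@threshold,
              if (object@degenerate) " [degenerate]" else ""))
})

#' Extract the time-density curve under a mask
#'
#' The density at each frame is the mean over the masked pixels (mean rather
#' than sum, so curves are comparable across masks of different size; the
#' FWHM is invariant to vertical scaling either way).
#'
#' @param series a [DSASeries-class] (the registered series, by pipeline
#'   convention).
#' @param mask a [VesselMask-class] or a logical H x W matrix.
#' @param label curve label; defaults to the mask's phase.
#' @return A [TDC-class].
#' @export
extractTDC <- function(series, mask, label = NULL) {
  stopifnot(is(series, "DSASeries"))
  if (is(mask, "VesselMask")) {
    if (mask@degenerate) stop("cannot extract a TDC from a degenerate mask")
    if (is.null(label)) label <- mask@phase
    mask <- mask@mask
  }
  stopifnot(is.logical(mask))
  if (is.null(label)) label <- "roi"
  d <- dim(series@frames)
  if (!identical(dim(mask), d[2:3]))
    stop("mask shape does not match the frames")
  if (!any(mask)) stop("mask selects no pixels")
  T <- d[1]
  dens <- vapply(seq_len(T), function(t) mean(series@frames[t, , ][mask]), 0)
  new("TDC", timestamps = series@timestamps, density = dens,
      label = label, nPixels = sum(mask))
}

setMethod("show", "TDC", function(object) {
  cat(sprintf("TDC '%s': %d samples over %.2f s (%s px), peak %.4g at %.2f s\n",
              object@label, length(object@density),
              max(object@timestamps),
              ifelse(is.na(object@nPixels), "?", object@nPixels),
              max(object@density),
              object@timestamps[which.max(object@density)]))
})

#' Export a mask as PNG (0/255)
#' @param mask a [VesselMask-class].
#' @param path output .png path.
#' @export
writeMaskPNG <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to write PNG masks")
  png::writePNG(mask@mask * 1, path)
  invisible(path)
}
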