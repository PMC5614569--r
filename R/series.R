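#' Construct a DSA series
#'
#' @param frames numeric T x H x W array of contrast density (larger = more
#'   iodine; the t = 0 frame should be approximately zero).
#' @param timestamps numeric length T, seconds, strictly increasing, first 0.
#' @param view "AP" or "LAT".
#' @param polarityInverted whether source pixels were inverted on load.
#' @param baselineSubtracted whether the t = 0 frame was subtracted on load.
#' @return A [DSASeries-class] object.
#' @export
DSASeries <- function(frames, timestamps, view = c("AP", "LAT"),
                      polarityInverted = FALSE, baselineSubtracted = TRUE) {
  view <- match.arg(view)
  new("DSASeries", frames = frames, timestamps = as.numeric(timestamps),
      view = view, polarityInverted = polarityInverted,
      baselineSubtracted = baselineSubtracted)
}

#' @rdname DSASeries
#' @param x,object a \code{DSASeries}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname DSASeries
#' @export
setMethod("nFrames", "DSASeries", function(x) dim(x@frames)[1])

#' @rdname DSASeries
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname DSASeries
#' @export
setMethod("frames", "DSASeries", function(x) x@frames)

#' Frame timestamps in seconds
#' @param x a \code{DSASeries}, \code{TDC} or \code{ComponentSet}.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname timePoints
#' @export
setMethod("timePoints", "DSASeries", function(x) x@timestamps)

#' @rdname timePoints
#' @export
setMethod("timePoints", "TDC", function(x) x@timestamps)

#' @rdname timePoints
#' @export
setMethod("timePoints", "ComponentSet", function(x) x@timestamps)

#' @rdname DSASeries
#' @export
setGeneric("viewLabel", function(x) standardGeneric("viewLabel"))

#' @rdname DSASeries
#' @export
setMethod("viewLabel", "DSASeries", function(x) x@view)

#' @rdname DSASeries
#' @export
setMethod("dim", "DSASeries", function(x) dim(x@frames))

setMethod("show", "DSASeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("DSASeries: %d frames of %d x %d (%s view)\n",
              d[1], d[2], d[3], object@view))
  ts <- object@timestamps
  cat(sprintf("  time grid: %.3f .. %.3f s (median dt %.3f s)\n",
              ts[1], ts[length(ts)], stats::median(diff(ts))))
  cat(sprintf("  density range: [%.4g, %.4g]\n",
              min(object@frames), max(object@frames)))
})

#' Extract one frame as an H x W matrix
#' @param series a \code{DSASeries}.
#' @param t frame index (1-based).
#' @export
getFrame <- function(series, t) series@frames[t, , ]

#' Flatten a series into a T x (H*W) data matrix
#'
#' Row t is frame t in row-major pixel order: pixel (row r, col c), 0-based,
#' maps to column r * W + c + 1. [unflattenMap()] inverts the pixel order for
#' a single map.
#'
#' @param series a [DSASeries-class].
#' @return numeric matrix T x (H*W) with attribute \code{frameDim = c(H, W)}.
#' @export
flattenSeries <- function(series) {
  stopifnot(is(series, "DSASeries"))
  d <- dim(series@frames)
  m <- matrix(aperm(series@frames, c(1, 3, 2)), nrow = d[1])
  attr(m, "frameDim") <- d[2:3]
  m
}

#' @rdname flattenSeries
#' @param v numeric vector of length H*W in row-major order.
#' @param H,W frame dimensions.
#' @export
unflattenMap <- function(v, H, W) matrix(v, nrow = H, ncol = W, byrow = TRUE)
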