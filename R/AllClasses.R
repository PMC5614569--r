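#' @import methods
NULL

#' Acquisition schedule of a dynamic DSA run
#'
#' A multi-rate frame schedule: an ordered list of (frame rate, duration)
#' segments, optionally prolonged at a fixed extension rate to follow slow
#' venous washout. The clinical default is 7.5 fps for 5 s, then 4 fps for
#' 3 s, 3 fps for 2 s and 2 fps for 2 s, a 12 s base acquisition.
#'
#' @slot rates numeric, frames per second per segment (> 0).
#' @slot durations numeric, seconds per segment (> 0), same length as rates.
#' @slot extensionRate numeric(1), fps used if the run is prolonged.
#' @slot extensionDuration numeric(1), seconds of prolongation (>= 0).
#' @seealso [defaultSchedule()], [buildTimeGrid()]
#' @export
setClass("AcquisitionSchedule",
  representation(rates = "numeric", durations = "numeric",
                 extensionRate = "numeric", extensionDuration = "numeric"),
  prototype(extensionRate = 2, extensionDuration = 0))

setValidity("AcquisitionSchedule", function(object) {
  msg <- character()
  if (length(object@rates) != length(object@durations))
    msg <- c(msg, "rates and durations must have the same length")
  if (length(object@rates) < 1L) msg <- c(msg, "at least one segment required")
  if (any(!is.finite(object@rates)) || any(object@rates <= 0))
    msg <- c(msg, "all frame rates must be finite and > 0")
  if (any(!is.finite(object@durations)) || any(object@durations <= 0))
    msg <- c(msg, "all durations must be finite and > 0")
  if (length(object@extensionDuration) != 1L || object@extensionDuration < 0)
    msg <- c(msg, "extensionDuration must be a single value >= 0")
  if (object@extensionDuration > 0 &&
      (length(object@extensionRate) != 1L || object@extensionRate <= 0))
    msg <- c(msg, "extensionRate must be > 0 when an extension is requested")
  if (length(msg)) msg else TRUE
})

#' Dynamic DSA series
#'
#' A time-ordered stack of subtraction frames on a (generally non-uniform)
#' time grid. The canonical density convention is: larger value = more iodine
#' contrast, with the reference frame at t = 0 close to zero everywhere.
#'
#' @slot frames numeric array T x H x W of contrast density.
#' @slot timestamps numeric length T, seconds, strictly increasing, first 0.
#' @slot view character(1), \code{"AP"} or \code{"LAT"}.
#' @slot polarityInverted logical(1), whether source pixels were inverted on
#'   load (subtraction angiograms conventionally render contrast dark).
#' @slot baselineSubtracted logical(1), whether the t = 0 frame was subtracted.
#' @seealso [DSASeries()], [readSeries()], [registerSeries()]
#' @export
setClass("DSASeries",
  representation(frames = "array", timestamps = "numeric", view = "character",
                 polarityInverted = "logical", baselineSubtracted = "logical"),
  prototype(view = "AP", polarityInverted = FALSE, baselineSubtracted = TRUE))

setValidity("DSASeries", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a T x H x W array")
  if (d[1] != length(object@timestamps))
    msg <- c(msg, "number of frames must equal the number of timestamps")
  if (d[2] < 16L || d[3] < 16L) msg <- c(msg, "frames must be at least 16 x 16")
  if (length(object@timestamps) < 2L)
    msg <- c(msg, "a series needs at least 2 frames")
  else {
    if (any(!is.finite(object@timestamps)) || object@timestamps[1] != 0)
      msg <- c(msg, "timestamps must be finite with first element 0")
    if (any(diff(object@timestamps) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
  }
  if (any(!is.finite(object@frames))) msg <- c(msg, "frames must be finite")
  if (!(object@view %in% c("AP", "LAT")))
    msg <- c(msg, "view must be 'AP' or 'LAT'")
  if (length(msg)) msg else TRUE
})

#' Rigid (rotation + translation) frame transform
#'
#' Maps moving-frame coordinates into reference-frame coordinates:
#' \code{x_ref = R(theta) (x_mov - c) + c + t}, where the rotation centre
#' \code{c} is the image centre and \code{(x, y)} are 0-based (column, row)
#' pixel coordinates.
#'
#' @slot rotation numeric(1), degrees, |rotation| <= 45.
#' @slot dx,dy numeric(1), translation in pixels.
#' @export
setClass("RigidTransform",
  representation(rotation = "numeric", dx = "numeric", dy = "numeric"),
  prototype(rotation = 0, dx = 0, dy = 0))

setValidity("RigidTransform", function(object) {
  if (!all(is.finite(c(object@rotation, object@dx, object@dy))))
    return("transform parameters must be finite")
  if (abs(object@rotation) > 45)
    return("|rotation| must be <= 45 degrees for cranial DSA")
  TRUE
})

#' Three-phase independent component decomposition
#'
#' Result of the temporal FastICA of a DSA series: exactly three paired
#' (time course, spatial map) components, labelled arterial / capillary /
#' venous once phases have been assigned.
#'
#' @slot timeCourses numeric matrix T x 3, one course per column.
#' @slot spatialMaps numeric array 3 x H x W of mixing weights per pixel.
#' @slot phaseLabels character(3); \code{"unassigned"} before labelling, else
#'   a permutation of arterial/capillary/venous aligned with the columns.
#' @slot timestamps numeric length T (seconds) carried from the series.
#' @slot converged logical(1); FALSE when the fixed-point iteration hit the
#'   iteration cap or the data were rank-deficient.
#' @slot iterations integer(1), fixed-point iterations used.
#' @slot tol numeric(1), convergence tolerance requested.
#' @slot seed integer(1), RNG seed used for the random orthogonal start.
#' @export
setClass("ComponentSet",
  representation(timeCourses = "matrix", spatialMaps = "array",
                 phaseLabels = "character", timestamps = "numeric",
                 converged = "logical", iterations = "integer",
                 tol = "numeric", seed = "integer"))

setValidity("ComponentSet", function(object) {
  msg <- character()
  if (ncol(object@timeCourses) != 3L) msg <- c(msg, "exactly 3 components required")
  d <- dim(object@spatialMaps)
  if (length(d) != 3L || d[1] != 3L)
    msg <- c(msg, "spatialMaps must be a 3 x H x W array")
  if (length(object@phaseLabels) != 3L)
    msg <- c(msg, "phaseLabels must have length 3")
  lab <- object@phaseLabels
  if (!all(lab == "unassigned") &&
      !setequal(lab, c("arterial", "capillary", "venous")))
    msg <- c(msg, "phaseLabels must be 'unassigned' or a permutation of the three phases")
  if (length(object@timestamps) &&
      length(object@timestamps) != nrow(object@timeCourses))
    msg <- c(msg, "timestamps length must match the time courses")
  if (length(msg)) msg else TRUE
})

#' Binary vessel mask for one phase
#'
#' @slot mask logical H x W matrix.
#' @slot phase character(1): arterial, capillary, venous, or an ROI name.
#' @slot threshold numeric(1), the Otsu cut applied (NA when degenerate).
#' @slot fractionOn numeric(1), proportion of pixels TRUE.
#' @slot degenerate logical(1), TRUE when no informative cut existed.
#' @export
setClass("VesselMask",
  representation(mask = "matrix", phase = "character", threshold = "numeric",
                 fractionOn = "numeric", degenerate = "logical"),
  prototype(degenerate = FALSE))

setValidity("VesselMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!object@degenerate && !any(object@mask))
    return("non-degenerate mask must contain at least one TRUE pixel")
  TRUE
})

#' Time-density curve
#'
#' Aggregated contrast density in a mask or ROI as a function of time.
#'
#' @slot timestamps numeric, seconds.
#' @slot density numeric, mean contrast density over the masked pixels
#'   (arbitrary units), same length as timestamps.
#' @slot label character(1), phase or ROI name.
#' @slot nPixels integer(1), number of pixels aggregated.
#' @export
setClass("TDC",
  representation(timestamps = "numeric", density = "numeric",
                 label = "character", nPixels = "integer"))

setValidity("TDC", function(object) {
  msg <- character()
  if (length(object@timestamps) != length(object@density))
    msg <- c(msg, "timestamps and density must have the same length")
  if (any(!is.finite(object@density))) msg <- c(msg, "density must be finite")
  if (length(object@timestamps) > 1 && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Fitted gamma-variate bolus model
#'
#' The indicator-dilution model
#' \deqn{C(t) = baseline + K (t - t_0)^{\alpha} e^{-(t - t_0)/\beta}, t > t_0}
#' and \code{C(t) = baseline} otherwise. Time to peak is exactly
#' \code{t0 + alpha * beta}; the full width at half maximum scales linearly
#' in beta at fixed alpha.
#'
#' @slot t0 numeric(1), bolus arrival delay, s.
#' @slot alpha numeric(1), dimensionless shape (> 0).
#' @slot beta numeric(1), time scale, s (> 0).
#' @slot K numeric(1), amplitude, density units.
#' @slot baseline numeric(1), density units.
#' @slot rSquared numeric(1), goodness of fit in [0, 1].
#' @slot ttp numeric(1), s, equals t0 + alpha * beta.
#' @slot fwhm numeric(1), s, full width at half maximum of the fitted curve.
#' @slot converged logical(1).
#' @export
setClass("GammaVariateFit",
  representation(t0 = "numeric", alpha = "numeric", beta = "numeric",
                 K = "numeric", baseline = "numeric", rSquared = "numeric",
                 ttp = "numeric", fwhm = "numeric", converged = "logical"),
  prototype(converged = TRUE))

setValidity("GammaVariateFit", function(object) {
  if (object@alpha <= 0 || object@beta <= 0)
    return("alpha and beta must be > 0")
  if (abs(object@ttp - (object@t0 + object@alpha * object@beta)) > 1e-9)
    return("ttp must equal t0 + alpha * beta")
  TRUE
})

#' Named regions of interest
#'
#' Each region is either a polygon (matrix of (x, y) vertices in 0-based
#' pixel coordinates, filled by the even-odd rule) or a logical H x W mask.
#'
#' @slot regions named list; each element is a list with \code{type}
#'   ("polygon" or "mask") and either \code{xy} (n x 2 matrix) or
#'   \code{mask} (logical matrix).
#' @export
setClass("ROISet", representation(regions = "list"))

setValidity("ROISet", function(object) {
  nm <- names(object@regions)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    return("regions must be uniquely named")
  for (r in object@regions) {
    if (!is.list(r) || is.null(r$type)) return("each region needs a 'type'")
    if (r$type == "polygon") {
      if (!is.matrix(r$xy) || ncol(r$xy) != 2 || nrow(r$xy) < 3)
        return("polygon regions need an n x 2 vertex matrix, n >= 3")
    } else if (r$type == "mask") {
      if (!is.logical(r$mask) || !any(r$mask))
        return("mask regions must be non-empty logical matrices")
    } else return("region type must be 'polygon' or 'mask'")
  }
  TRUE
})

#' Cerebral circulation time result
#'
#' CCT is the time-to-peak difference between the parietal vein and the
#' cavernous segment of the internal carotid artery on a lateral angiogram.
#'
#' @slot ttpArtery numeric(1), s.
#' @slot ttpVein numeric(1), s.
#' @slot cct numeric(1), s, = ttpVein - ttpArtery.
#' @slot method character(1), \code{"argmax"} or \code{"fitted"}.
#' @export
setClass("CCTResult",
  representation(ttpArtery = "numeric", ttpVein = "numeric",
                 cct = "numeric", method = "character"))

setValidity("CCTResult", function(object) {
  if (abs(object@cct - (object@ttpVein - object@ttpArtery)) > 1e-9)
    return("cct must equal ttpVein - ttpArtery")
  TRUE
})

#' Hemodynamic marker report
#'
#' Aggregates per-view aMTT pipeline results, the CCT (when ROIs were
#' supplied), correlations (when a cohort table was supplied) and full
#' provenance for reproducibility.
#'
#' @slot views named list ("AP"/"LAT"); each element a pipeline result list
#'   as returned by [computeAMTT()].
#' @slot cct \code{CCTResult} or NULL.
#' @slot correlations data.frame of pairwise marker correlations or NULL.
#' @slot provenance list: seed, software version, parameters, inputs.
#' @export
setClass("MarkerReport",
  representation(views = "list", cct = "ANY", correlations = "ANY",
                 provenance = "list"),
  prototype(cct = NULL, correlations = NULL, provenance = list()))

#' One phantom compartment
#'
#' @slot phase character(1): arterial, capillary or venous.
#' @slot geometry list of shape descriptors in unit coordinates
#'   (see [ellipseGeom()], [polylineGeom()]).
#' @slot kinetics named list (t0, alpha, beta, K) of the compartment's
#'   gamma-variate course.
#' @slot jitter numeric(1), lognormal sigma of static per-pixel amplitude
#'   jitter (0 = uniform amplitude).
#' @export
setClass("CompartmentSpec",
  representation(phase = "character", geometry = "list", kinetics = "list",
                 jitter = "numeric"),
  prototype(jitter = 0))

setValidity("CompartmentSpec", function(object) {
  msg <- character()
  if (!(object@phase %in% c("arterial", "capillary", "venous")))
    msg <- c(msg, "phase must be arterial, capillary or venous")
  if (!length(object@geometry)) msg <- c(msg, "geometry must be non-empty")
  k <- object@kinetics
  need <- c("t0", "alpha", "beta", "K")
  if (!all(need %in% names(k)))
    msg <- c(msg, "kinetics needs t0, alpha, beta, K")
  else if (k$alpha <= 0 || k$beta <= 0 || k$K <= 0 || k$t0 < 0)
    msg <- c(msg, "kinetics require alpha, beta, K > 0 and t0 >= 0")
  if (object@jitter < 0) msg <- c(msg, "jitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Full synthetic phantom description
#'
#' @slot shape integer(2), (H, W) in pixels.
#' @slot schedule an \code{AcquisitionSchedule}.
#' @slot compartments list of \code{CompartmentSpec}.
#' @slot noiseSigma numeric(1), Gaussian noise s.d. as a fraction of the
#'   global (noiseless) peak density.
#' @slot motion list of per-frame \code{RigidTransform} (empty = motionless).
#' @slot seed integer(1), reproducibility seed.
#' @slot view character(1), "AP" or "LAT".
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", schedule = "AcquisitionSchedule",
                 compartments = "list", noiseSigma = "numeric",
                 motion = "list", seed = "integer", view = "character"),
  prototype(noiseSigma = 0, motion = list(), view = "LAT"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 2L || any(object@shape < 16L))
    msg <- c(msg, "shape must be (H, W) with both >= 16")
  if (!length(object@compartments))
    msg <- c(msg, "at least one compartment required")
  if (!all(vapply(object@compartments, is, TRUE, class2 = "CompartmentSpec")))
    msg <- c(msg, "compartments must be CompartmentSpec objects")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (!(object@view %in% c("AP", "LAT"))) msg <- c(msg, "view must be AP or LAT")
  if (length(msg)) msg else TRUE
})
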