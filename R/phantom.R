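# Synthetic biplane DSA phantom: spatially overlapping arterial, capillary
# and venous compartments with gamma-variate kinetics on the clinical
# multi-rate schedule, optional Gaussian noise, per-pixel amplitude jitter
# and rigid per-frame motion -- every pipeline stage gets a ground truth.
# Densities of overlapping compartments add, as projection physics dictates.

#' Geometry primitives for phantom compartments
#'
#' Shapes are specified in unit coordinates ((0,0) top-left, (1,1)
#' bottom-right) and scaled to the frame, so phantoms are
#' resolution-independent. \code{ellipseGeom} is an axis-angled filled
#' ellipse (a parenchymal blush); \code{polylineGeom} is a stroked path of
#' the given full width (a vessel).
#'
#' @param cx,cy ellipse centre.
#' @param rx,ry ellipse semi-axes.
#' @param angle ellipse rotation, degrees.
#' @return a geometry descriptor list.
#' @export
ellipseGeom <- function(cx, cy, rx, ry, angle = 0)
  list(type = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry, angle = angle)

#' @rdname ellipseGeom
#' @param points n x 2 matrix of path vertices in unit coordinates.
#' @param width full stroke width in unit coordinates.
#' @export
polylineGeom <- function(points, width)
  list(type = "polyline", points = matrix(points, ncol = 2), width = width)

#' @rdname CompartmentSpec-class
#' @param phase,geometry,kinetics,jitter see the class slots.
#' @export
CompartmentSpec <- function(phase, geometry, kinetics, jitter = 0) {
  if (!is.null(geometry$type)) geometry <- list(geometry)
  new("CompartmentSpec", phase = phase, geometry = geometry,
      kinetics = kinetics, jitter = jitter)
}

#' @rdname PhantomSpec-class
#' @param shape,schedule,compartments,noiseSigma,motion,seed,view see slots.
#' @export
PhantomSpec <- function(shape = c(128L, 128L), schedule = defaultSchedule(),
                        compartments, noiseSigma = 0, motion = list(),
                        seed = 1L, view = "LAT") {
  new("PhantomSpec", shape = as.integer(shape), schedule = schedule,
      compartments = compartments, noiseSigma = noiseSigma, motion = motion,
      seed = as.integer(seed), view = view)
}

rasterizeGeometry <- function(geometry, H, W) {
  g <- expand.grid(row = seq_len(H), col = seq_len(W))
  px <- (g$col - 0.5) / W
  py <- (g$row - 0.5) / H
  inside <- rep(FALSE, H * W)
  for (el in geometry) {
    if (el$type == "ellipse") {
      th <- el$angle * pi / 180
      dx <- px - el$cx; dy <- py - el$cy
      u <- (cos(th) * dx + sin(th) * dy) / el$rx
      v <- (-sin(th) * dx + cos(th) * dy) / el$ry
      inside <- inside | (u^2 + v^2 <= 1)
    } else if (el$type == "polyline") {
      pts <- el$points
      half <- el$width / 2
      for (i in seq_len(nrow(pts) - 1L)) {
        ax <- pts[i, 1]; ay <- pts[i, 2]
        bx <- pts[i + 1L, 1]; by <- pts[i + 1L, 2]
        vx <- bx - ax; vy <- by - ay
        len2 <- vx^2 + vy^2
        tproj <- if (len2 > 0) pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1) else 0
        d2 <- (px - (ax + tproj * vx))^2 + (py - (ay + tproj * vy))^2
        inside <- inside | (d2 <= half^2)
      }
    } else stop("unknown geometry type: ", el$type)
  }
  matrix(inside, nrow = H)
}

rasterizeCompartment <- function(comp, H, W) {
  m <- rasterizeGeometry(comp@geometry, H, W) * 1
  if (!any(m > 0)) stop("compartment '", comp@phase,
                        "' rasterizes to an empty region (out of bounds?)")
  if (comp@jitter > 0) {
    j <- matrix(stats::rlnorm(H * W, 0, comp@jitter), H, W)
    m <- m * j
  }
  m
}

#' Generate a phantom series with its ground-truth bundle
#'
#' Each frame is the sum over compartments of its amplitude raster times its
#' gamma-variate course at the frame time, plus Gaussian noise scaled to the
#' noiseless global peak; scheduled rigid motion is applied last. Fully
#' deterministic given the spec's seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with \code{series} (a [DSASeries-class]) and \code{truth}:
#'   per-compartment rasters, binary regions, exact courses on the grid,
#'   kinetics, analytic TTP and FWHM, the motion schedule, timestamps and
#'   the noiseless peak.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  H <- spec@shape[1]; W <- spec@shape[2]
  ts <- buildTimeGrid(spec@schedule)
  T <- length(ts)
  if (length(spec@motion) && length(spec@motion) != T)
    stop("motion schedule must have one transform per frame")
  withSeed(spec@seed, {
    rasters <- lapply(spec@compartments, rasterizeCompartment, H = H, W = W)
    courses <- vapply(spec@compartments, function(cmp) {
      k <- cmp@kinetics
      gammaVariate(ts, k$t0, k$alpha, k$beta, k$K)
    }, numeric(T))
    arr <- array(0, dim = c(T, H, W))
    for (k in seq_along(rasters))
      arr <- arr + outer(courses[, k], rasters[[k]])
    peak <- max(arr)
    if (spec@noiseSigma > 0)
      arr <- arr + array(stats::rnorm(length(arr), 0,
                                      spec@noiseSigma * peak), dim(arr))
    if (length(spec@motion)) {
      for (t in seq_len(T))
        if (!isIdentityTransform(spec@motion[[t]]))
          arr[t, , ] <- warpFrame(arr[t, , ], spec@motion[[t]])
    }
    phases <- vapply(spec@compartments, function(cmp) cmp@phase, "")
    kin <- lapply(spec@compartments, function(cmp) cmp@kinetics)
    names(rasters) <- names(kin) <- phases
    colnames(courses) <- phases
    truth <- list(
      phases = phases,
      rasters = rasters,
      regions = lapply(rasters, function(r) r > 0),
      courses = courses,
      kinetics = kin,
      ttp = vapply(kin, function(k) k$t0 + k$alpha * k$beta, 0),
      fwhm = vapply(kin, function(k) computeFWHM(alpha = k$alpha,
                                                 beta = k$beta), 0),
      motion = spec@motion,
      timestamps = ts,
      peak = peak)
    list(series = DSASeries(arr, ts, view = spec@view), truth = truth)
  })
}

# Amplitude -> K so the course peaks at `amp`: peak = K (alpha beta)^alpha e^-alpha
kForPeak <- function(amp, alpha, beta) amp * exp(alpha) / (alpha * beta)^alpha

# Kinetics with a prescribed TTP: t0 = ttp - alpha*beta
kineticsFor <- function(ttp, alpha, beta, amp) {
  t0 <- ttp - alpha * beta
  stopifnot(t0 >= 0)
  list(t0 = t0, alpha = alpha, beta = beta, K = kForPeak(amp, alpha, beta))
}

phantomGeometries <- function(view) {
  if (view == "LAT") list(
    arterial = list(
      polylineGeom(rbind(c(0.10, 0.90), c(0.15, 0.50), c(0.30, 0.25),
                         c(0.55, 0.15)), 0.035),
      polylineGeom(rbind(c(0.30, 0.25), c(0.38, 0.38)), 0.02)),
    capillary = list(ellipseGeom(0.62, 0.50, 0.20, 0.28)),
    venous = list(
      polylineGeom(rbind(c(0.25, 0.08), c(0.90, 0.12), c(0.92, 0.40)), 0.03))
  ) else list(
    arterial = list(
      polylineGeom(rbind(c(0.50, 0.95), c(0.50, 0.55), c(0.42, 0.42)), 0.035),
      polylineGeom(rbind(c(0.50, 0.60), c(0.58, 0.45)), 0.02)),
    capillary = list(ellipseGeom(0.25, 0.30, 0.15, 0.22),
                     ellipseGeom(0.75, 0.30, 0.15, 0.22)),
    venous = list(polylineGeom(rbind(c(0.50, 0.05), c(0.50, 0.48)), 0.04))
  )
}

# Smooth bolus-sensation motion starting after contrast arrival (patients
# are still at injection): bounded by 4 px translation and 1.5 deg rotation.
motionSchedule <- function(ts, onset = 2) {
  lapply(ts, function(t) {
    if (t < onset) return(RigidTransform())
    u <- t - onset
    RigidTransform(rotation = 1.5 * sin(2 * pi * u / 11),
                   dx = 4.0 * sin(2 * pi * u / 7),
                   dy = 2.5 * sin(2 * pi * u / 9))
  })
}

#' Named standard phantoms
#'
#' \describe{
#'   \item{easy}{spatially disjoint compartments with TTPs 2 / 4.5 / 7 s and
#'     a capillary FWHM of exactly 5 s.}
#'   \item{overlap}{the easy kinetics with the capillary blush shifted onto
#'     the arterial tree (about 20\% pixel overlap).}
#'   \item{severe_stenosis_like}{arterial washout slowed until the arterial
#'     and capillary courses correlate above 0.7 -- the stagnant-flow stress
#'     case in which arteries leak into the capillary component.}
#'   \item{motion}{the easy phantom with rigid motion (<= 5 px, <= 2 deg)
#'     starting after contrast arrival.}
#' }
#'
#' @param name one of "easy", "overlap", "severe_stenosis_like", "motion".
#' @param seed reproducibility seed.
#' @param view "AP" or "LAT" geometry variant (kinetics are shared).
#' @param noiseSigma Gaussian noise s.d. as a fraction of the global peak.
#' @param shape frame shape (default 128 x 128).
#' @param extensionDuration seconds of 2 fps schedule prolongation.
#' @return A [PhantomSpec-class].
#' @export
standardPhantom <- function(name = c("easy", "overlap",
                                     "severe_stenosis_like", "motion"),
                            seed = 1L, view = c("LAT", "AP"),
                            noiseSigma = 0, shape = c(128L, 128L),
                            extensionDuration = 0) {
  name <- match.arg(name)
  view <- match.arg(view)
  schedule <- defaultSchedule(extensionDuration = extensionDuration)
  betaCap <- 5 / gammaShapeWidth(3)        # capillary FWHM exactly 5 s
  kinArt <- kineticsFor(2.0, alpha = 3, beta = 0.45, amp = 1.0)
  kinCap <- kineticsFor(4.5, alpha = 3, beta = betaCap, amp = 0.5)
  kinVen <- kineticsFor(7.0, alpha = 3, beta = 0.8, amp = 0.8)
  geo <- phantomGeometries(view)
  if (name %in% c("overlap", "severe_stenosis_like")) {
    # capillary blush shifted onto the arterial tree: ~20% of the arterial
    # pixels fall inside the blush
    geo$capillary <- if (view == "LAT")
      list(ellipseGeom(0.535, 0.42, 0.20, 0.28))
    else list(ellipseGeom(0.47, 0.52, 0.17, 0.24),
              ellipseGeom(0.75, 0.30, 0.15, 0.22))
  }
  if (name == "severe_stenosis_like")
    kinArt <- kineticsFor(3.6, alpha = 3, beta = 0.95, amp = 1.0)
  motion <- list()
  if (name == "motion")
    motion <- motionSchedule(buildTimeGrid(schedule), onset = 2)
  comps <- list(
    CompartmentSpec("arterial", geo$arterial, kinArt, jitter = 0.15),
    CompartmentSpec("capillary", geo$capillary, kinCap, jitter = 0.15),
    CompartmentSpec("venous", geo$venous, kinVen, jitter = 0.15))
  PhantomSpec(shape = shape, schedule = schedule, compartments = comps,
              noiseSigma = noiseSigma, motion = motion, seed = seed,
              view = view)
}

#' Read a phantom spec from YAML
#'
#' Mirrors the constructor arguments: \code{shape}, \code{schedule}
#' (\code{rates}, \code{durations}, optional \code{extension_rate},
#' \code{extension_duration}), \code{compartments} (each with \code{phase},
#' \code{kinetics} (t0, alpha, beta, K), optional \code{jitter} and a list
#' of \code{geometry} entries), optional \code{noise_sigma}, \code{view},
#' \code{seed}. Alternatively a single \code{standard: <name>} field selects
#' a [standardPhantom()].
#'
#' @param path YAML file.
#' @param seed overrides the seed in the file when not NULL.
#' @return A [PhantomSpec-class].
#' @export
phantomSpecFromYAML <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$standard)) {
    return(standardPhantom(y$standard,
                           seed = if (is.null(seed)) y$seed %||% 1L else seed,
                           view = y$view %||% "LAT",
                           noiseSigma = y$noise_sigma %||% 0,
                           shape = unlist(y$shape %||% c(128L, 128L))))
  }
  if (is.null(y$compartments) || !length(y$compartments))
    stop("phantom spec must define at least one compartment")
  sched <- if (is.null(y$schedule)) defaultSchedule() else
    AcquisitionSchedule(unlist(y$schedule$rates), unlist(y$schedule$durations),
                        extensionRate = y$schedule$extension_rate %||% 2,
                        extensionDuration = y$schedule$extension_duration %||% 0)
  comps <- lapply(y$compartments, function(cc) {
    geo <- lapply(cc$geometry, function(el) {
      if (el$type == "ellipse")
        ellipseGeom(el$cx, el$cy, el$rx, el$ry, el$angle %||% 0)
      else polylineGeom(do.call(rbind, lapply(el$points, unlist)), el$width)
    })
    CompartmentSpec(cc$phase, geo, lapply(cc$kinetics, as.numeric),
                    jitter = cc$jitter %||% 0)
  })
  PhantomSpec(shape = unlist(y$shape %||% c(128L, 128L)), schedule = sched,
              compartments = comps, noiseSigma = y$noise_sigma %||% 0,
              seed = if (is.null(seed)) y$seed %||% 1L else seed,
              view = y$view %||% "LAT")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a phantom's ground truth as JSON
#' @param truth the truth bundle from [generatePhantom()].
#' @param path output JSON path.
#' @export
writeTruth <- function(truth, path) {
  doc <- list(
    phases = truth$phases,
    kinetics = truth$kinetics,
    ttp_s = as.list(truth$ttp),
    fwhm_s = as.list(truth$fwhm),
    motion = lapply(truth$motion, function(tf)
      list(rotation_deg = tf@rotation, dx_px = tf@dx, dy_px = tf@dy)),
    timestamps_s = truth$timestamps,
    peak = truth$peak)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
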