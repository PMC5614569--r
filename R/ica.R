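# Independent component analysis of a DSA series. Each 2-D frame is
# permuted into a 1-D signal over pixels and treated as a mixture of three
# statistically independent source images (arterial tree, capillary blush,
# venous drainage); the per-frame mixing weights are the components' time
# courses. Spatial sources are the natural choice here: distinct vascular
# territories overlap little in space, so their (mean-removed) maps are
# close to independent, whereas the phases' bolus curves overlap heavily in
# time and are substantially correlated -- a temporal-source model could
# not reproduce them under whitening. Estimation is symmetric fixed-point
# FastICA with a log-cosh contrast on PCA-whitened data.

matInvSqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' FastICA decomposition into three vascular phases
#'
#' Rows of the data matrix (frames as 1-D pixel signals) are centred,
#' whitened to \code{nComponents} principal directions, and rotated by
#' symmetric fixed-point iteration maximizing non-Gaussianity (log-cosh
#' contrast) of the spatial sources. The result pairs each spatial map with
#' its per-frame mixing weights (the component's time course); their
#' outer-product sum reconstructs the centred data up to the subspace
#' discarded by whitening. Deterministic given \code{seed}.
#'
#' @param x a [DSASeries-class], or a T x (H*W) matrix as produced by
#'   [flattenSeries()] (then \code{frameDim} must be supplied or attached).
#' @param nComponents number of components; fixed at 3 for the three-phase
#'   model of the cerebral bolus passage.
#' @param seed integer seed for the random orthogonal start.
#' @param maxIter fixed-point iteration cap (default 500).
#' @param tol convergence tolerance on the rotation update (default 1e-4).
#' @param frameDim c(H, W) when \code{x} is a plain matrix.
#' @return An unlabelled [ComponentSet-class] (see [fixSigns()],
#'   [assignPhases()]).
#' @export
decomposeSeries <- function(x, nComponents = 3L, seed = 1L, maxIter = 500L,
                            tol = 1e-4, frameDim = NULL) {
  if (is(x, "DSASeries")) {
    ts <- x@timestamps
    m <- flattenSeries(x)
    frameDim <- attr(m, "frameDim")
  } else {
    ts <- numeric()
    m <- x
    if (is.null(frameDim)) frameDim <- attr(m, "frameDim")
    if (is.null(frameDim)) stop("frameDim (H, W) required for matrix input")
  }
  if (nComponents != 3L)
    stop("the three-phase model fixes nComponents at 3")
  T <- nrow(m)
  if (T < nComponents) stop("need at least as many frames as components")
  if (any(!is.finite(m))) stop("data must be finite")
  P <- ncol(m)

  Xr <- m - rowMeans(m)                    # centre each frame over pixels
  G <- Xr %*% t(Xr) / P                    # T x T frame covariance
  e <- eigen(G, symmetric = TRUE)
  evals <- pmax(e$values, 0)
  effRank <- sum(evals > max(evals) * 1e-10)
  degenerate <- effRank < nComponents
  if (degenerate)
    warning(sprintf("data rank %d < %d components; trailing components are degenerate",
                    effRank, nComponents), call. = FALSE)
  nAct <- min(effRank, nComponents)
  U <- e$vectors[, seq_len(nAct), drop = FALSE]
  d <- sqrt(evals[seq_len(nAct)])
  Za <- diag(1 / d, nAct) %*% t(U) %*% Xr  # whitened: Za %*% t(Za) / P = I

  W <- withSeed(seed, matrix(stats::rnorm(nAct * nAct), nAct, nAct))
  W <- matInvSqrt(W %*% t(W)) %*% W
  iter <- 0L; converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    S <- W %*% Za
    gS <- tanh(S)
    gPrime <- 1 - gS^2
    Wnew <- (gS %*% t(Za)) / P - diag(rowMeans(gPrime), nAct) %*% W
    Wnew <- matInvSqrt(Wnew %*% t(Wnew)) %*% Wnew
    delta <- max(abs(abs(diag(Wnew %*% t(W))) - 1))
    W <- Wnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("FastICA did not converge in %d iterations", maxIter),
            call. = FALSE)

  maps <- matrix(0, nComponents, P)
  maps[seq_len(nAct), ] <- W %*% Za        # sources: unit-variance maps
  # time courses are the mixing weights solving Xr ~ courses %*% maps
  courses <- matrix(0, T, nComponents)
  courses[, seq_len(nAct)] <- Xr %*% t(maps[seq_len(nAct), , drop = FALSE]) / P
  mapArr <- array(0, dim = c(nComponents, frameDim[1], frameDim[2]))
  for (k in seq_len(nComponents))
    mapArr[k, , ] <- unflattenMap(maps[k, ], frameDim[1], frameDim[2])

  new("ComponentSet", timeCourses = courses, spatialMaps = mapArr,
      phaseLabels = rep("unassigned", 3L), timestamps = ts,
      converged = converged && !degenerate, iterations = iter,
      tol = tol, seed = as.integer(seed))
}

#' @rdname ComponentSet-class
#' @param x a \code{ComponentSet}.
#' @export
setGeneric("timeCourses", function(x) standardGeneric("timeCourses"))

#' @rdname ComponentSet-class
#' @export
setMethod("timeCourses", "ComponentSet", function(x) x@timeCourses)

#' @rdname ComponentSet-class
#' @export
setGeneric("spatialMaps", function(x) standardGeneric("spatialMaps"))

#' @rdname ComponentSet-class
#' @export
setMethod("spatialMaps", "ComponentSet", function(x) x@spatialMaps)

#' @rdname ComponentSet-class
#' @export
setGeneric("phaseLabels", function(x) standardGeneric("phaseLabels"))

#' @rdname ComponentSet-class
#' @export
setMethod("phaseLabels", "ComponentSet", function(x) x@phaseLabels)

setMethod("show", "ComponentSet", function(object) {
  d <- dim(object@spatialMaps)
  cat(sprintf("ComponentSet: 3 components over %d frames (%d x %d maps)\n",
              nrow(object@timeCourses), d[2], d[3]))
  cat(sprintf("  labels: %s\n", paste(object@phaseLabels, collapse = ", ")))
  cat(sprintf("  converged: %s after %d iterations (tol %.1e, seed %d)\n",
              object@converged, object@iterations, object@tol, object@seed))
})

#' Resolve the ICA sign ambiguity
#'
#' Each component is multiplied by +/-1 so that its time course's maximum
#' exceeds the absolute value of its minimum (a contrast bolus raises
#' density); the spatial map is flipped with it, leaving the reconstruction
#' unchanged.
#'
#' @param components a [ComponentSet-class].
#' @return The sign-fixed [ComponentSet-class].
#' @export
fixSigns <- function(components) {
  stopifnot(is(components, "ComponentSet"))
  tc <- components@timeCourses
  maps <- components@spatialMaps
  for (k in seq_len(ncol(tc))) {
    if (max(tc[, k]) < abs(min(tc[, k]))) {
      tc[, k] <- -tc[, k]
      maps[k, , ] <- -maps[k, , ]
    }
  }
  initialize(components, timeCourses = tc, spatialMaps = maps)
}

#' Label components as arterial / capillary / venous
#'
#' Components are ordered by the time of their time-course maximum (time to
#' peak): earliest is arterial, middle capillary, latest venous. Ties are
#' broken by spatial-map energy (larger energy takes the earlier phase),
#' then by component index (with a warning). Components are reordered into
#' arterial, capillary, venous order.
#'
#' @param components a sign-fixed [ComponentSet-class].
#' @param timestamps frame times; defaults to those stored in the set.
#' @return The labelled, reordered [ComponentSet-class].
#' @export
assignPhases <- function(components, timestamps = NULL) {
  stopifnot(is(components, "ComponentSet"))
  if (is.null(timestamps)) timestamps <- components@timestamps
  if (!length(timestamps)) stop("timestamps required to assign phases")
  if (length(timestamps) != nrow(components@timeCourses))
    stop("timestamps length must match the time courses")
  ttp <- timestamps[apply(components@timeCourses, 2L, which.max)]
  energy <- apply(components@spatialMaps, 1L, function(m) sum(m^2))
  if (anyDuplicated(ttp)) {
    dup <- duplicated(ttp) | duplicated(ttp, fromLast = TRUE)
    if (anyDuplicated(cbind(ttp, energy)))
      warning("components tie on both TTP and map energy; breaking by index",
              call. = FALSE)
  }
  ord <- order(ttp, -energy, seq_along(ttp))
  initialize(components,
             timeCourses = components@timeCourses[, ord, drop = FALSE],
             spatialMaps = components@spatialMaps[ord, , , drop = FALSE],
             phaseLabels = c("arterial", "capillary", "venous"))
}

#' Extract one labelled component
#' @param components a labelled [ComponentSet-class].
#' @param phase "arterial", "capillary" or "venous".
#' @return list with \code{course} (length T) and \code{map} (H x W).
#' @export
getComponent <- function(components, phase = c("arterial", "capillary",
                                               "venous")) {
  phase <- match.arg(phase)
  k <- match(phase, components@phaseLabels)
  if (is.na(k)) stop("components are not phase-labelled yet")
  list(course = components@timeCourses[, k],
       map = components@spatialMaps[k, , ])
}

#' Export component time courses as CSV
#'
#' Columns \code{t_s,arterial,capillary,venous}.
#' @param components a labelled [ComponentSet-class].
#' @param path output CSV path.
#' @export
writeTimeCourses <- function(components, path) {
  stopifnot(!any(components@phaseLabels == "unassigned"))
  d <- data.frame(t_s = components@timestamps,
                  arterial = getComponent(components, "arterial")$course,
                  capillary = getComponent(components, "capillary")$course,
                  venous = getComponent(components, "venous")$course)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Export component spatial maps as a multi-page TIFF
#' @param components a [ComponentSet-class].
#' @param path output .tif path.
#' @export
writeComponentMaps <- function(components, path) {
  maps <- components@spatialMaps
  lo <- min(maps); hi <- max(maps)
  pages <- lapply(seq_len(dim(maps)[1]), function(k)
    if (hi > lo) (maps[k, , ] - lo) / (hi - lo) else maps[k, , ] * 0)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
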