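# Keypoint-based rigid motion correction. Every frame of a series is aligned
# to the reference frame at t = 0 so that patient motion does not smear the
# time-density curves. Corners are detected on a smoothed frame (Harris
# response), described by orientation-normalized intensity patches, matched
# under Lowe's ratio test and fitted with a RANSAC rigid consensus.

#' @rdname RigidTransform-class
#' @param rotation degrees; \code{dx,dy} pixels.
#' @param dx,dy translation components in pixels.
#' @export
RigidTransform <- function(rotation = 0, dx = 0, dy = 0)
  new("RigidTransform", rotation = rotation, dx = dx, dy = dy)

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rot %.3f deg, dx %.3f px, dy %.3f px\n",
              object@rotation, object@dx, object@dy))
})

isIdentityTransform <- function(tf, tol = 1e-12)
  abs(tf@rotation) < tol && abs(tf@dx) < tol && abs(tf@dy) < tol

# Harris corner response and local-maximum keypoints (0-based x = col,
# y = row), strongest first, borders excluded so descriptors fit.
detectKeypoints <- function(frame, maxKeypoints = 200L, margin = 14L,
                            sigma = 1.5) {
  f <- smoothMatrix(frame, 1)
  H <- nrow(f); W <- ncol(f)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (f[, 3:W] - f[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (f[3:H, ] - f[1:(H - 2), ]) / 2
  Sxx <- smoothMatrix(gx * gx, sigma)
  Syy <- smoothMatrix(gy * gy, sigma)
  Sxy <- smoothMatrix(gx * gy, sigma)
  R <- (Sxx * Syy - Sxy^2) - 0.04 * (Sxx + Syy)^2
  rmax <- max(R)
  if (!is.finite(rmax) || rmax <= 0) return(NULL)
  keep <- matrix(FALSE, H, W)
  inner <- R[2:(H - 1), 2:(W - 1)]
  keep[2:(H - 1), 2:(W - 1)] <-
    inner > R[1:(H - 2), 2:(W - 1)] & inner >= R[3:H, 2:(W - 1)] &
    inner > R[2:(H - 1), 1:(W - 2)] & inner >= R[2:(H - 1), 3:W] &
    inner > 0.005 * rmax
  keep[seq_len(margin), ] <- FALSE; keep[(H - margin + 1):H, ] <- FALSE
  keep[, seq_len(margin)] <- FALSE; keep[, (W - margin + 1):W] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  ord <- order(R[keep], decreasing = TRUE)
  idx <- idx[ord[seq_len(min(maxKeypoints, nrow(idx)))], , drop = FALSE]
  list(x = idx[, 2] - 1, y = idx[, 1] - 1, gx = gx, gy = gy)
}

# Dominant gradient orientation (radians) per keypoint: magnitude-weighted
# 36-bin histogram over a disc of the given radius.
keypointOrientations <- function(kp, radius = 6L) {
  offs <- expand.grid(oy = -radius:radius, ox = -radius:radius)
  offs <- offs[offs$ox^2 + offs$oy^2 <= radius^2, ]
  w <- exp(-(offs$ox^2 + offs$oy^2) / (2 * (radius / 1.5)^2))
  H <- nrow(kp$gx); W <- ncol(kp$gx)
  vapply(seq_along(kp$x), function(i) {
    r <- kp$y[i] + offs$oy + 1; c <- kp$x[i] + offs$ox + 1
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    ii <- cbind(r[ok], c[ok])
    mx <- kp$gx[ii]; my <- kp$gy[ii]
    mag <- sqrt(mx^2 + my^2) * w[ok]
    ang <- atan2(my, mx)
    bins <- pmin(floor((ang + pi) / (2 * pi) * 36) + 1, 36)
    hist <- vapply(seq_len(36), function(b) sum(mag[bins == b]), 0)
    (which.max(hist) - 0.5) / 36 * 2 * pi - pi
  }, 0)
}

# 8 x 8 intensity patch sampled on a grid rotated to the keypoint
# orientation, normalized to zero mean / unit norm.
describeKeypoints <- function(frame, kp, spacing = 2.5) {
  ori <- keypointOrientations(kp)
  g <- expand.grid(u = seq(-3.5, 3.5), v = seq(-3.5, 3.5)) * spacing
  desc <- matrix(0, nrow = length(kp$x), ncol = nrow(g))
  for (i in seq_along(kp$x)) {
    ct <- cos(ori[i]); st <- sin(ori[i])
    sx <- kp$x[i] + ct * g$u - st * g$v
    sy <- kp$y[i] + st * g$u + ct * g$v
    v <- bilinearSample(frame, sy + 1, sx + 1)
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    desc[i, ] <- if (nv > 0) v / nv else v
  }
  desc
}

# Lowe ratio-test matching: for each moving keypoint the nearest and second
# nearest reference descriptors; keep matches with d1/d2 < ratio.
matchKeypoints <- function(descMov, descRef, ratio = 0.75) {
  if (is.null(descMov) || is.null(descRef) ||
      nrow(descMov) < 2L || nrow(descRef) < 2L) return(NULL)
  # squared euclidean distances via cross products
  d2 <- outer(rowSums(descMov^2), rowSums(descRef^2), "+") -
    2 * descMov %*% t(descRef)
  d2[d2 < 0] <- 0
  best <- apply(d2, 1, function(r) {
    o <- order(r)[1:2]
    c(o[1], sqrt(r[o[1]]), sqrt(r[o[2]]))
  })
  keep <- best[2, ] < ratio * best[3, ]
  if (!any(keep)) return(NULL)
  list(mov = which(keep), ref = best[1, keep])
}

# Closed-form rigid fit (2-D Procrustes without scale) mapping moving
# points onto reference points; coordinates are centre-relative.
fitRigid <- function(mx, my, rx, ry, H, W) {
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  pm <- cbind(mx - cx, my - cy); pr <- cbind(rx - cx, ry - cy)
  mm <- colMeans(pm); mr <- colMeans(pr)
  a <- sweep(pm, 2, mm); b <- sweep(pr, 2, mr)
  num <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  den <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  th <- atan2(num, den)
  if (abs(th) > 45 * pi / 180) return(NULL)  # outside cranial sanity bounds
  ct <- cos(th); st <- sin(th)
  t <- mr - c(ct * mm[1] - st * mm[2], st * mm[1] + ct * mm[2])
  RigidTransform(rotation = th * 180 / pi, dx = t[1], dy = t[2])
}

#' Estimate the rigid transform aligning a moving frame to a reference
#'
#' Keypoints are detected on both frames, described by orientation-normalized
#' patches, matched under a 0.75 ratio test and fitted by RANSAC (1 px inlier
#' tolerance) followed by a least-squares refit on the inliers. With fewer
#' than \code{minMatches} matches the identity is returned with a warning:
#' early contrast-free subtraction frames legitimately carry no anatomy.
#'
#' @param moving,reference numeric H x W frames of the same shape.
#' @param minMatches minimum ratio-test matches required (default 8).
#' @return A [RigidTransform-class] mapping moving coordinates into reference
#'   coordinates; attribute \code{nInliers} records the consensus size.
#' @export
estimateTransform <- function(moving, reference, minMatches = 8L) {
  if (!identical(dim(moving), dim(reference)))
    stop("moving and reference frames must have the same shape")
  H <- nrow(reference); W <- ncol(reference)
  tf <- estimateFromFeatures(frameFeatures(moving), frameFeatures(reference),
                             H, W, minMatches = minMatches)
  nInliers <- if (is.null(tf)) 0L else attr(tf, "nInliers")
  if (is.null(tf)) {
    warning("too few keypoint matches or no rigid consensus; ",
            "returning identity transform", call. = FALSE)
    tf <- RigidTransform()
  }
  # sub-pixel intensity refinement (no-op on featureless frames)
  tf <- refineRigid(moving, reference, init = tf)
  attr(tf, "nInliers") <- nInliers
  tf
}

# Gauss-Newton intensity refinement of a rigid transform (sub-pixel).
# Estimates S mapping reference coords -> moving coords by minimizing
# || g * moving(S x) - reference(x) ||^2 over rotation, translation and a
# global gain g (contrast amplitude evolves between frames). Returns the
# moving -> reference transform (the inverse of S). Falls back to `init`
# when there is too little shared signal to refine against.
refineRigid <- function(moving, reference, init = RigidTransform(),
                        maxIter = 15L, sigma = 1.5) {
  H <- nrow(reference); W <- ncol(reference)
  refS <- smoothMatrix(reference, sigma)
  movS <- smoothMatrix(moving, sigma)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (movS[, 3:W] - movS[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (movS[3:H, ] - movS[1:(H - 2), ]) / 2
  thr <- 0.03 * max(abs(refS))
  sel <- which(abs(refS) > thr, arr.ind = TRUE)
  sel <- sel[sel[, 1] > 2 & sel[, 1] < H - 1 & sel[, 2] > 2 & sel[, 2] < W - 1,
             , drop = FALSE]
  if (nrow(sel) < 50L || max(abs(movS)) == 0) return(init)
  if (nrow(sel) > 4000L) {
    # the normal equations are well determined long before this; thin
    # deterministically to bound the per-frame cost
    sel <- sel[seq(1L, nrow(sel), length.out = 4000L), , drop = FALSE]
  }
  x <- sel[, 2] - 1; y <- sel[, 1] - 1
  ref <- refS[sel]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  Sinv <- invertTransform(init)
  phi <- Sinv@rotation * pi / 180; ex <- Sinv@dx; ey <- Sinv@dy
  cost <- function(phi, ex, ey) {
    ct <- cos(phi); st <- sin(phi)
    sx <- ct * (x - cx) - st * (y - cy) + cx + ex
    sy <- st * (x - cx) + ct * (y - cy) + cy + ey
    inb <- sx >= 1 & sx <= W - 2 & sy >= 1 & sy <= H - 2
    if (sum(inb) < 50L) return(Inf)
    w <- bilinearSample(movS, sy[inb] + 1, sx[inb] + 1)
    ww <- sum(w * w)
    if (ww <= 0) return(Inf)
    g <- sum(w * ref[inb]) / ww
    sum((g * w - ref[inb])^2) / sum(inb)
  }
  initCost <- cost(phi, ex, ey)
  for (it in seq_len(maxIter)) {
    ct <- cos(phi); st <- sin(phi)
    sx <- ct * (x - cx) - st * (y - cy) + cx + ex
    sy <- st * (x - cx) + ct * (y - cy) + cy + ey
    inb <- sx >= 1 & sx <= W - 2 & sy >= 1 & sy <= H - 2
    if (sum(inb) < 50L) break
    w <- bilinearSample(movS, sy[inb] + 1, sx[inb] + 1)
    ww <- sum(w * w)
    if (ww <= 0) break
    g <- sum(w * ref[inb]) / ww
    r <- g * w - ref[inb]
    jx <- g * bilinearSample(gx, sy[inb] + 1, sx[inb] + 1)
    jy <- g * bilinearSample(gy, sy[inb] + 1, sx[inb] + 1)
    dxp <- -st * (x[inb] - cx) - ct * (y[inb] - cy)
    dyp <- ct * (x[inb] - cx) - st * (y[inb] - cy)
    J <- cbind(jx * dxp + jy * dyp, jx, jy)
    JtJ <- crossprod(J)
    step <- tryCatch(solve(JtJ, -crossprod(J, r)), error = function(e) NULL)
    if (is.null(step)) break
    phi <- phi + step[1]; ex <- ex + step[2]; ey <- ey + step[3]
    if (abs(step[1]) < 1e-6 && abs(step[2]) < 1e-4 && abs(step[3]) < 1e-4)
      break
  }
  # reject solutions outside sanity bounds or worse than the initializer
  if (abs(phi) > 45 * pi / 180 || abs(ex) > W / 2 || abs(ey) > H / 2)
    return(init)
  if (!is.finite(initCost) || cost(phi, ex, ey) > initCost)
    return(init)
  invertTransform(RigidTransform(rotation = phi * 180 / pi, dx = ex, dy = ey))
}

frameFeatures <- function(frame) {
  kp <- detectKeypoints(frame)
  if (is.null(kp)) return(NULL)
  list(kp = kp, desc = describeKeypoints(frame, kp))
}

estimateFromFeatures <- function(featM, featR, H, W, minMatches = 8L) {
  if (is.null(featM) || is.null(featR) ||
      length(featM$kp$x) < minMatches || length(featR$kp$x) < minMatches)
    return(NULL)
  m <- matchKeypoints(featM$desc, featR$desc)
  if (is.null(m) || length(m$mov) < minMatches) return(NULL)
  mx <- featM$kp$x[m$mov]; my <- featM$kp$y[m$mov]
  rx <- featR$kp$x[m$ref]; ry <- featR$kp$y[m$ref]
  n <- length(mx)
  best <- NULL; bestInl <- logical(n); bestCount <- 0L
  withSeed(760417L, {
    for (it in seq_len(400L)) {
      s <- sample.int(n, 2L)
      if (abs(mx[s[1]] - mx[s[2]]) + abs(my[s[1]] - my[s[2]]) < 2) next
      tf <- fitRigid(mx[s], my[s], rx[s], ry[s], H, W)
      if (is.null(tf)) next
      p <- applyTransform(tf, mx, my, H, W)
      inl <- (p$x - rx)^2 + (p$y - ry)^2 <= 1
      if (sum(inl) > bestCount) {
        bestCount <- sum(inl); bestInl <- inl; best <- tf
      }
    }
  })
  if (is.null(best) || bestCount < max(3L, minMatches %/% 2L)) return(NULL)
  tf <- fitRigid(mx[bestInl], my[bestInl], rx[bestInl], ry[bestInl], H, W)
  if (is.null(tf) || abs(tf@dx) > W / 2 || abs(tf@dy) > H / 2)
    return(NULL)
  attr(tf, "nInliers") <- bestCount
  tf
}

#' Motion-correct a series against its t = 0 reference frame
#'
#' Every frame is rigidly aligned into the coordinate system of the t = 0
#' reference and resampled bilinearly (out-of-bounds pixels are zero
#' density). Because adjacent frames are the only pairs guaranteed to share
#' appearance through contrast wash-in and wash-out, each frame is aligned
#' to its predecessor -- keypoint consensus when the relative motion is
#' large, always followed by sub-pixel Gauss-Newton intensity refinement
#' with a free gain -- and the relative transforms are composed back to the
#' reference. Contrast-free frames (no usable signal, e.g. before bolus
#' arrival) contribute an identity link, which simply carries their
#' neighbour's transform forward.
#'
#' @param series a [DSASeries-class].
#' @param minMatches minimum keypoint matches per frame for the consensus
#'   stage (default 8).
#' @return list with \code{series} (registered [DSASeries-class]) and
#'   \code{transforms} (list of [RigidTransform-class] for frames 2..T,
#'   each mapping that frame into reference coordinates).
#' @export
registerSeries <- function(series, minMatches = 8L) {
  stopifnot(is(series, "DSASeries"))
  T <- nFrames(series)
  if (T == 1L) return(list(series = series, transforms = list()))
  H <- dim(series@frames)[2]; W <- dim(series@frames)[3]
  tfs <- rep(list(RigidTransform()), T)
  for (t in 2:T) {
    prev <- series@frames[t - 1L, , ]
    cur <- series@frames[t, , ]
    rel <- refineRigid(cur, prev)
    if (isIdentityTransform(rel)) {
      # refinement may have bailed out (large motion or weak signal);
      # try the keypoint consensus stage as an initializer
      kp <- estimateFromFeatures(frameFeatures(cur), frameFeatures(prev),
                                 H, W, minMatches)
      if (!is.null(kp)) rel <- refineRigid(cur, prev, init = kp)
    }
    # adjacent frames are a fraction of a second apart: implausibly large
    # relative motion is a mis-estimate, carried as an identity link
    if (abs(rel@rotation) > 10 || abs(rel@dx) > 10 || abs(rel@dy) > 10 ||
        abs(tfs[[t - 1L]]@rotation + rel@rotation) > 45)
      rel <- RigidTransform()
    tfs[[t]] <- composeTransforms(tfs[[t - 1L]], rel)
  }
  out <- series@frames
  for (t in seq_len(T))
    if (!isIdentityTransform(tfs[[t]]))
      out[t, , ] <- warpFrame(series@frames[t, , ], tfs[[t]])
  reg <- DSASeries(out, series@timestamps, view = series@view,
                   polarityInverted = series@polarityInverted,
                   baselineSubtracted = series@baselineSubtracted)
  list(series = reg, transforms = tfs[-1L])
}

#' Export per-frame transforms as CSV
#'
#' Columns \code{frame,rotation_deg,dx_px,dy_px} (frame index 1-based,
#' starting at the first moving frame).
#' @param transforms list of [RigidTransform-class].
#' @param path output CSV path.
#' @export
writeTransforms <- function(transforms, path) {
  d <- data.frame(
    frame = seq_along(transforms) + 1L,
    rotation_deg = vapply(transforms, function(x) x@rotation, 0),
    dx_px = vapply(transforms, function(x) x@dx, 0),
    dy_px = vapply(transforms, function(x) x@dy, 0))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
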