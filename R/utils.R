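# Internal numeric helpers shared across modules.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

gaussianKernel1D <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# n x n smoothing operator with replicate boundary handling; smoothing a
# matrix separably is then two dense matrix products (cheap at DSA sizes).
smoothingOperator <- function(n, sigma) {
  k <- gaussianKernel1D(sigma)
  r <- (length(k) - 1L) / 2L
  S <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in seq(-r, r)) {
    j <- pmin(pmax(idx + o, 1L), n)
    S[cbind(idx, j)] <- S[cbind(idx, j)] + k[o + r + 1L]
  }
  S
}

smoothMatrix <- function(x, sigma) {
  if (sigma <= 0) return(x)
  Sr <- smoothingOperator(nrow(x), sigma)
  Sc <- smoothingOperator(ncol(x), sigma)
  Sr %*% x %*% t(Sc)
}

# Bilinear sampling of a matrix at continuous 1-based (row, col) positions;
# out-of-bounds samples return 0 (no contrast outside the detector).
bilinearSample <- function(img, row, col) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  val <- numeric(length(row))
  pick <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  val <- pick(r0, c0) * (1 - fr) * (1 - fc) +
    pick(r0 + 1, c0) * fr * (1 - fc) +
    pick(r0, c0 + 1) * (1 - fr) * fc +
    pick(r0 + 1, c0 + 1) * fr * fc
  val
}

# Apply a RigidTransform to 0-based (x, y) points: x_ref = R (x - c) + c + t.
applyTransform <- function(tf, x, y, H, W) {
  th <- tf@rotation * pi / 180
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xr <- cos(th) * (x - cx) - sin(th) * (y - cy) + cx + tf@dx
  yr <- sin(th) * (x - cx) + cos(th) * (y - cy) + cy + tf@dy
  list(x = xr, y = yr)
}

invertTransform <- function(tf) {
  # inverse of x -> R(x - c) + c + t  is  x -> R^T (x - c - t) + c, i.e. a
  # rigid transform with angle -theta and translation -R^T t
  th <- -tf@rotation * pi / 180
  new("RigidTransform", rotation = -tf@rotation,
      dx = -(cos(th) * tf@dx - sin(th) * tf@dy),
      dy = -(sin(th) * tf@dx + cos(th) * tf@dy))
}

composeTransforms <- function(a, b) {
  # transform equivalent to applying b first, then a
  tha <- a@rotation * pi / 180
  new("RigidTransform", rotation = a@rotation + b@rotation,
      dx = cos(tha) * b@dx - sin(tha) * b@dy + a@dx,
      dy = sin(tha) * b@dx + cos(tha) * b@dy + a@dy)
}

# Warp a frame so that its content is mapped by `tf` into reference
# coordinates: out(x_ref) = frame(tf^-1(x_ref)), bilinear, 0 outside.
warpFrame <- function(frame, tf) {
  H <- nrow(frame); W <- ncol(frame)
  inv <- invertTransform(tf)
  g <- expand.grid(row = seq_len(H), col = seq_len(W))
  p <- applyTransform(inv, g$col - 1, g$row - 1, H, W)
  matrix(bilinearSample(frame, p$y + 1, p$x + 1), nrow = H)
}

# Even-odd polygon fill over pixel centres; xy is an n x 2 matrix of
# 0-based (x, y) vertices. Returns a logical H x W mask.
rasterizePolygon <- function(xy, H, W) {
  g <- expand.grid(row = seq_len(H), col = seq_len(W))
  px <- g$col - 1; py <- g$row - 1
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = H)
}

pearson <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  stats::cor(a, b)
}
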